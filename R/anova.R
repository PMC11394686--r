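#' Partial eta squared from an F statistic
#'
#' Effect size for a reported ANOVA effect:
#' `F * df1 / (F * df1 + df2)`, the proportion of effect-plus-error variance
#' attributable to the effect.
#'
#' @param F_value F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Partial eta squared, in `[0, 1)`. Vectorised.
#' @examples
#' partial_eta_squared(4.516, 1, 18) # 0.201 at 3 dp
#' @export
partial_eta_squared <- function(F_value, df1, df2) {
  if (any(F_value < 0)) abort("`F_value` must be non-negative.")
  if (any(df1 < 1) || any(df2 < 1)) abort("degrees of freedom must be >= 1.")
  F_value * df1 / (F_value * df1 + df2)
}

#' Upper-tail p value of an F statistic
#'
#' @inheritParams partial_eta_squared
#' @return `P(F(df1, df2) >= F_value)`. Vectorised.
#' @export
f_pvalue <- function(F_value, df1, df2) {
  if (any(F_value < 0)) abort("`F_value` must be non-negative.")
  if (any(df1 < 1) || any(df2 < 1)) abort("degrees of freedom must be >= 1.")
  pf(F_value, df1, df2, lower.tail = FALSE)
}

#' Greenhouse-Geisser epsilon of a within-subject covariance
#'
#' `epsilon = (sum lambda)^2 / ((k - 1) * sum lambda^2)` where `lambda` are
#' the eigenvalues of the doubly-centred covariance matrix. Equals 1 under
#' compound symmetry (sphericity) and attains its lower bound `1/(k-1)` for a
#' maximally non-spherical (rank-1 centred) covariance.
#'
#' @param within_covariance Symmetric positive semidefinite `k x k` matrix,
#'   `k >= 2`.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(within_covariance) {
  S <- as.matrix(within_covariance)
  k <- nrow(S)
  if (k < 2 || ncol(S) != k) abort("`within_covariance` must be k x k, k >= 2.")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    abort("`within_covariance` must be symmetric.")
  }
  M <- diag(k) - 1 / k
  lambda <- eigen(M %*% S %*% M, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  eps <- sum(lambda)^2 / ((k - 1) * sum(lambda^2))
  min(max(eps, 1 / (k - 1)), 1)
}

# Mauchly's sphericity test on the pooled within-group covariance.
# S: residual covariance with df n_e (number of subjects minus groups).
mauchly_sphericity <- function(S, n_e) {
  k <- nrow(S)
  d <- k - 1L
  if (d < 2L) return(list(W = 1, p = 1))  # sphericity trivially holds at k = 2
  C <- contrast_matrix(k)
  E <- C %*% S %*% t(C)
  lambda <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  if (any(lambda <= 0)) return(list(W = 0, p = 0))
  W <- prod(lambda) / (mean(lambda)^d)
  chi <- -(n_e - (2 * d^2 + d + 2) / (6 * d)) * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, p = pchisq(chi, df, lower.tail = FALSE))
}

# Orthonormal contrast matrix (k-1 x k) spanning the complement of the mean.
contrast_matrix <- function(k) {
  H <- stats::contr.helmert(k)
  t(sweep(H, 2, sqrt(colSums(H^2)), "/"))
}

#' Split-plot (mixed repeated-measures) ANOVA of the difference statistic
#'
#' Analyses the per-subject walking-minus-resting band-power differences for
#' one band with a two-way mixed design: `group` (between subjects) x
#' `region` (within subjects). Sums of squares follow the classical
#' split-plot decomposition — group tested against subjects-within-groups,
#' region and group x region against the region x subjects-within-groups
#' residual. Mauchly's test (on the pooled within-group covariance, df
#' `N - g`) gates the Greenhouse-Geisser correction at
#' `sphericity_alpha`: when sphericity is rejected, the within-effect p
#' values are recomputed with epsilon-multiplied degrees of freedom (the F
#' statistics are unchanged). Fisher LSD pairwise comparisons for both
#' factors use the corresponding pooled error mean square and df.
#'
#' @param data Tibble with one row per subject x region.
#' @param value,between,within,subject Column names (strings) of the
#'   response, group factor, within factor, and subject identifier.
#' @param band Optional band label carried into the result.
#' @param sphericity_alpha Alpha of the Mauchly gate (default 0.05).
#' @return Object of class `lfp_anova`; see [tidy.lfp_anova()] and
#'   [glance.lfp_anova()].
#' @examples
#' d <- simulate_diff_table(n_per_group = 6, seed = 42)
#' fit <- mixed_anova(d)
#' tidy(fit)
#' @export
mixed_anova <- function(data, value = "diff", between = "group",
                        within = "region", subject = "subject_id",
                        band = NA_character_, sphericity_alpha = 0.05) {
  cols <- c(value, between, within, subject)
  if (!all(cols %in% names(data))) {
    abort(paste("missing columns:", paste(setdiff(cols, names(data)), collapse = ", ")))
  }
  df <- data.frame(y = data[[value]],
                   g = as.character(data[[between]]),
                   r = as.character(data[[within]]),
                   s = as.character(data[[subject]]))
  if (anyNA(df)) abort("missing values in the design.")
  regions <- unique(df$r)
  k <- length(regions)
  subjects <- unique(df[, c("s", "g")])
  if (anyDuplicated(subjects$s)) abort("a subject appears in more than one group.")
  N <- nrow(subjects)
  groups <- unique(subjects$g)
  g <- length(groups)
  n_per <- table(subjects$g)
  if (length(unique(n_per)) != 1) {
    abort(sprintf("unbalanced design: group sizes %s.",
                  paste(n_per, collapse = ", ")))
  }
  n <- unname(n_per[1])
  if (n < 2) abort("need at least 2 subjects per group.")
  if (nrow(df) != N * k || anyDuplicated(df[, c("s", "r")])) {
    abort("incomplete design: every subject needs exactly one value per region.")
  }
  # wide response matrix, subjects x regions
  Y <- matrix(NA_real_, N, k, dimnames = list(subjects$s, regions))
  Y[cbind(match(df$s, subjects$s), match(df$r, regions))] <- df$y

  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  group_of <- subjects$g
  group_means <- tapply(subj_means, group_of, mean)[groups]
  region_means <- colMeans(Y)
  cell_means <- rowsum(Y, group_of)[groups, , drop = FALSE] / n

  ss_total <- sum((Y - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * n * sum((group_means - grand)^2)
  ss_e1 <- ss_subj - ss_group
  ss_region <- N * sum((region_means - grand)^2)
  inter_dev <- sweep(sweep(cell_means, 1, group_means, "-"),
                     2, region_means, "-") + grand
  ss_gxr <- n * sum(inter_dev^2)
  ss_e2 <- ss_total - ss_subj - ss_region - ss_gxr

  df_group <- g - 1; df_e1 <- N - g
  df_region <- k - 1; df_gxr <- (g - 1) * (k - 1); df_e2 <- (N - g) * (k - 1)
  ms_e1 <- ss_e1 / df_e1
  ms_e2 <- ss_e2 / df_e2
  F_group <- (ss_group / df_group) / ms_e1
  F_region <- (ss_region / df_region) / ms_e2
  F_gxr <- (ss_gxr / df_gxr) / ms_e2

  # pooled within-group covariance of the region columns
  resid <- Y - cell_means[match(group_of, groups), colnames(Y), drop = FALSE]
  S <- crossprod(resid) / (N - g)
  mauchly <- mauchly_sphericity(S, N - g)
  eps <- gg_epsilon(S)
  correct <- k > 2 && mauchly$p < sphericity_alpha

  p_within <- function(F_value, df1, df2) {
    c(uncorrected = pf(F_value, df1, df2, lower.tail = FALSE),
      reported = if (correct) {
        pf(F_value, eps * df1, eps * df2, lower.tail = FALSE)
      } else pf(F_value, df1, df2, lower.tail = FALSE))
  }
  p_r <- p_within(F_region, df_region, df_e2)
  p_x <- p_within(F_gxr, df_gxr, df_e2)
  effects <- tibble::tibble(
    effect = c("group", "channel", "group:channel"),
    F = c(F_group, F_region, F_gxr),
    df1 = c(df_group, df_region, df_gxr),
    df2 = c(df_e1, df_e2, df_e2),
    p_uncorrected = c(pf(F_group, df_group, df_e1, lower.tail = FALSE),
                      p_r["uncorrected"], p_x["uncorrected"]),
    p_reported = c(pf(F_group, df_group, df_e1, lower.tail = FALSE),
                   p_r["reported"], p_x["reported"]),
    partial_eta_sq = partial_eta_squared(
      c(F_group, F_region, F_gxr),
      c(df_group, df_region, df_gxr), c(df_e1, df_e2, df_e2)))

  fit <- structure(
    list(band = band, effects = effects,
         mauchly_W = mauchly$W, mauchly_p = mauchly$p, gg_epsilon = eps,
         correction_applied = correct,
         means = list(group = group_means, channel = region_means,
                      cell = cell_means),
         error_ms = c(between = ms_e1, within = ms_e2),
         error_df = c(between = df_e1, within = df_e2),
         n_per_group = n, n_groups = g, k = k,
         ss = c(group = ss_group, e1 = ss_e1, channel = ss_region,
                gxr = ss_gxr, e2 = ss_e2, total = ss_total)),
    class = "lfp_anova")
  fit$lsd <- list(channel = lsd_posthoc(fit, "channel"),
                  group = lsd_posthoc(fit, "group"))
  fit
}

#' Fisher LSD post hoc comparisons for a fitted split-plot ANOVA
#'
#' All pairwise comparisons of the marginal means of one factor, each tested
#' with the ANOVA's pooled error mean square and error df for that stratum
#' (subjects-within-groups for `group`, the within residual for `channel`).
#' Per-pair p values are two-sided and unadjusted (classical least
#' significant difference). Channel comparisons pool across groups.
#'
#' @param fit An `lfp_anova` object.
#' @param effect `"channel"` or `"group"`.
#' @return Tibble of comparisons (`a`, `b`, `mean_a`, `mean_b`, `diff`, `t`,
#'   `df`, `p`) with attribute `ordering`: the compact ordering string, e.g.
#'   `"PPN/SNc/STN > M1"`, listing significant pairs with mutually
#'   indistinguishable left/right sides grouped by `/`; `"NA"` when no pair
#'   is significant.
#' @export
lsd_posthoc <- function(fit, effect = c("channel", "group")) {
  effect <- match.arg(effect)
  if (!inherits(fit, "lfp_anova")) abort("`fit` must be an lfp_anova.")
  means <- fit$means[[effect]]
  if (is.null(means)) abort(sprintf("effect '%s' not present in the fit.", effect))
  n_eff <- if (effect == "channel") {
    fit$n_per_group * fit$n_groups            # subjects per channel mean
  } else {
    fit$n_per_group * fit$k                   # observations per group mean
  }
  ms <- if (effect == "channel") fit$error_ms["within"] else fit$error_ms["between"]
  edf <- if (effect == "channel") fit$error_df["within"] else fit$error_df["between"]
  labs <- names(means)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  cmp <- purrr::map_dfr(pairs, function(p) {
    a <- p[1]; b <- p[2]
    if (means[a] < means[b]) { tmp <- a; a <- b; b <- tmp }  # larger first
    se <- sqrt(2 * ms / n_eff)
    tval <- (means[a] - means[b]) / se
    tibble::tibble(a = a, b = b, mean_a = unname(means[a]),
                   mean_b = unname(means[b]), diff = unname(means[a] - means[b]),
                   t = unname(tval), df = unname(edf),
                   p = unname(2 * pt(-abs(tval), edf)))
  })
  attr(cmp, "ordering") <- ordering_string(cmp)
  cmp
}

# Render significant LSD pairs as a compact ordering string. Left and right
# sides group labels that are mutually non-significant; members are listed
# alphabetically within a cluster, statements separated by "; ".
ordering_string <- function(cmp, alpha = 0.05) {
  sig <- cmp[cmp$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return("NA")
  ns_pair <- function(x, y) {
    row <- cmp[(cmp$a == x & cmp$b == y) | (cmp$a == y & cmp$b == x), ]
    nrow(row) == 0 || row$p[1] >= alpha
  }
  means <- setNames(c(cmp$mean_a, cmp$mean_b), c(cmp$a, cmp$b))
  means <- means[!duplicated(names(means))]
  # cluster the left sides per right label
  statements <- list()
  for (b in unique(sig$b)) {
    lefts <- unique(sig$a[sig$b == b])
    lefts <- lefts[order(-means[lefts])]
    clusters <- list()
    for (l in lefts) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        if (all(vapply(clusters[[ci]], ns_pair, logical(1), y = l))) {
          clusters[[ci]] <- c(clusters[[ci]], l)
          placed <- TRUE
          break
        }
      }
      if (!placed) clusters[[length(clusters) + 1L]] <- l
    }
    for (cl in clusters) {
      statements[[length(statements) + 1L]] <- list(left = sort(cl), right = b)
    }
  }
  # merge statements sharing an identical left cluster when their right
  # sides are mutually non-significant (e.g. "PPN > CPu/M1")
  merged <- list()
  for (st in statements) {
    hit <- FALSE
    for (mi in seq_along(merged)) {
      m <- merged[[mi]]
      if (identical(m$left, st$left) &&
          all(vapply(m$right, ns_pair, logical(1), y = st$right))) {
        merged[[mi]]$right <- sort(c(m$right, st$right))
        hit <- TRUE
        break
      }
    }
    if (!hit) merged[[length(merged) + 1L]] <- st
  }
  ord <- order(-vapply(merged, function(m) max(means[m$left]), numeric(1)),
               vapply(merged, function(m) min(means[m$right]), numeric(1)))
  paste(vapply(merged[ord], function(m) {
    paste(paste(m$left, collapse = "/"), ">", paste(m$right, collapse = "/"))
  }, character(1)), collapse = "; ")
}

#' Tidy the per-effect table of a fitted split-plot ANOVA
#'
#' @param x An `lfp_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per effect (band, effect, F, dfs, p values,
#'   partial eta squared).
#' @method tidy lfp_anova
#' @export
tidy.lfp_anova <- function(x, ...) {
  dplyr::mutate(x$effects, band = x$band, .before = 1)
}

#' One-row sphericity and design summary of a fitted split-plot ANOVA
#'
#' @inheritParams tidy.lfp_anova
#' @return One-row tibble: Mauchly W and p, Greenhouse-Geisser epsilon,
#'   whether the correction was applied, and the design dimensions.
#' @method glance lfp_anova
#' @export
glance.lfp_anova <- function(x, ...) {
  tibble::tibble(band = x$band, mauchly_W = x$mauchly_W,
                 mauchly_p = x$mauchly_p, gg_epsilon = x$gg_epsilon,
                 correction_applied = x$correction_applied,
                 n_per_group = x$n_per_group, n_groups = x$n_groups,
                 k = x$k)
}

#' @export
print.lfp_anova <- function(x, ...) {
  cat(sprintf("<lfp_anova>%s split-plot ANOVA: %d x %d subjects, %d within levels\n",
              if (is.na(x$band)) "" else paste0(" [", x$band, "]"),
              x$n_groups, x$n_per_group, x$k))
  print(as.data.frame(x$effects), digits = 4, row.names = FALSE)
  cat(sprintf("Mauchly W = %.4f (p = %.4f), GG epsilon = %.4f, correction %s\n",
              x$mauchly_W, x$mauchly_p, x$gg_epsilon,
              if (x$correction_applied) "applied" else "not applied"))
  cat("LSD (channel):", attr(x$lsd$channel, "ordering"), "\n")
  invisible(x)
}
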