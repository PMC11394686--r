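#' Classify a p value by the study's significance convention
#'
#' `p < 0.05` is significant, `0.05 <= p < 0.1` marginally significant,
#' `p >= 0.1` not significant.
#'
#' @param p Probability in `[0, 1]`. Vectorised.
#' @return Character vector in `{"significant", "marginal", "ns"}`.
#' @export
classify_significance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  dplyr::case_when(p < 0.05 ~ "significant",
                   p < 0.1 ~ "marginal",
                   TRUE ~ "ns")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning a tidy one-row
#' tibble. Errors on constant samples (W undefined).
#'
#' @param x Numeric sample, `3 <= n <= 5000`.
#' @return Tibble with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) abort("Shapiro-Wilk needs at least 3 observations.")
  if (sd(x) == 0) abort("Shapiro-Wilk is undefined for a constant sample.")
  res <- shapiro.test(x)
  tibble::tibble(W = unname(res$statistic), p = res$p.value)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations from each group's centre; the
#' original formulation centres on the group mean (default), the
#' Brown-Forsythe variant on the median. Groups with identical spread give a
#' statistic of 0.
#'
#' @param x,y Two numeric samples, or pass `groups` instead.
#' @param groups Optional list of numeric samples (two or more).
#' @param center `"mean"` (classical) or `"median"`.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p`.
#' @export
levene_test <- function(x = NULL, y = NULL, groups = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.null(groups)) groups <- list(x, y)
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 2)) {
    abort("Levene's test needs >= 2 groups with >= 2 observations each.")
  }
  z <- unlist(lapply(groups, function(v) {
    abs(v - if (center == "mean") mean(v) else median(v))
  }))
  gf <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (sd(z) == 0) {
    return(tibble::tibble(statistic = 0, df1 = length(groups) - 1L,
                          df2 = length(z) - length(groups), p = 1))
  }
  a <- anova(lm(z ~ gf))
  tibble::tibble(statistic = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p = a$`Pr(>F)`[1])
}

#' Independent two-sample t test (pooled variance)
#'
#' Classical Student t with pooled variance, `df = n1 + n2 - 2`, matching the
#' reporting convention of the analysis (not Welch).
#'
#' @param x,y Numeric samples.
#' @return Tibble with `statistic` (t), `df`, `p`.
#' @export
independent_t <- function(x, y) {
  res <- t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The reported `U` is the
#' number of (x, y) pairs with x ahead of y; `Z` is the normal approximation
#' with continuity and tie correction (the conventional reporting statistic).
#' The p value is exact (full enumeration of rank assignments) when both
#' samples are small and untied, and the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact_max Use the exact distribution when `n1 + n2` does not exceed
#'   this and there are no ties.
#' @return Tibble with `U`, `Z`, `p`, `exact` (logical).
#' @export
mann_whitney <- function(x, y, exact_max = 50) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) abort("both samples must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  N <- nx + ny
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  mu <- nx * ny / 2
  sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  Z <- if (sigma == 0) 0 else (U - mu - sign(U - mu) * 0.5) / sigma
  has_ties <- any(ties > 1)
  use_exact <- !has_ties && N <= exact_max
  p <- if (use_exact) {
    suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
  } else if (sigma == 0) 1 else min(1, 2 * pnorm(-abs(Z)))
  tibble::tibble(U = U, Z = Z, p = p, exact = use_exact)
}

#' Assumption-driven two-sample test cascade
#'
#' Implements the endpoint-testing policy: (1) check normality per group
#' (Shapiro-Wilk) and homogeneity of variance (Levene, mean-centred) at
#' `alpha`; (2) if violated, retest after a log transform (requires strictly
#' positive data) and then a square-root transform (requires non-negative
#' data); (3) if some transform satisfies both checks, run the pooled-variance
#' independent t test on that scale, otherwise fall back to the Mann-Whitney
#' U test on the original data. The cascade always returns a result.
#'
#' @param x,y Numeric samples (each `n >= 3`).
#' @param endpoint Optional endpoint label carried into the result.
#' @param alpha Assumption-check level.
#' @return One-row tibble: `endpoint`, `test_used` (`"t"`/`"mann_whitney"`),
#'   `transform_used` (`"none"`/`"log"`/`"sqrt"`), `statistic` (t or Z), `p`,
#'   `significance_class`.
#' @export
select_and_run_test <- function(x, y, endpoint = NA_character_, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("each sample needs at least 3 observations.")
  }
  assumptions_ok <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(FALSE)  # SW undefined: treat as violated
    shapiro_wilk(a)$p >= alpha && shapiro_wilk(b)$p >= alpha &&
      levene_test(a, b)$p >= alpha
  }
  transforms <- list(
    none = identity,
    log = function(v) if (min(c(x, y)) > 0) log(v) else NULL,
    sqrt = function(v) if (min(c(x, y)) >= 0) sqrt(v) else NULL)
  for (tr in names(transforms)) {
    tx <- transforms[[tr]](x)
    if (is.null(tx)) next
    ty <- transforms[[tr]](y)
    if (assumptions_ok(tx, ty)) {
      res <- independent_t(tx, ty)
      return(tibble::tibble(endpoint = endpoint, test_used = "t",
                            transform_used = tr, statistic = res$statistic,
                            p = res$p,
                            significance_class = classify_significance(res$p)))
    }
  }
  res <- mann_whitney(x, y)
  tibble::tibble(endpoint = endpoint, test_used = "mann_whitney",
                 transform_used = "none", statistic = res$Z, p = res$p,
                 significance_class = classify_significance(res$p))
}
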