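# Shared fixtures: small synthetic specs and independent statistical oracles.

# A fast, small synthetic study for integration tests.
quick_spec <- function(n_per_group = 3, state_duration_s = 12, seed = 1L, ...) {
  synthetic_spec(n_per_group = n_per_group, state_duration_s = state_duration_s,
                 seed = seed, ...)
}

# A random balanced split-plot design table.
random_design <- function(n_per_group, k, seed) {
  simulate_diff_table(
    n_per_group = n_per_group, regions = paste0("R", seq_len(k)),
    group_shift = stats::rnorm(1),
    region_shifts = stats::setNames(stats::rnorm(k), paste0("R", seq_len(k))),
    subject_sd = stats::runif(1, 0.3, 2), resid_sd = stats::runif(1, 0.3, 2),
    seed = seed)
}

# Independent split-plot oracle via stats::aov error strata.
oracle_split_plot <- function(d) {
  dd <- data.frame(y = d$diff, g = factor(d$group), r = factor(d$region),
                   s = factor(d$subject_id))
  a <- summary(stats::aov(y ~ g * r + Error(s), data = dd))
  between <- a[["Error: s"]][[1]]
  within <- a[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  list(
    F = c(group = between["g", "F value"],
          channel = within["r", "F value"],
          interaction = within["g:r", "F value"]),
    df = c(group1 = between["g", "Df"], group2 = between["Residuals", "Df"],
           within1 = within["r", "Df"], within2 = within["Residuals", "Df"]),
    ms_within_resid = within["Residuals", "Mean Sq"])
}

# Greenhouse-Geisser epsilon by the orthonormal-contrast formula
# (independent of the doubly-centred eigendecomposition in the package).
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  H <- stats::contr.helmert(k)
  C <- t(sweep(H, 2, sqrt(colSums(H^2)), "/"))
  E <- C %*% S %*% t(C)
  sum(diag(E))^2 / ((k - 1) * sum(E^2))
}

# Pooled within-group covariance of a diff table in wide form.
pooled_within_cov <- function(d) {
  w <- tidyr::pivot_wider(d, names_from = "region", values_from = "diff")
  Y <- as.matrix(w[, setdiff(names(w), c("subject_id", "group"))])
  gs <- split(seq_len(nrow(Y)), w$group)
  resid <- do.call(rbind, lapply(gs, function(i) {
    sweep(Y[i, , drop = FALSE], 2, colMeans(Y[i, , drop = FALSE]))
  }))
  crossprod(resid) / (nrow(Y) - length(gs))
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a
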