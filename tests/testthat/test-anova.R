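# Frozen reference rows of the published ANOVA report: F, dfs, printed
# partial eta^2, and (for the between-subject rows) the printed p value.
table1_rows <- tibble::tribble(
  ~band,   ~factor,   ~F,     ~df1, ~df2, ~eta,   ~p,
  "delta", "group",    4.516, 1,   18,   0.201,  0.048,
  "delta", "channel",  1.608, 4,   72,   0.082,  NA,
  "delta", "gxc",      0.635, 4,   72,   0.034,  NA,
  "theta", "group",    4.191, 1,   18,   0.189,  0.056,
  "theta", "channel",  3.016, 4,   72,   0.144,  NA,
  "theta", "gxc",      0.420, 4,   72,   0.023,  NA,
  "alpha", "group",    3.999, 1,   18,   0.182,  0.061,
  "alpha", "channel",  3.457, 4,   72,   0.161,  NA,
  "alpha", "gxc",      0.095, 4,   72,   0.005,  NA,
  "beta",  "group",    4.425, 1,   18,   0.197,  0.050,
  "beta",  "channel",  6.491, 4,   72,   0.265,  NA,
  "beta",  "gxc",      0.708, 4,   72,   0.038,  NA,
  "gamma", "group",    5.804, 1,   18,   0.244,  0.027,
  "gamma", "channel",  3.616, 4,   72,   0.167,  NA,
  "gamma", "gxc",      0.432, 4,   72,   0.023,  NA)

test_that("partial eta squared reproduces every published value at 3 dp", {
  eta <- partial_eta_squared(table1_rows$F, table1_rows$df1, table1_rows$df2)
  expect_equal(round(eta, 3), table1_rows$eta)
  expect_equal(partial_eta_squared(0, 3, 10), 0)
  expect_error(partial_eta_squared(-1, 1, 10), "non-negative")
  expect_error(partial_eta_squared(1, 0, 10), "freedom")
})

test_that("F tail probabilities reproduce the published group p values at 3 dp", {
  grp <- table1_rows[table1_rows$factor == "group", ]
  expect_equal(round(f_pvalue(grp$F, grp$df1, grp$df2), 3), grp$p)
  expect_equal(f_pvalue(0, 1, 18), 1)
  expect_error(f_pvalue(1, 1, 0), "freedom")
})

test_that("Greenhouse-Geisser epsilon has its analytic values and bounds", {
  expect_equal(gg_epsilon(diag(2)), 1)
  # compound symmetry: sphericity holds exactly
  cs <- matrix(0.4, 5, 5) + diag(0.6, 5)
  expect_equal(gg_epsilon(cs), 1)
  # maximally non-spherical: rank-1 doubly-centred covariance
  v <- c(2, -0.5, -0.5, -0.5, -0.5)
  expect_equal(gg_epsilon(tcrossprod(v)), 1 / 4)
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")

  # random PSD matrices: matches the orthonormal-contrast formula and bounds
  set.seed(16)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 0.1
    e <- gg_epsilon(S)
    expect_equal(e, oracle_gg_epsilon(S), tolerance = 1e-10)
    expect_gte(e, 1 / (k - 1) - 1e-12)
    expect_lte(e, 1 + 1e-12)
  }
})

test_that("mixed_anova matches the aov error-strata oracle", {
  set.seed(17)
  for (i in 1:30) {
    d <- random_design(n_per_group = sample(2:4, 1), k = sample(3:4, 1),
                       seed = 1000 + i)
    fit <- mixed_anova(d)
    orc <- oracle_split_plot(d)
    expect_equal(unname(fit$effects$F), unname(orc$F), tolerance = 1e-8)
    expect_equal(unname(fit$effects$df1), unname(c(orc$df["group1"],
                                                   orc$df["within1"],
                                                   orc$df["within1"] * orc$df["group1"])))
    # partial eta^2 self-consistency with the stored F and dfs
    expect_equal(fit$effects$partial_eta_sq,
                 partial_eta_squared(fit$effects$F, fit$effects$df1,
                                     fit$effects$df2),
                 tolerance = 1e-9)
  }
})

test_that("reference design yields the published degrees of freedom", {
  d <- simulate_diff_table(n_per_group = 10, seed = 18)
  fit <- mixed_anova(d, band = "gamma")
  expect_equal(fit$effects$df1, c(1, 4, 4))
  expect_equal(fit$effects$df2, c(18, 72, 72))
  expect_identical(tidy(fit)$band, rep("gamma", 3))
  g <- glance(fit)
  expect_equal(g$k, 5)
  expect_true(g$mauchly_p >= 0 && g$mauchly_p <= 1)
})

test_that("Mauchly test agrees with the mlm route on W", {
  d <- simulate_diff_table(n_per_group = 8, region_shifts = c(M1 = 2), seed = 19)
  fit <- mixed_anova(d)
  w <- tidyr::pivot_wider(d, names_from = "region", values_from = "diff")
  Y <- as.matrix(w[, c("M1", "CPu", "STN", "SNc", "PPN")])
  ml <- stats::lm(Y ~ factor(w$group))
  mt <- stats::mauchly.test(ml, X = ~1)
  expect_equal(fit$mauchly_W, unname(mt$statistic), tolerance = 1e-10)
  expect_equal(fit$mauchly_p, mt$p.value, tolerance = 0.01)
  # and GG epsilon agrees with the pooled-covariance contrast oracle
  expect_equal(fit$gg_epsilon, oracle_gg_epsilon(pooled_within_cov(d)),
               tolerance = 1e-10)
})

test_that("the GG correction never lowers p when F >= 1", {
  set.seed(20)
  for (i in 1:20) {
    d <- random_design(n_per_group = 4, k = 4, seed = 2000 + i)
    fit <- mixed_anova(d)
    eff <- fit$effects[fit$effects$effect != "group", ]
    for (j in seq_len(nrow(eff))) {
      if (eff$F[j] >= 1) expect_gte(eff$p_reported[j], eff$p_uncorrected[j] - 1e-12)
    }
  }
  # k = 2 has a single contrast: epsilon is exactly 1, no correction possible
  d2 <- simulate_diff_table(n_per_group = 5, regions = c("M1", "STN"), seed = 3)
  fit2 <- mixed_anova(d2)
  expect_false(fit2$correction_applied)
  expect_equal(fit2$gg_epsilon, 1)
})

test_that("degenerate designs raise explicit errors", {
  d <- simulate_diff_table(n_per_group = 3, seed = 21)
  expect_error(mixed_anova(d[-1, ]), "incomplete")
  d2 <- d
  d2$subject_id[d2$subject_id == "sham01"] <- "sham02"
  expect_error(mixed_anova(d2), "unbalanced|incomplete|one value")
  d3 <- simulate_diff_table(n_per_group = 3, seed = 22)
  d3 <- d3[d3$subject_id != "sham01", ]
  expect_error(mixed_anova(d3), "unbalanced")
})

test_that("LSD post hoc equals pooled-error pairwise t tests", {
  d <- simulate_diff_table(n_per_group = 4, region_shifts = c(M1 = -3),
                           seed = 23)
  fit <- mixed_anova(d)
  cmp <- lsd_posthoc(fit, "channel")
  orc <- oracle_split_plot(d)
  means <- tapply(d$diff, d$region, mean)
  for (i in seq_len(nrow(cmp))) {
    se <- sqrt(2 * orc$ms_within_resid / 8)
    tval <- (means[cmp$a[i]] - means[cmp$b[i]]) / se
    p <- 2 * stats::pt(-abs(tval), orc$df["within2"])
    expect_equal(cmp$p[i], unname(p), tolerance = 1e-9)
  }
})

test_that("LSD ordering strings render the expected patterns", {
  # all cell means equal in expectation, no signal: empty ordering
  d0 <- simulate_diff_table(n_per_group = 5, subject_sd = 1, resid_sd = 1,
                            seed = 24)
  fit0 <- mixed_anova(d0)
  expect_identical(attr(fit0$lsd$channel, "ordering"), "NA")

  # one region shifted +10 SD dominates every other
  d1 <- simulate_diff_table(n_per_group = 5, region_shifts = c(STN = 10),
                            resid_sd = 1, subject_sd = 0.5, seed = 25)
  fit1 <- mixed_anova(d1)
  expect_match(attr(fit1$lsd$channel, "ordering"), "^STN > ")
  expect_error(lsd_posthoc(fit1, "interaction"))

  # group ordering at 2 levels reflects the shift direction
  d2 <- simulate_diff_table(n_per_group = 6, group_shift = 8, resid_sd = 1,
                            subject_sd = 0.5, seed = 26)
  fit2 <- mixed_anova(d2)
  expect_match(attr(fit2$lsd$group, "ordering"), "lesion > sham")
})
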