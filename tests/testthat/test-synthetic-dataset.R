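test_that("dataset generation matches the study design and is deterministic", {
  spec <- quick_spec(n_per_group = 2, seed = 5)
  ds <- generate_lfp_dataset(spec)
  expect_length(ds$recordings, 4)
  # ground truth aligns with the future band-power table: subjects x regions
  # x states x bands
  expect_equal(nrow(ds$ground_truth), 4 * 5 * 2 * 5)
  rec <- ds$recordings[[1]]
  expect_s3_class(rec, "lfp_recording")
  expect_identical(colnames(rec$signals), c("M1", "CPu", "STN", "SNc", "PPN"))
  expect_equal(nrow(rec$signals), 2 * 12 * 1000)
  expect_identical(rec$states$state, c("rest", "walk"))
  ds2 <- generate_lfp_dataset(quick_spec(n_per_group = 2, seed = 5))
  expect_identical(ds$recordings[[3]]$signals, ds2$recordings[[3]]$signals)
  expect_identical(ds$ground_truth, ds2$ground_truth)
})

test_that("band effects referencing unknown regions or bands are rejected", {
  bad <- demo_band_effects()
  bad$region[1] <- "GPi"
  expect_error(synthetic_spec(band_effects = bad), "unknown region")
  bad2 <- demo_band_effects()
  bad2$band[1] <- "mu"
  expect_error(synthetic_spec(band_effects = bad2), "unknown")
  expect_error(synthetic_spec(n_per_group = 1), "n_per_group")
  expect_error(synthetic_spec(regions = c("M1", "M1")), "distinct")
})

test_that("null generator shows no state effect in band powers", {
  spec <- quick_spec(n_per_group = 4, band_effects = NULL, seed = 11)
  tabs <- build_band_power_table(generate_lfp_dataset(spec), keep_spectra = FALSE)
  # per band, paired comparison of walk vs rest powers across all
  # subject x region cells: no injected effect, so no signal
  for (b in c("theta", "beta", "gamma")) {
    bp <- tabs$band_power[tabs$band_power$band == b, ]
    wide <- tidyr::pivot_wider(bp, names_from = "state", values_from = "power")
    p <- stats::t.test(wide$walk, wide$rest, paired = TRUE)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("injected oscillation power is recovered in the difference statistic", {
  # lesion-walk gamma at 2x sham-walk amplitude: recovered gamma walk-rest
  # difference larger in the lesion group
  fx <- demo_band_effects()
  fx <- fx[fx$band == "gamma", ]
  fx$rms[fx$group == "sham"] <- 1
  fx$rms[fx$group == "lesion"] <- 2
  spec <- quick_spec(n_per_group = 4, band_effects = fx, subject_sd = 0.05,
                     seed = 21)
  ds <- generate_lfp_dataset(spec)
  tabs <- build_band_power_table(ds, keep_spectra = FALSE)
  g <- tabs$diff[tabs$diff$band == "gamma", ]
  m_lesion <- mean(g$diff[g$group == "lesion"])
  m_sham <- mean(g$diff[g$group == "sham"])
  expect_gt(m_lesion, m_sham)
  # injected power is rms^2 * multiplier^2: lesion ~4, sham ~1
  expect_equal(m_lesion, 4, tolerance = 0.35)
  expect_equal(m_sham, 1, tolerance = 0.35)
})

test_that("behavior generator honours the effect profile and seed", {
  null_beh <- generate_behavior_dataset(10, effect_profile = list(), seed = 3)
  s <- summarize_endpoints(null_beh$endpoints, null_beh$cylinder, null_beh$gait)
  expect_true(all(c("rotarod_latency", "cylinder_asymmetry",
                    "gait_diagonal_pct") %in% s$endpoint))
  # no injected effect: endpoint tests reject at about the nominal rate and
  # the standardised group deviations are centred on zero across seeds
  stats <- lapply(1:10, function(sd0) {
    b <- generate_behavior_dataset(10, effect_profile = list(), seed = 500 + sd0)
    si <- summarize_endpoints(b$endpoints, b$cylinder, b$gait)
    list(p = si$p[!is.na(si$p)],
         dev = (si$mean_lesion - si$mean_sham) /
           sqrt(si$sd_sham^2 / si$n_sham + si$sd_lesion^2 / si$n_lesion))
  })
  pvals <- unlist(lapply(stats, `[[`, "p"))
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_lt(abs(mean(unlist(lapply(stats, `[[`, "dev")))), 0.35)

  # lesion bias towards the injection side: mean asymmetry > 0 over many
  # subjects (direct mean, >= 200 simulated lesion subjects)
  big <- generate_behavior_dataset(200, seed = 4)
  asym <- asymmetry_ratio(big$cylinder$touches_injection,
                          big$cylinder$touches_non_injection,
                          big$cylinder$touches_both)
  expect_gt(mean(asym[big$cylinder$group == "lesion"]), 20)
  expect_lt(abs(mean(asym[big$cylinder$group == "sham"])), 5)

  again <- generate_behavior_dataset(200, seed = 4)
  expect_identical(big$endpoints, again$endpoints)
  expect_identical(big$cylinder, again$cylinder)
  expect_error(generate_behavior_dataset(1), "n_per_group")
})

test_that("cell-count generator reproduces the prescribed density loss", {
  # zero loss: lesion and sham densities equal in expectation
  eq <- generate_cell_counts(50, loss_injection = 0, loss_noninjection = 0,
                             seed = 6)
  d <- dplyr::summarise(
    dplyr::group_by(eq, .data$group, .data$subject_id, .data$side),
    density = mean(.data$th_count / .data$area), .groups = "drop")
  ratio <- mean(d$density[d$group == "lesion"]) / mean(d$density[d$group == "sham"])
  expect_equal(ratio, 1, tolerance = 0.05)

  # three slices per subject per side
  cc <- generate_cell_counts(4, n_slices = 3, seed = 7)
  counts <- table(cc$subject_id, cc$side)
  expect_true(all(counts == 3))

  # Monte-Carlo percent-loss recovery at large n and small noise
  mc <- generate_cell_counts(200, loss_injection = 0.8952, seed = 8,
                             subject_cv = 0.02)
  dm <- dplyr::summarise(
    dplyr::group_by(mc[mc$side == "injection", ], .data$group, .data$subject_id),
    density = mean(.data$th_count / .data$area), .groups = "drop")
  loss <- percent_loss(mean(dm$density[dm$group == "lesion"]),
                       mean(dm$density[dm$group == "sham"]))
  expect_equal(loss, 89.52, tolerance = 1)
})

test_that("simulated diff tables have the requested structure", {
  d <- simulate_diff_table(n_per_group = 4, group_shift = 3,
                           region_shifts = c(M1 = -1), seed = 10)
  expect_equal(nrow(d), 2 * 4 * 5)
  expect_identical(d, simulate_diff_table(n_per_group = 4, group_shift = 3,
                                          region_shifts = c(M1 = -1), seed = 10))
})
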