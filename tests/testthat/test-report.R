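test_that("the rendered ANOVA table mirrors the report layout", {
  fits <- lapply(c("delta", "theta", "alpha", "beta", "gamma"), function(b) {
    mixed_anova(simulate_diff_table(n_per_group = 10, seed = 40), band = b)
  })
  tab <- render_table1(fits)
  expect_equal(nrow(tab), 15)  # 5 bands x 3 factors
  expect_identical(names(tab),
                   c("Band", "Factor", "F", "p-Value", "Partial eta^2", "LSD"))
  expect_identical(tab$Factor[1:3],
                   c("group(1,18)", "channel(4,72)", "group*channel(4,72)"))
  # null data: no LSD entries
  expect_true(all(tab$LSD[tab$`p-Value` >= "0.100"] == "NA"))

  # a fit with a strong group effect renders the direction
  dstrong <- simulate_diff_table(n_per_group = 10, group_shift = 5,
                                 subject_sd = 0.5, resid_sd = 0.5, seed = 41)
  tab2 <- render_table1(list(mixed_anova(dstrong, band = "gamma")))
  expect_identical(tab2$LSD[1], "Lesion > Sham")
})

test_that("report rounding is 3 dp, half away from zero", {
  f <- mixed_anova(simulate_diff_table(n_per_group = 3, seed = 42), band = "x")
  tab <- render_table1(list(f))
  expect_match(tab$F, "^\\d+\\.\\d{3}$")
  # the published delta-row eta: F = 4.516 at (1, 18) renders as 0.201
  eta <- partial_eta_squared(4.516, 1, 18)
  expect_identical(lfpband:::format_3dp(eta), "0.201")
  expect_identical(lfpband:::format_3dp(0.0005), "0.001")
  expect_identical(lfpband:::format_3dp(-0.0005), "-0.001")
  expect_identical(lfpband:::format_3dp(0.2015), "0.202")
})

test_that("datasets round-trip through the delimited + sidecar format", {
  ds <- generate_lfp_dataset(quick_spec(n_per_group = 2, state_duration_s = 11,
                                        seed = 43))
  dir <- withr::local_tempdir()
  write_lfp_dataset(ds, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 4)
  back <- read_lfp_dataset(dir)
  expect_length(back$recordings, 4)
  r0 <- ds$recordings[["sham01"]]
  r1 <- back$recordings[["sham01"]]
  expect_identical(r1$group, "sham")
  expect_equal(r1$fs, r0$fs)
  expect_equal(r1$signals, r0$signals, tolerance = 1e-12)
  expect_equal(r1$states$end_s, r0$states$end_s)
  expect_error(read_lfp_dataset(withr::local_tempdir()), "no recording")
})

test_that("run_full_analysis produces a complete, reproducible bundle", {
  cfg <- run_config(spec = quick_spec(n_per_group = 3, seed = 44), seed = 44)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- run_full_analysis(cfg, out_dir = d1)
  res2 <- run_full_analysis(cfg, out_dir = d2)
  expect_equal(nrow(res1$table1), 15)
  expect_equal(nrow(res1$band_power), 6 * 5 * 2 * 5)
  expect_length(res1$anova, 5)
  expect_s3_class(res1$anova$gamma, "lfp_anova")
  expect_true(!is.null(res1$endpoints) && !is.null(res1$histology))
  # identical seed and config: byte-identical outputs
  for (f in c("band_power.csv", "diff.csv", "anova_table.csv",
              "endpoints.csv", "histology.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # manifest records the processing decisions
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 44)
  expect_match(man$decisions$artifact, "6")
  expect_match(man$decisions$estimator, "Welch")
  expect_match(man$decisions$epsilon_policy, "Mauchly")
})

test_that("YAML configurations load with overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "synthetic:", "  n_per_group: 2",
               "  state_duration_s: 11", "artifact_k: 5"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$spec$n_per_group, 2L)
  expect_equal(cfg$artifact_k, 5)
  cfg2 <- read_run_config(path, seed = 77)
  expect_equal(cfg2$seed, 77L)
  # the bundled demonstration configuration parses to the reference design
  demo_path <- system.file("extdata", "demo_config.yaml", package = "lfpband")
  expect_true(nzchar(demo_path))
  demo <- read_run_config(demo_path)
  expect_equal(demo$spec$n_per_group, 10L)
  expect_equal(demo$spec$state_duration_s, 300)
})

test_that("plot builders return ggplot objects", {
  ds <- generate_lfp_dataset(quick_spec(n_per_group = 2, seed = 45))
  tabs <- build_band_power_table(ds)
  expect_s3_class(ggplot2::autoplot(tabs$spectra), "ggplot")
  expect_s3_class(plot_state_difference(tabs$diff), "ggplot")
  fit <- mixed_anova(tabs$diff[tabs$diff$band == "gamma", ], band = "gamma")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
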