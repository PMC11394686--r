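test_that("band-pass filter passes in-band and rejects out-of-band content", {
  fs <- 1000
  t <- (0:19999) / fs
  s40 <- sin(2 * pi * 40 * t + 0.7)
  expect_gte(sd(bandpass_filter(s40, fs)) / sd(s40), 0.95)
  s200 <- sin(2 * pi * 200 * t + 0.7)
  expect_lte(sd(bandpass_filter(s200, fs)) / sd(s200), 0.1)
  # one octave below the low corner
  s025 <- sin(2 * pi * 0.25 * t + 0.7)
  expect_lte(sd(bandpass_filter(s025, fs)) / sd(s025), 0.1)
  # DC removal
  out <- bandpass_filter(s40 + 10, fs)
  expect_lt(abs(mean(out)), 0.1)
  expect_error(bandpass_filter(s40, fs, low = 90, high = 80), "corner")
  expect_error(bandpass_filter(s40, fs, low = 0.5, high = 600), "corner")
  expect_error(bandpass_filter(rnorm(10), fs), "too short")
})

test_that("filtering never increases energy for mixed-band content", {
  set.seed(8)
  for (i in 1:5) {
    x <- generate_pink_noise(20000, 1000, 1, 10) +
      sin(2 * pi * 200 * (0:19999) / 1000) * runif(1, 0, 5)
    expect_lte(var(bandpass_filter(x, 1000)), var(x) * (1 + 1e-6))
  }
})

test_that("artifact-free segment search returns the earliest clean window", {
  fs <- 1000
  set.seed(12)
  clean <- generate_pink_noise(28000, fs, 1, 10)
  rec <- lfp_recording("s1", "sham", fs,
                       matrix(clean, ncol = 1, dimnames = list(NULL, "M1")),
                       tibble::tibble(state = c("rest", "walk"),
                                      start_s = c(0, 14), end_s = c(14, 28)))
  win <- find_artifact_free_segment(rec, "M1", "rest", 10)
  expect_equal(unname(win), c(0, 10))
  win_w <- find_artifact_free_segment(rec, "M1", "walk", 10)
  expect_equal(unname(win_w), c(14, 24))

  # spike at t = 3 s of the rest block: the window must start after it
  spiky <- clean
  spiky[3000] <- 1000
  rec2 <- rec
  rec2$signals[, 1] <- spiky
  win2 <- find_artifact_free_segment(rec2, "M1", "rest", 10)
  expect_gt(win2["start_s"], 3 - 1e-9)
  # brute-force oracle: earliest start with no flagged sample inside
  x <- spiky[1:14000]
  bad <- abs(x - median(x)) > 6 * mad(x)
  ok <- which(vapply(seq_len(4001), function(i) !any(bad[i:(i + 9999)]),
                     logical(1)))[1]
  expect_equal(unname(win2["start_s"]), (ok - 1) / fs)

  # saturated signal: every sample exceeds an absolute limit
  rec3 <- rec
  rec3$signals[, 1] <- rep(c(-500, 500), 14000)
  expect_error(
    find_artifact_free_segment(rec3, "M1", "rest", 10,
                               criterion = artifact_criterion("absolute",
                                                              abs_limit = 400)),
    "no artifact-free segment.*s1.*M1.*rest")
  # spikes denser than the window under the amplitude rule: no clean window
  rec4 <- rec
  rec4$signals[seq(500, 14000, by = 4000), 1] <- 2000
  expect_error(find_artifact_free_segment(rec4, "M1", "rest", 10),
               "no artifact-free segment")

  # criterion "none" accepts the first window regardless
  win4 <- find_artifact_free_segment(rec3, "M1", "rest", 10,
                                     criterion = artifact_criterion("none"))
  expect_equal(unname(win4), c(0, 10))
  expect_error(find_artifact_free_segment(rec, "M1", "rest", 20),
               "shorter")
})

test_that("epoching partitions segments exactly", {
  x <- rnorm(10000)
  ep <- epoch_segment(x, 1000, 1)
  expect_equal(dim(ep), c(10, 1000))
  expect_identical(as.numeric(t(ep)), x)

  expect_warning(ep2 <- epoch_segment(rnorm(10500), 1000, 1), "partial epoch")
  expect_equal(nrow(ep2), 10)
  expect_error(epoch_segment(rnorm(500), 1000, 1), "shorter than one epoch")
})

test_that("recording and epoch-set constructors validate their invariants", {
  sig <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("M1", "CPu")))
  st <- tibble::tibble(state = c("rest", "walk"), start_s = c(0, 0.5),
                       end_s = c(0.5, 1))
  rec <- lfp_recording("a", "sham", 1000, sig, st)
  expect_s3_class(rec, "lfp_recording")
  st_bad <- tibble::tibble(state = c("rest", "walk"), start_s = c(0, 0.3),
                           end_s = c(0.5, 1))
  expect_error(lfp_recording("a", "sham", 1000, sig, st_bad), "overlap")
  expect_error(lfp_recording("a", "ctrl", 1000, sig, st), "group")
  expect_error(epoch_set(matrix(0, 2, 500), fs = 1000, epoch_length_s = 1),
               "inconsistent")
})
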