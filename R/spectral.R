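#' Welch power spectral density of an epoch set
#'
#' Averages Hann-windowed periodograms of the (already non-overlapping)
#' epochs — Welch's estimator with the epoching defining the segmentation.
#' One-sided density normalisation: `sum(psd) * df` equals the mean windowed
#' epoch variance, so a unit-variance white signal has density `2/fs` and a
#' sinusoid of amplitude A integrates to `A^2/2` around its peak. Frequency
#' resolution is `1/epoch_length_s`.
#'
#' @param epochs An [epoch_set()], or a plain matrix (one epoch per row) if
#'   `fs` is given.
#' @param fs Sampling rate, required when `epochs` is a bare matrix.
#' @return Object of class `power_spectrum`: list with `freqs` (Hz), `psd`
#'   (uV^2/Hz), `n_epochs`, and the epoch-set metadata.
#' @export
compute_psd <- function(epochs, fs = NULL) {
  if (inherits(epochs, "epoch_set")) {
    meta <- epochs[c("subject_id", "group", "region", "state")]
    fs <- epochs$fs
    ep <- epochs$epochs
  } else {
    if (is.null(fs)) abort("`fs` is required when `epochs` is a matrix.")
    meta <- list(subject_id = NA, group = NA, region = NA, state = NA)
    ep <- epochs
  }
  if (!is.matrix(ep) || nrow(ep) < 1) abort("empty epoch set.")
  n <- ncol(ep)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))  # periodic Hann
  X <- mvfft(t(ep) * w)
  half <- seq_len(n %/% 2 + 1L)
  pxx <- Mod(X[half, , drop = FALSE])^2 / (fs * sum(w^2))
  scale <- rep(2, length(half))
  scale[1] <- 1
  if (n %% 2 == 0) scale[length(half)] <- 1
  psd <- rowMeans(pxx) * scale
  structure(c(list(freqs = (half - 1L) * fs / n, psd = psd,
                   n_epochs = nrow(ep)), meta),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s/%s/%s/%s: %d bins (0-%g Hz), %d epochs\n",
              x$subject_id, x$group, x$region, x$state, length(x$freqs),
              max(x$freqs), x$n_epochs))
  invisible(x)
}

#' @method as_tibble power_spectrum
#' @export
as_tibble.power_spectrum <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, group = x$group, region = x$region,
                 state = x$state, freq = x$freqs, psd = x$psd)
}

#' Integrate band power from a spectrum
#'
#' Rectangle-rule integral of the density over `low <= f < high` (half-open,
#' so adjacent bands share no bin). Errors when the band extends beyond the
#' spectral grid.
#'
#' @param spectrum A `power_spectrum`.
#' @param low,high Band edges in Hz, or pass a one-row band definition via
#'   `band`.
#' @param band Optional list/one-row data frame with `low` and `high`.
#' @return Band power in uV^2.
#' @export
band_power <- function(spectrum, low = NULL, high = NULL, band = NULL) {
  if (!is.null(band)) {
    low <- band$low
    high <- band$high
  }
  if (is.null(low) || is.null(high) || low >= high) {
    abort("need band edges with low < high.")
  }
  df <- spectrum$freqs[2] - spectrum$freqs[1]
  if (low < min(spectrum$freqs) - 1e-9 || high > max(spectrum$freqs) + df + 1e-9) {
    abort(sprintf("band [%g, %g) outside the spectral grid (0-%g Hz).",
                  low, high, max(spectrum$freqs)))
  }
  sel <- spectrum$freqs >= low - 1e-9 & spectrum$freqs < high - 1e-9
  sum(spectrum$psd[sel]) * df
}

#' Walking-minus-resting difference table
#'
#' Pairs the rest and walk rows of a band-power table per
#' subject x region x band and returns the per-cell difference
#' `walk - rest` — the movement-related transient-change statistic the
#' split-plot ANOVA analyses.
#'
#' @param band_power_table Tibble with columns `subject_id`, `group`,
#'   `region`, `state`, `band`, `power`; exactly one rest and one walk row
#'   per cell.
#' @return Tibble: `subject_id`, `group`, `region`, `band`, `diff` (uV^2).
#' @export
state_difference <- function(band_power_table) {
  req <- c("subject_id", "group", "region", "state", "band", "power")
  if (!all(req %in% names(band_power_table))) {
    abort(paste("band-power table must have columns:", paste(req, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(band_power_table, names_from = "state",
                             values_from = "power")
  if (!all(c("rest", "walk") %in% names(wide)) ||
      anyNA(wide$rest) || anyNA(wide$walk)) {
    missing <- wide[if ("walk" %in% names(wide)) is.na(wide$walk) | is.na(wide$rest %||% NA) else TRUE, ]
    abort(sprintf(
      "state pairing error: %d cell(s) lack a rest or walk partner (first: %s/%s/%s).",
      nrow(missing), missing$subject_id[1], missing$region[1],
      as.character(missing$band[1])))
  }
  dplyr::mutate(
    dplyr::select(wide, dplyr::all_of(c("subject_id", "group", "region", "band"))),
    diff = wide$walk - wide$rest)
}

#' Run the conditioning and spectral stages over a set of recordings
#'
#' For every subject x region: band-pass filter the full trace, locate the
#' earliest artifact-free `segment_s`-second window in each state, cut it
#' into `epoch_length_s`-second epochs, estimate the Welch spectrum, and
#' integrate the five band powers; finally form the walking-minus-resting
#' difference table. The stage order is fixed: filter the whole signal first,
#' then segment, then epoch.
#'
#' @param recordings List of [lfp_recording()] (or an `lfp_dataset`).
#' @param criterion An [artifact_criterion()].
#' @param bands Band definition tibble, see [default_bands()].
#' @param filter_low,filter_high Conditioning passband, Hz.
#' @param segment_s Artifact-free segment length, seconds.
#' @param epoch_length_s Epoch length, seconds.
#' @param keep_spectra Keep the per-subject spectra (needed for plots).
#' @return List with `band_power` (tibble; one row per
#'   subject x region x state x band), `diff` ([state_difference()] of it),
#'   `spectra` (tibble of per-subject spectra, class `lfp_spectra`), and
#'   `group_spectra` (mean +/- SEM per group x region x state x frequency).
#' @export
build_band_power_table <- function(recordings,
                                   criterion = artifact_criterion(),
                                   bands = default_bands(),
                                   filter_low = 0.5, filter_high = 80,
                                   segment_s = 10, epoch_length_s = 1,
                                   keep_spectra = TRUE) {
  if (inherits(recordings, "lfp_dataset")) recordings <- recordings$recordings
  if (!length(recordings)) abort("no recordings supplied.")
  bp_rows <- vector("list", length(recordings))
  sp_rows <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    fs <- rec$fs
    filt <- rec
    filt$signals <- apply(rec$signals, 2, bandpass_filter, fs = fs,
                          low = filter_low, high = filter_high)
    sub_rows <- list()
    for (region in colnames(rec$signals)) {
      for (state in c("rest", "walk")) {
        win <- find_artifact_free_segment(filt, region, state,
                                          duration_s = segment_s,
                                          criterion = criterion)
        i0 <- as.integer(round(win["start_s"] * fs)) + 1L
        seg <- filt$signals[i0:(i0 + as.integer(round(segment_s * fs)) - 1L), region]
        ep <- epoch_set(epoch_segment(seg, fs, epoch_length_s), fs,
                        epoch_length_s, rec$subject_id, rec$group, region, state)
        spec <- compute_psd(ep)
        sub_rows[[paste(region, state)]] <- tibble::tibble(
          subject_id = rec$subject_id, group = rec$group, region = region,
          state = state, band = bands$band,
          power = purrr::map2_dbl(bands$low, bands$high,
                                  function(lo, hi) band_power(spec, lo, hi)))
        if (keep_spectra) sp_rows[[length(sp_rows) + 1L]] <- as_tibble.power_spectrum(spec)
      }
    }
    bp_rows[[ri]] <- dplyr::bind_rows(sub_rows)
  }
  band_power_table <- dplyr::bind_rows(bp_rows)
  spectra <- if (keep_spectra) {
    structure(dplyr::bind_rows(sp_rows), class = c("lfp_spectra", "tbl_df",
                                                   "tbl", "data.frame"))
  } else NULL
  group_spectra <- if (keep_spectra) {
    dplyr::summarise(
      dplyr::group_by(spectra, .data$group, .data$region, .data$state, .data$freq),
      mean_psd = mean(.data$psd),
      sem_psd = sd(.data$psd) / sqrt(dplyr::n()), .groups = "drop")
  } else NULL
  list(band_power = band_power_table,
       diff = state_difference(band_power_table),
       spectra = spectra, group_spectra = group_spectra)
}
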