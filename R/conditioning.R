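#' Artifact criterion for segment selection
#'
#' Defines when a sample is considered an artifact while searching for a
#' clean analysis segment. `amplitude_sd` flags samples deviating from the
#' state-interval median by more than `k` robust standard deviations
#' (median absolute deviation, scaled); `absolute` flags samples exceeding
#' `abs_limit` microvolts in magnitude; `none` accepts everything.
#'
#' @param method One of `"amplitude_sd"`, `"absolute"`, `"none"`.
#' @param k SD multiplier for `amplitude_sd` (must be > 0).
#' @param abs_limit Amplitude limit in microvolts for `absolute`.
#' @return Object of class `artifact_criterion`.
#' @export
artifact_criterion <- function(method = c("amplitude_sd", "absolute", "none"),
                               k = 6, abs_limit = NULL) {
  method <- match.arg(method)
  if (method == "amplitude_sd") stop_if_not_scalar_number(k, "k", min = 1e-12)
  if (method == "absolute") stop_if_not_scalar_number(abs_limit, "abs_limit", min = 0)
  structure(list(method = method, k = k, abs_limit = abs_limit),
            class = "artifact_criterion")
}

#' Zero-phase band-pass filter
#'
#' Conditions an LFP trace with a 4th-order Butterworth band-pass applied
#' with zero phase (forward-backward response). The band-pass is realised as
#' a high-pass/low-pass cascade, which is numerically better conditioned
#' than a single transfer-function band-pass when the lower corner (0.5 Hz
#' at a 1000 Hz rate) sits very close to DC, and the squared-magnitude
#' (two-pass) response is applied in the frequency domain after
#' odd-reflection padding — identical to the steady-state filtfilt response
#' and far cheaper on long offline recordings. Attenuation one octave
#' outside the passband exceeds 20 dB per pass (doubled by the two-pass
#' response); the DC component is removed.
#'
#' @param x Numeric signal, microvolts.
#' @param fs Sampling rate, Hz.
#' @param low,high Passband corners in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order of each cascade stage.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 0.5, high = 80, order = 4) {
  stop_if_not_scalar_number(fs, "fs", min = .Machine$double.eps)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low ||
      high >= fs / 2) {
    abort("corner frequencies must satisfy 0 < low < high < fs/2.")
  }
  if (length(x) <= 3 * 2 * order) {
    abort(sprintf("signal too short to filter: %d samples.", length(x)))
  }
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  # Autoregressive extrapolation padding: the high-pass corner sits close to
  # DC, so the filter transient lasts seconds; reflection padding leaves a
  # curvature kink at the joins whose broadband blip lands exactly on the
  # retained edges. Burg-AR extrapolation continues the local oscillatory
  # structure coherently (exactly, for a sinusoid), so edge windows stay
  # clean.
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(6 * fs / low)))
  xp <- c(rev(ar_extrapolate(rev(x), pad)), x, ar_extrapolate(x, pad))
  np <- length(xp)
  w <- 2 * pi * (0:(np - 1L)) / np
  w <- pmin(w, 2 * pi - w)                   # fold to [0, pi]
  z <- exp(-1i * w)
  horner <- function(coefs) {                # evaluate sum coefs[k+1] z^k
    acc <- rep(coefs[length(coefs)] + 0i, length(z))
    for (k in (length(coefs) - 1L):1L) acc <- acc * z + coefs[k]
    acc
  }
  gain2 <- function(filt) Mod(horner(filt$b) / horner(filt$a))^2

  G <- gain2(hp) * gain2(lp)
  y <- Re(fft(fft(xp) * G, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

# Continue a signal forward by `pad` samples with a Burg AR fit on its tail;
# decays toward the local mean over the AR memory. Falls back to a constant
# continuation for (near-)constant tails.
ar_extrapolate <- function(x, pad, fit_len = 2000, max_order = 30) {
  n <- length(x)
  tail_x <- x[max(1L, n - min(n, fit_len) + 1L):n]
  if (sd(tail_x) < .Machine$double.eps^0.5 * (1 + mean(abs(tail_x)))) {
    return(rep(x[n], pad))
  }
  p <- max(1L, min(max_order, length(tail_x) %/% 4L))
  fit <- tryCatch(stats::ar(tail_x, aic = FALSE, order.max = p, method = "burg"),
                  error = function(e) NULL)
  reflect <- function() 2 * x[n] - x[(n - 1L):(n - pad)]
  if (is.null(fit) || length(fit$ar) == 0) return(reflect())
  m <- fit$x.mean
  init <- rev(x[(n - length(fit$ar) + 1L):n]) - m
  ext <- as.numeric(stats::filter(rep(0, pad), fit$ar, method = "recursive",
                                  init = init)) + m
  # marginally unstable AR fits (slow oscillations) can diverge over a long
  # extrapolation; fall back to odd reflection, which is bounded and smooth
  # exactly where AR fails (slowly varying signals)
  ref_amp <- max(abs(tail_x - m))
  if (!all(is.finite(ext)) || max(abs(ext - m)) > 5 * ref_amp + 1e-12) {
    return(reflect())
  }
  ext
}

# Flag artifact samples under a criterion; x is the state-interval signal.
flag_artifacts <- function(x, criterion) {
  switch(criterion$method,
    none = logical(length(x)),
    absolute = abs(x) > criterion$abs_limit,
    amplitude_sd = {
      centre <- median(x)
      s <- mad(x)
      if (s == 0) abs(x - centre) > 0 else abs(x - centre) > criterion$k * s
    })
}

#' Locate the earliest artifact-free window within a state interval
#'
#' Scans one region's trace inside the annotated state interval and returns
#' the earliest window of `duration_s` seconds in which no sample violates
#' the artifact criterion. With `method = "none"` the first window is
#' returned.
#'
#' @param recording An [lfp_recording()] (filter it first with
#'   [bandpass_filter()] if the pipeline order calls for it).
#' @param region Region (channel) label.
#' @param state `"rest"` or `"walk"`.
#' @param duration_s Window length in seconds (default 10).
#' @param criterion An [artifact_criterion()].
#' @return Named numeric vector `c(start_s, end_s)` in recording time.
#' @export
find_artifact_free_segment <- function(recording, region, state,
                                       duration_s = 10,
                                       criterion = artifact_criterion()) {
  if (!inherits(recording, "lfp_recording")) abort("`recording` must be an lfp_recording.")
  if (!region %in% colnames(recording$signals)) {
    abort(sprintf("unknown region '%s' for subject %s.", region, recording$subject_id))
  }
  st <- recording$states[recording$states$state == state, ]
  if (nrow(st) == 0) abort(sprintf("subject %s has no '%s' interval.",
                                   recording$subject_id, state))
  st <- st[1, ]
  fs <- recording$fs
  if (st$end_s - st$start_s < duration_s) {
    abort(sprintf("state interval shorter than %g s for subject %s.",
                  duration_s, recording$subject_id))
  }
  i0 <- as.integer(round(st$start_s * fs)) + 1L
  i1 <- as.integer(round(st$end_s * fs))
  x <- recording$signals[i0:i1, region]
  w <- as.integer(round(duration_s * fs))
  bad <- flag_artifacts(x, criterion)
  n <- length(x)
  if (n < w) abort("state interval shorter than the requested window.")
  cs <- c(0, cumsum(bad))
  ok <- which(cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)] == 0)
  if (length(ok) == 0) {
    abort(sprintf("no artifact-free segment: subject %s, region %s, state %s.",
                  recording$subject_id, region, state))
  }
  start_s <- st$start_s + (ok[1] - 1L) / fs
  c(start_s = start_s, end_s = start_s + duration_s)
}

#' Cut a segment into fixed-length epochs
#'
#' Splits a signal into consecutive non-overlapping epochs of
#' `epoch_length_s` seconds. A trailing remainder shorter than one epoch is
#' dropped with a warning; concatenating the returned rows reproduces the
#' retained part of the input exactly.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param epoch_length_s Epoch duration in seconds (default 1).
#' @return Matrix with one epoch per row (`n_epochs x fs*epoch_length_s`).
#' @export
epoch_segment <- function(x, fs, epoch_length_s = 1) {
  len <- as.integer(round(fs * epoch_length_s))
  if (len < 1) abort("epoch length must be at least one sample.")
  n_ep <- length(x) %/% len
  if (n_ep < 1) {
    abort(sprintf("segment (%d samples) shorter than one epoch (%d samples).",
                  length(x), len))
  }
  if (length(x) %% len != 0) {
    warn(sprintf("dropping trailing %d samples (partial epoch).",
                 length(x) %% len))
  }
  matrix(x[seq_len(n_ep * len)], nrow = n_ep, ncol = len, byrow = TRUE)
}

#' Construct an epoch set
#'
#' Container for the 1 s epochs of one subject x region x state cell,
#' carrying the metadata the spectral stage needs.
#'
#' @param epochs Matrix, one epoch per row.
#' @param fs Sampling rate, Hz.
#' @param epoch_length_s Epoch duration, seconds.
#' @param subject_id,group,region,state Metadata labels.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, epoch_length_s = 1, subject_id = NA_character_,
                      group = NA_character_, region = NA_character_,
                      state = NA_character_) {
  if (!is.matrix(epochs) || nrow(epochs) < 1) abort("need at least one epoch.")
  if (ncol(epochs) != as.integer(round(fs * epoch_length_s))) {
    abort("epoch length inconsistent with fs and epoch_length_s.")
  }
  structure(list(epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
                 subject_id = subject_id, group = group, region = region,
                 state = state),
            class = "epoch_set")
}
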