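#' Generate a 1/f^beta ("pink") noise signal
#'
#' Random-phase spectral synthesis for the broadband background of a
#' simulated LFP channel: deterministic Fourier amplitudes proportional to
#' f^(-`exponent`/2) with independent uniform phases, inverse-transformed and
#' scaled to the requested RMS. Every realization therefore has exactly the
#' target 1/f^`exponent` spectrum and RMS (the surrogate-data construction),
#' with asymptotically Gaussian marginals; band powers do not inherit the
#' large sampling fluctuation of the lowest-frequency bins, which an
#' empirically renormalised white-noise-shaping synthesis would impose on
#' all bands at once. `exponent = 0` gives white noise, `exponent = 1` the
#' canonical pink background of field potentials.
#'
#' @param n_samples Number of samples to generate (positive integer).
#' @param fs Sampling rate in Hz.
#' @param exponent Spectral slope beta of the 1/f^beta density, in `[0, 2]`.
#' @param rms Target root-mean-square amplitude in microvolts; the returned
#'   signal is rescaled so its empirical RMS matches exactly. `rms = 0`
#'   returns an all-zero signal.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of length `n_samples`, zero mean.
#' @examples
#' x <- generate_pink_noise(2^12, fs = 1000, exponent = 1, rms = 10, seed = 1)
#' sqrt(mean(x^2))
#' @export
generate_pink_noise <- function(n_samples, fs, exponent = 1, rms = 1, seed = NULL) {
  stop_if_not_scalar_number(n_samples, "n_samples", min = 1)
  stop_if_not_scalar_number(fs, "fs", min = .Machine$double.eps)
  stop_if_not_scalar_number(exponent, "exponent", min = 0, max = 2)
  stop_if_not_scalar_number(rms, "rms", min = 0)
  n <- as.integer(n_samples)
  if (rms == 0) return(numeric(n))
  with_local_seed(seed, {
    half <- (n - 1L) %/% 2L                    # bins 1 .. half are free
    f <- (1:half) * fs / n
    amp <- f^(-exponent / 2)
    X <- complex(length.out = n)
    phases <- runif(half, 0, 2 * pi)
    X[2:(half + 1L)] <- amp * exp(1i * phases)
    X[n:(n - half + 1L)] <- Conj(X[2:(half + 1L)])
    if (n %% 2L == 0L) {                       # real Nyquist bin, random sign
      X[n / 2L + 1L] <- (fs / 2)^(-exponent / 2) * sign(runif(1) - 0.5)
    }
    x <- Re(fft(X, inverse = TRUE)) / n
    x <- x - mean(x)
    x * rms / sqrt(mean(x^2))
  })
}

#' Generate a narrow-band oscillation
#'
#' Random-phase sinusoid with a small per-block frequency jitter, used to
#' inject band-limited power into synthetic LFP channels. The jitter keeps the
#' component narrow-band (power concentrated within about +/- `jitter_hz` of
#' the carrier) while avoiding a perfectly deterministic line. Phase is
#' continuous across jitter blocks, so the waveform has no discontinuities.
#'
#' @param freq Carrier frequency in Hz; must satisfy `0 < freq < fs / 2`.
#' @param rms Target RMS amplitude in microvolts (exactly matched; 0 gives a
#'   zero signal). A pure sinusoid of amplitude A has RMS A/sqrt(2).
#' @param n_samples,fs Length and sampling rate.
#' @param seed Optional integer seed.
#' @param jitter_hz Half-width of the uniform per-block frequency jitter.
#' @param jitter_block_s Duration in seconds of each constant-frequency block.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_oscillation <- function(freq, rms, n_samples, fs, seed = NULL,
                                 jitter_hz = 0.5, jitter_block_s = 1) {
  stop_if_not_scalar_number(n_samples, "n_samples", min = 1)
  stop_if_not_scalar_number(fs, "fs", min = .Machine$double.eps)
  stop_if_not_scalar_number(rms, "rms", min = 0)
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0) {
    abort("`freq` must be a single positive frequency in Hz.")
  }
  if (freq >= fs / 2) {
    abort(sprintf("aliasing: freq = %g Hz is not below the Nyquist frequency %g Hz.",
                  freq, fs / 2))
  }
  n <- as.integer(n_samples)
  if (rms == 0) return(numeric(n))
  with_local_seed(seed, {
    block <- max(1L, as.integer(round(jitter_block_s * fs)))
    n_blocks <- ceiling(n / block)
    f_block <- freq + runif(n_blocks, -jitter_hz, jitter_hz)
    f_inst <- rep(f_block, each = block)[seq_len(n)]
    phase <- runif(1, 0, 2 * pi) + 2 * pi * cumsum(f_inst) / fs
    x <- sin(phase)
    x * rms / sqrt(mean(x^2))
  })
}
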