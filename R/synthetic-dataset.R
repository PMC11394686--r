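#' Default frequency bands
#'
#' The five analysis bands, half-open on the right so adjacent edges are
#' counted once: delta `[1, 4)`, theta `[4, 8)`, alpha `[8, 21)`,
#' beta `[21, 32)`, gamma `[32, 100)` Hz. The alpha/beta partition follows the
#' source convention of this analysis (8-21 / 21-32 Hz) rather than the
#' clinical EEG one, and the gamma band deliberately extends to 100 Hz even
#' though the conditioning filter passes only up to 80 Hz.
#'
#' @return A tibble with columns `band` (factor, in spectral order), `low`,
#'   `high` (Hz).
#' @export
default_bands <- function() {
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "gamma")),
    low = c(1, 4, 8, 21, 32),
    high = c(4, 8, 21, 32, 100)
  )
}

default_regions <- function() c("M1", "CPu", "STN", "SNc", "PPN")

# Carrier frequency used when injecting an oscillation for each band (Hz).
# The gamma carrier sits mid-band at 50 Hz, well inside the 0.5-80 Hz
# conditioning passband, so injected gamma power is not lost to the filter
# skirt (the 80-100 Hz tail of the gamma band is attenuated by design).
band_carrier_freqs <- function() {
  c(delta = 2.5, theta = 6, alpha = 12, beta = 26, gamma = 50)
}

#' Band-effect table of the bundled demonstration study
#'
#' Walk-state oscillation amplitudes (RMS, microvolts) per group x region x
#' band; resting-state injections are zero, so the injected
#' walking-minus-resting band-power difference for a subject with unit
#' between-subject multiplier equals RMS^2. The gamma column encodes the
#' lesion-specific movement effect: an increase in M1, STN, SNc and PPN but
#' not CPu, with regional magnitudes chosen so the pooled channel means rank
#' M1 lowest, CPu intermediate and PPN/SNc/STN highest, and the lesion-sham
#' group contrast is about 1.5 between-subject standard deviations. Other
#' bands receive modest uniform walk-related increases; at the default
#' background level the low bands remain dominated by 1/f noise, which is
#' physiologically realistic.
#'
#' @return Tibble with columns `group`, `state`, `region`, `band`, `freq_hz`,
#'   `rms` (microvolts).
#' @export
demo_band_effects <- function() {
  regions <- default_regions()
  freqs <- band_carrier_freqs()
  # injected walk-state power (uV^2) per region, by group and band
  pow <- list(
    sham = list(
      delta = c(2.0, 2.0, 2.0, 2.0, 2.0),
      theta = c(2.2, 1.4, 2.2, 2.2, 2.2),
      alpha = c(1.6, 1.6, 2.0, 2.0, 2.6),
      beta  = c(1.2, 2.0, 2.4, 2.2, 2.2),
      gamma = c(1.2, 2.2, 1.8, 1.8, 1.8)
    ),
    lesion = list(
      delta = c(2.9, 2.9, 2.9, 2.9, 2.9),
      theta = c(3.0, 2.2, 3.0, 3.0, 3.0),
      alpha = c(2.3, 2.3, 2.7, 2.7, 3.3),
      beta  = c(2.0, 2.8, 3.2, 3.0, 3.0),
      gamma = c(2.1, 2.2, 3.7, 3.7, 3.7)
    )
  )
  purrr::map_dfr(names(pow), function(g) {
    purrr::map_dfr(names(pow[[g]]), function(b) {
      tibble::tibble(
        group = g, state = "walk", region = regions, band = b,
        freq_hz = unname(freqs[[b]]), rms = sqrt(pow[[g]][[b]])
      )
    })
  })
}

#' Specification of a synthetic LFP study
#'
#' Collects the generative parameters of a simulated two-group recording
#' study: group sizes, recorded regions, sampling rate, duration of the
#' resting and walking phases, the 1/f background (slope and RMS), the table
#' of injected band-limited oscillations, and the between-subject lognormal
#' variability. Defaults reproduce the bundled demonstration study: 2 groups
#' x 10 subjects x 5 regions, 5 min per state at 1000 Hz.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param regions Ordered region labels (distinct).
#' @param fs Sampling rate, Hz.
#' @param state_duration_s Seconds per behavioral state (one contiguous rest
#'   block followed by one walk block).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_scale Background RMS in microvolts.
#' @param band_effects Tibble as returned by [demo_band_effects()]; rows give
#'   the injected oscillation RMS per (group, state, region, band). Missing
#'   combinations inject nothing. `NULL` injects nothing anywhere (null
#'   generator).
#' @param subject_sd Lognormal sigma of the per-subject amplitude multiplier.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = 10,
                           regions = default_regions(),
                           fs = 1000,
                           state_duration_s = 300,
                           noise_exponent = 1,
                           noise_scale = 12,
                           band_effects = demo_band_effects(),
                           subject_sd = 0.2,
                           seed = 1L) {
  stop_if_not_scalar_number(n_per_group, "n_per_group", min = 2)
  stop_if_not_scalar_number(fs, "fs", min = .Machine$double.eps)
  stop_if_not_scalar_number(state_duration_s, "state_duration_s", min = 1)
  stop_if_not_scalar_number(noise_exponent, "noise_exponent", min = 0, max = 2)
  stop_if_not_scalar_number(noise_scale, "noise_scale", min = 0)
  stop_if_not_scalar_number(subject_sd, "subject_sd", min = 0)
  if (anyDuplicated(regions) || length(regions) < 2) {
    abort("`regions` must be at least two distinct labels.")
  }
  if (!is.null(band_effects)) {
    req <- c("group", "state", "region", "band", "freq_hz", "rms")
    if (!all(req %in% names(band_effects))) {
      abort(paste("`band_effects` must have columns:", paste(req, collapse = ", ")))
    }
    bad_region <- setdiff(unique(band_effects$region), regions)
    bad_band <- setdiff(unique(as.character(band_effects$band)),
                        as.character(default_bands()$band))
    if (length(bad_region) || length(bad_band)) {
      abort(sprintf("`band_effects` references unknown %s: %s",
                    if (length(bad_region)) "region(s)" else "band(s)",
                    paste(c(bad_region, bad_band), collapse = ", ")))
    }
    if (any(band_effects$rms < 0)) abort("oscillation amplitudes must be >= 0.")
    if (fs <= 2 * max(band_effects$freq_hz)) {
      abort("`fs` must exceed twice the highest injected carrier frequency.")
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), regions = regions, fs = fs,
         state_duration_s = state_duration_s, noise_exponent = noise_exponent,
         noise_scale = noise_scale, band_effects = band_effects,
         subject_sd = subject_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> 2 x %d subjects, %d regions, %g s/state @ %g Hz, 1/f^%g background (%g uV RMS)\n",
    x$n_per_group, length(x$regions), x$state_duration_s, x$fs,
    x$noise_exponent, x$noise_scale))
  if (is.null(x$band_effects)) cat("  no injected oscillations (null generator)\n")
  else cat(sprintf("  %d injected oscillation rows, subject_sd = %g, seed = %d\n",
                   nrow(x$band_effects), x$subject_sd, x$seed))
  invisible(x)
}

#' A single synthetic or imported LFP recording
#'
#' One subject's multi-channel time series with group label and state
#' annotation: one contiguous resting block followed by one walking block.
#'
#' @param subject_id Subject label.
#' @param group `"sham"` or `"lesion"`.
#' @param fs Sampling rate, Hz.
#' @param signals Numeric matrix, one column per region (column names are the
#'   region labels), in microvolts.
#' @param states Tibble with columns `state` (`"rest"`/`"walk"`), `start_s`,
#'   `end_s`; intervals must be non-overlapping and within the signal.
#' @return Object of class `lfp_recording`.
#' @export
lfp_recording <- function(subject_id, group, fs, signals, states) {
  if (!is.matrix(signals) || is.null(colnames(signals))) {
    abort("`signals` must be a matrix with region column names.")
  }
  if (!group %in% c("sham", "lesion")) abort("`group` must be 'sham' or 'lesion'.")
  if (!all(states$state %in% c("rest", "walk"))) {
    abort("state labels must be 'rest' or 'walk'.")
  }
  dur <- nrow(signals) / fs
  st <- states[order(states$start_s), ]
  if (any(st$end_s <= st$start_s) || any(st$start_s < 0) ||
      any(st$end_s > dur + 1e-9)) {
    abort("state intervals must lie within the recording.")
  }
  if (nrow(st) > 1 && any(st$start_s[-1] < st$end_s[-nrow(st)] - 1e-9)) {
    abort("state intervals must not overlap.")
  }
  structure(list(subject_id = subject_id, group = group, fs = fs,
                 signals = signals, states = tibble::as_tibble(states)),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s (%s): %d regions x %g s @ %g Hz, states: %s\n",
              x$subject_id, x$group, ncol(x$signals), nrow(x$signals) / x$fs,
              x$fs, paste(x$states$state, collapse = "+")))
  invisible(x)
}

#' Generate a synthetic two-group LFP dataset
#'
#' Simulates `2 * n_per_group` recordings under a [synthetic_spec()]: each
#' region's trace is a 1/f^beta background plus the injected band-limited
#' oscillations for that (group, state, region), all oscillation amplitudes
#' scaled by a per-subject lognormal multiplier. Returns the recordings
#' together with the ground-truth table of injected band powers
#' (`rms^2 * multiplier^2`, in uV^2), aligned row-for-row with the band-power
#' table the analysis pipeline later produces.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `lfp_dataset`: a list with elements `recordings`
#'   (list of [lfp_recording()]), `ground_truth` (tibble: subject_id, group,
#'   region, state, band, injected_power), and `spec`.
#' @export
generate_lfp_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec.")
  n_state <- as.integer(round(spec$state_duration_s * spec$fs))
  bands <- as.character(default_bands()$band)
  with_local_seed(spec$seed, {
    recs <- list()
    gt <- list()
    for (group in c("sham", "lesion")) {
      for (i in seq_len(spec$n_per_group)) {
        sid <- sprintf("%s%02d", group, i)
        mult <- if (spec$subject_sd > 0) {
          rlnorm(1, meanlog = -spec$subject_sd^2 / 2, sdlog = spec$subject_sd)
        } else 1
        sig <- matrix(0, nrow = 2L * n_state, ncol = length(spec$regions),
                      dimnames = list(NULL, spec$regions))
        for (region in spec$regions) {
          for (state in c("rest", "walk")) {
            x <- generate_pink_noise(n_state, spec$fs, spec$noise_exponent,
                                     spec$noise_scale)
            if (!is.null(spec$band_effects)) {
              fx <- spec$band_effects[
                spec$band_effects$group == group &
                  spec$band_effects$state == state &
                  spec$band_effects$region == region & spec$band_effects$rms > 0, ]
              for (j in seq_len(nrow(fx))) {
                x <- x + generate_oscillation(fx$freq_hz[j], fx$rms[j] * mult,
                                              n_state, spec$fs)
              }
            }
            rows <- if (state == "rest") seq_len(n_state) else n_state + seq_len(n_state)
            sig[rows, region] <- x
            inj <- setNames(numeric(length(bands)), bands)
            if (!is.null(spec$band_effects)) {
              fx <- spec$band_effects[
                spec$band_effects$group == group &
                  spec$band_effects$state == state &
                  spec$band_effects$region == region, ]
              inj[as.character(fx$band)] <- (fx$rms * mult)^2
            }
            gt[[length(gt) + 1L]] <- tibble::tibble(
              subject_id = sid, group = group, region = region, state = state,
              band = bands, injected_power = unname(inj),
              subject_multiplier = mult)
          }
        }
        recs[[sid]] <- lfp_recording(
          sid, group, spec$fs, sig,
          tibble::tibble(state = c("rest", "walk"),
                         start_s = c(0, spec$state_duration_s),
                         end_s = c(spec$state_duration_s, 2 * spec$state_duration_s)))
      }
    }
    structure(list(recordings = recs,
                   ground_truth = dplyr::bind_rows(gt),
                   spec = spec),
              class = "lfp_dataset")
  })
}

#' @export
print.lfp_dataset <- function(x, ...) {
  cat(sprintf("<lfp_dataset> %d recordings, ground truth %d rows\n",
              length(x$recordings), nrow(x$ground_truth)))
  invisible(x)
}

#' Simulate a walking-minus-resting difference table directly
#'
#' Table-level companion to the waveform generator for calibration studies:
#' draws per subject x region difference values from the generator's
#' statistical model (group shift + region shifts + a normal subject random
#' intercept + exchangeable residual noise) without synthesising waveforms.
#' With all shifts zero this is the null model used for type-I-error
#' calibration of [mixed_anova()].
#'
#' @param n_per_group Subjects per group.
#' @param regions Region labels.
#' @param group_shift Added to every lesion-group value (same units as the
#'   difference statistic).
#' @param region_shifts Optional named vector of per-region shifts.
#' @param subject_sd SD of the subject random intercept.
#' @param resid_sd SD of the residual noise.
#' @param seed Optional seed.
#' @return Tibble with columns `subject_id`, `group`, `region`, `diff`.
#' @export
simulate_diff_table <- function(n_per_group = 10, regions = default_regions(),
                                group_shift = 0, region_shifts = NULL,
                                subject_sd = 1, resid_sd = 1, seed = NULL) {
  stop_if_not_scalar_number(n_per_group, "n_per_group", min = 2)
  k <- length(regions)
  rs <- setNames(numeric(k), regions)
  if (!is.null(region_shifts)) rs[names(region_shifts)] <- region_shifts
  with_local_seed(seed, {
    purrr::map_dfr(c("sham", "lesion"), function(group) {
      purrr::map_dfr(seq_len(n_per_group), function(i) {
        b <- rnorm(1, 0, subject_sd)
        tibble::tibble(
          subject_id = sprintf("%s%02d", group, i), group = group,
          region = regions,
          diff = (group == "lesion") * group_shift + unname(rs) + b +
            rnorm(k, 0, resid_sd))
      })
    })
  })
}

#' Default behavioral effect profile of the demonstration study
#'
#' Lesion-group shifts for each behavioral endpoint in units of the sham
#' between-subject SD, plus the cylinder side-preference shift (probability
#' points moved from the non-injection to the injection forelimb) and the
#' gait shift (percentage points moved from diagonal to three-limb support).
#' Signs follow the hemiparkinsonian phenotype: shorter rotarod latency and
#' distance, more hindlimb errors, ipsilateral forelimb preference, less
#' diagonal and more three-limb support, less time in the arena centre.
#'
#' @return Named list of shifts.
#' @export
demo_effect_profile <- function() {
  list(rotarod_latency = -1.0, rotarod_speed = -0.6, rotarod_distance = -1.0,
       beam_time = 0.5, beam_errors = 1.2, pole_time = 0.1,
       open_distance = -0.45, open_centre_entries = -0.6,
       open_centre_time_pct = -0.9,
       cylinder_bias = 0.15, gait_shift = 14)
}

behavior_endpoint_params <- function() {
  tibble::tibble(
    endpoint = c("rotarod_latency", "rotarod_speed", "rotarod_distance",
                 "beam_time", "beam_errors", "pole_time", "open_distance",
                 "open_centre_entries", "open_centre_time_pct"),
    mean = c(220, 36, 1400, 12, 1, 8, 3000, 25, 8),
    sd = c(40, 4, 300, 4, NA, 2, 600, 8, 3),
    trials = c(3L, 3L, 3L, 1L, 1L, 3L, 1L, 1L, 1L),
    dist = c("normal", "normal", "normal", "normal", "poisson", "normal",
             "normal", "normal", "normal"),
    lo = c(0, 4, 0, 1, 0, 1, 0, 0, 0),
    hi = c(300, 40, Inf, Inf, Inf, Inf, Inf, Inf, 100)
  )
}

#' Generate synthetic behavioral tables
#'
#' Emulates the behavioral battery of a unilateral 6-OHDA study: rotarod
#' (latency s, speed rpm, distance cm; three trials), beam traversal (time s,
#' hindlimb errors), pole descent (s; three trials), open field (distance,
#' centre entries, centre time %), rearing-cylinder forelimb touch counts and
#' per-frame gait support labels. Group differences follow `effect_profile`
#' (see [demo_effect_profile()]); an empty profile gives equal groups in
#' expectation.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param effect_profile Named list of lesion shifts; missing entries are 0.
#' @param seed Optional seed.
#' @param n_gait_frames Video frames scored per subject.
#' @return List of tibbles: `endpoints` (subject_id, group, endpoint, trial,
#'   value), `cylinder` (touch counts by side), `gait` (subject_id, group,
#'   frame, support in diagonal/three_limb/other).
#' @export
generate_behavior_dataset <- function(n_per_group = 10,
                                      effect_profile = demo_effect_profile(),
                                      seed = NULL, n_gait_frames = 200) {
  stop_if_not_scalar_number(n_per_group, "n_per_group", min = 2)
  stop_if_not_scalar_number(n_gait_frames, "n_gait_frames", min = 1)
  prof <- function(name) effect_profile[[name]] %||% 0
  params <- behavior_endpoint_params()
  with_local_seed(seed, {
    subjects <- tibble::tibble(
      subject_id = c(sprintf("sham%02d", seq_len(n_per_group)),
                     sprintf("lesion%02d", seq_len(n_per_group))),
      group = rep(c("sham", "lesion"), each = n_per_group))
    endpoints <- purrr::map_dfr(seq_len(nrow(params)), function(j) {
      p <- params[j, ]
      purrr::map_dfr(seq_len(nrow(subjects)), function(s) {
        lesioned <- subjects$group[s] == "lesion"
        if (p$dist == "poisson") {
          lam <- p$mean + lesioned * prof(p$endpoint) * sqrt(p$mean)
          val <- rpois(p$trials, max(lam, 0))
        } else {
          mu <- p$mean + lesioned * prof(p$endpoint) * p$sd
          # subject effect + trial noise; single-trial endpoints get full sd
          subj <- rnorm(1, mu, p$sd * if (p$trials > 1) 0.9 else 1)
          val <- pmin(pmax(rnorm(p$trials, subj, p$sd * 0.45 * (p$trials > 1)),
                           p$lo), p$hi)
        }
        tibble::tibble(subject_id = subjects$subject_id[s],
                       group = subjects$group[s], endpoint = p$endpoint,
                       trial = seq_len(p$trials), value = as.numeric(val))
      })
    })
    cylinder <- purrr::map_dfr(seq_len(nrow(subjects)), function(s) {
      bias <- if (subjects$group[s] == "lesion") prof("cylinder_bias") else 0
      pr <- c(0.40 + bias, 0.40 - bias, 0.20)
      total <- rpois(1, 30) + 1L
      counts <- as.vector(rmultinom(1, total, pr))
      tibble::tibble(subject_id = subjects$subject_id[s],
                     group = subjects$group[s],
                     touches_injection = counts[1],
                     touches_non_injection = counts[2],
                     touches_both = counts[3])
    })
    gait <- purrr::map_dfr(seq_len(nrow(subjects)), function(s) {
      shift <- if (subjects$group[s] == "lesion") prof("gait_shift") else 0
      diag_pct <- min(max(rnorm(1, 70 - shift, 5), 5), 95)
      three_pct <- min(max(rnorm(1, 25 + 0.85 * shift, 4), 2), 100 - diag_pct - 1)
      pr <- c(diag_pct, three_pct, 100 - diag_pct - three_pct) / 100
      labs <- sample(c("diagonal", "three_limb", "other"), n_gait_frames,
                     replace = TRUE, prob = pr)
      tibble::tibble(subject_id = subjects$subject_id[s],
                     group = subjects$group[s],
                     frame = seq_len(n_gait_frames), support = labs)
    })
    list(endpoints = endpoints, cylinder = cylinder, gait = gait)
  })
}

#' Generate synthetic TH+ cell-count tables
#'
#' Per subject x hemisphere x slice counts of tyrosine-hydroxylase-positive
#' neurons with the delineated region area, mirroring a three-slice stereology
#' design. Expected lesion-side density is `sham_density * (1 - loss)` for the
#' corresponding hemisphere; sham subjects have no loss on either side.
#'
#' @param n_per_group Subjects per group.
#' @param sham_density Expected sham density, cells/mm^2.
#' @param loss_injection,loss_noninjection Fractional density loss in the
#'   lesion group on each side, in `[0, 1]`.
#' @param n_slices Slices per subject and side (>= 1).
#' @param seed Optional seed.
#' @param subject_cv Between-subject coefficient of variation of density.
#' @param area_mm2,area_sd Mean and SD of the delineated slice area.
#' @return Tibble: `subject_id`, `group`, `side`, `slice`, `th_count`, `area`.
#' @export
generate_cell_counts <- function(n_per_group = 10, sham_density = 400,
                                 loss_injection = 0.8952,
                                 loss_noninjection = 0.6121,
                                 n_slices = 3, seed = NULL,
                                 subject_cv = 0.1, area_mm2 = 0.16,
                                 area_sd = 0.02) {
  stop_if_not_scalar_number(n_per_group, "n_per_group", min = 2)
  stop_if_not_scalar_number(loss_injection, "loss_injection", 0, 1)
  stop_if_not_scalar_number(loss_noninjection, "loss_noninjection", 0, 1)
  stop_if_not_scalar_number(n_slices, "n_slices", min = 1)
  stop_if_not_scalar_number(sham_density, "sham_density", min = 0)
  with_local_seed(seed, {
    purrr::map_dfr(c("sham", "lesion"), function(group) {
      purrr::map_dfr(seq_len(n_per_group), function(i) {
        sdl <- sqrt(log(1 + subject_cv^2))
        mult <- if (subject_cv > 0) rlnorm(1, -sdl^2 / 2, sdl) else 1
        purrr::map_dfr(c("injection", "non_injection"), function(side) {
          loss <- if (group == "lesion") {
            if (side == "injection") loss_injection else loss_noninjection
          } else 0
          dens <- sham_density * mult * (1 - loss)
          area <- pmax(rnorm(n_slices, area_mm2, area_sd), area_mm2 / 4)
          tibble::tibble(
            subject_id = sprintf("%s%02d", group, i), group = group,
            side = side, slice = seq_len(as.integer(n_slices)),
            th_count = rpois(n_slices, dens * area), area = area)
        })
      })
    })
  })
}
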