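#' Cylinder-test forelimb asymmetry ratio
#'
#' `(injection - non_injection) / (injection + non_injection + both) * 100`,
#' in percent. Positive values indicate a preference for the forelimb
#' ipsilateral to the injected hemisphere. Vectorised; errors when a trial
#' has no touches at all.
#'
#' @param touches_injection,touches_non_injection,touches_both Non-negative
#'   touch counts.
#' @return Asymmetry ratio(s) in `[-100, 100]`.
#' @examples
#' asymmetry_ratio(6, 2, 2) # 40
#' @export
asymmetry_ratio <- function(touches_injection, touches_non_injection,
                            touches_both) {
  counts <- cbind(touches_injection, touches_non_injection, touches_both)
  if (any(counts < 0)) abort("touch counts must be non-negative.")
  total <- rowSums(counts)
  if (any(total == 0)) abort("undefined asymmetry ratio: a trial has zero touches.")
  as.numeric((counts[, 1] - counts[, 2]) / total * 100)
}

#' Gait support percentages
#'
#' Percentage of video frames spent in each support class. Classes are
#' exhaustive and exclusive per frame, so the percentages sum to exactly 100.
#'
#' @param frames Character vector of per-frame support labels (typically
#'   `"diagonal"`, `"three_limb"`, `"other"`).
#' @param classes Classes to report; labels outside this set are pooled into
#'   `"other"`.
#' @return Named numeric vector of percentages over `classes`.
#' @export
support_percentages <- function(frames,
                                classes = c("diagonal", "three_limb", "other")) {
  if (length(frames) == 0) abort("no frames supplied.")
  f <- ifelse(frames %in% classes, frames, "other")
  counts <- table(factor(f, levels = classes))
  as.vector(counts) / length(frames) * 100 -> pct
  setNames(pct, classes)
}

#' Summarise behavioral endpoints and test group differences
#'
#' Aggregates multi-trial endpoints to per-subject means, derives the
#' cylinder asymmetry ratio and the gait support percentages per subject,
#' then reports group mean +/- SD for every endpoint together with the
#' assumption-driven group comparison ([select_and_run_test()]).
#'
#' @param endpoints Tibble `subject_id, group, endpoint, trial, value` (as
#'   produced by [generate_behavior_dataset()]).
#' @param cylinder Optional tibble of cylinder touch counts per subject.
#' @param gait Optional tibble of per-frame gait labels per subject.
#' @return Tibble with one row per endpoint: group means/SDs, `test_used`,
#'   `transform_used`, `statistic`, `p`, `significance_class`.
#' @export
summarize_endpoints <- function(endpoints, cylinder = NULL, gait = NULL) {
  req <- c("subject_id", "group", "endpoint", "value")
  if (!all(req %in% names(endpoints))) {
    abort(paste("`endpoints` must have columns:", paste(req, collapse = ", ")))
  }
  per_subject <- dplyr::summarise(
    dplyr::group_by(endpoints, .data$subject_id, .data$group, .data$endpoint),
    value = mean(.data$value), .groups = "drop")
  if (!is.null(cylinder)) {
    asym <- dplyr::mutate(cylinder,
      endpoint = "cylinder_asymmetry",
      value = asymmetry_ratio(.data$touches_injection,
                              .data$touches_non_injection, .data$touches_both))
    per_subject <- dplyr::bind_rows(
      per_subject,
      dplyr::select(asym, dplyr::all_of(c("subject_id", "group", "endpoint", "value"))))
  }
  if (!is.null(gait)) {
    sup <- dplyr::reframe(
      dplyr::group_by(gait, .data$subject_id, .data$group),
      endpoint = c("gait_diagonal_pct", "gait_three_limb_pct", "gait_other_pct"),
      value = unname(support_percentages(.data$support)))
    # "other" support is carried in the summary but not tested
    per_subject <- dplyr::bind_rows(per_subject, sup)
  }
  tested <- setdiff(unique(per_subject$endpoint), "gait_other_pct")
  purrr::map_dfr(unique(per_subject$endpoint), function(ep) {
    d <- per_subject[per_subject$endpoint == ep, ]
    xs <- d$value[d$group == "sham"]
    xl <- d$value[d$group == "lesion"]
    if (length(xs) < 2 || length(xl) < 2) {
      abort(sprintf("endpoint '%s' needs >= 2 subjects per group.", ep))
    }
    base <- tibble::tibble(endpoint = ep,
                           n_sham = length(xs), mean_sham = mean(xs), sd_sham = sd(xs),
                           n_lesion = length(xl), mean_lesion = mean(xl),
                           sd_lesion = sd(xl))
    if (ep %in% tested && length(xs) >= 3 && length(xl) >= 3) {
      tst <- select_and_run_test(xl, xs, endpoint = ep)
      dplyr::bind_cols(base, dplyr::select(tst, -"endpoint"))
    } else {
      dplyr::mutate(base, test_used = NA_character_,
                    transform_used = NA_character_, statistic = NA_real_,
                    p = NA_real_, significance_class = NA_character_)
    }
  })
}
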