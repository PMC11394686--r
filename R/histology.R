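#' Per-subject TH+ neuron density
#'
#' Mean of the per-slice densities `th_count / area` (cells/mm^2) across the
#' slices of one subject and hemisphere, the quantity carried into group
#' statistics.
#'
#' @param slices Tibble of slice counts for a single subject and side, with
#'   columns `th_count` and `area` (and optionally `subject_id`/`side`,
#'   which must then be unique).
#' @return Density in cells/mm^2.
#' @export
subject_density <- function(slices) {
  if (nrow(slices) < 1) abort("need at least one slice.")
  for (col in c("subject_id", "side")) {
    if (col %in% names(slices) && length(unique(slices[[col]])) > 1) {
      abort(sprintf("`slices` mixes several values of `%s`.", col))
    }
  }
  if (any(slices$area <= 0) || any(slices$th_count < 0)) {
    abort("areas must be positive and counts non-negative.")
  }
  mean(slices$th_count / slices$area)
}

#' Percent loss of neuron density relative to the sham group
#'
#' `(1 - lesion_mean / sham_mean) * 100`. Scale-invariant: multiplying all
#' densities by a positive constant leaves it unchanged.
#'
#' @param lesion_mean,sham_mean Group mean densities, cells/mm^2;
#'   `sham_mean` must be positive.
#' @return Percent loss (negative if the lesion group is denser).
#' @examples
#' percent_loss(10.48, 100) # 89.52
#' @export
percent_loss <- function(lesion_mean, sham_mean) {
  if (any(sham_mean <= 0)) abort("`sham_mean` must be positive.")
  (1 - lesion_mean / sham_mean) * 100
}

#' Compare TH+ densities between groups, per hemisphere
#'
#' Computes per-subject densities with [subject_density()], then for each
#' side reports the group means, the percent loss relative to sham, and the
#' assumption-driven group comparison ([select_and_run_test()]).
#'
#' @param cells Tibble as produced by [generate_cell_counts()]: columns
#'   `subject_id`, `group`, `side`, `slice`, `th_count`, `area`.
#' @return Tibble with one row per side.
#' @export
compare_groups <- function(cells) {
  req <- c("subject_id", "group", "side", "th_count", "area")
  if (!all(req %in% names(cells))) {
    abort(paste("`cells` must have columns:", paste(req, collapse = ", ")))
  }
  dens <- dplyr::summarise(
    dplyr::group_by(cells, .data$subject_id, .data$group, .data$side),
    density = mean(.data$th_count / .data$area), .groups = "drop")
  purrr::map_dfr(unique(dens$side), function(s) {
    d <- dens[dens$side == s, ]
    xs <- d$density[d$group == "sham"]
    xl <- d$density[d$group == "lesion"]
    if (length(xs) < 3 || length(xl) < 3) {
      abort("need at least 3 subjects per group and side.")
    }
    tst <- select_and_run_test(xl, xs, endpoint = paste0("th_density_", s))
    tibble::tibble(side = s, mean_sham = mean(xs), sd_sham = sd(xs),
                   mean_lesion = mean(xl), sd_lesion = sd(xl),
                   percent_loss = percent_loss(mean(xl), mean(xs)),
                   test_used = tst$test_used, transform_used = tst$transform_used,
                   statistic = tst$statistic, p = tst$p,
                   significance_class = tst$significance_class)
  })
}
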