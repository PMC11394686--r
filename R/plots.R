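#' Plot group-average power spectra
#'
#' Fig.-6-style panels: mean power spectral density per region with a
#' +/- SEM ribbon, resting and walking states as colours, groups as line
#' types (or facet columns).
#'
#' @param object An `lfp_spectra` tibble (per-subject spectra from
#'   [build_band_power_table()]).
#' @param max_freq Upper frequency limit of the panel, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfp_spectra
#' @export
autoplot.lfp_spectra <- function(object, max_freq = 100, ...) {
  gs <- dplyr::summarise(
    dplyr::group_by(object, .data$group, .data$region, .data$state, .data$freq),
    mean_psd = mean(.data$psd),
    sem_psd = sd(.data$psd) / sqrt(dplyr::n()), .groups = "drop")
  gs <- gs[gs$freq >= 1 & gs$freq <= max_freq, ]
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$freq, y = .data$mean_psd,
                                   colour = .data$state, fill = .data$state)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_psd - .data$sem_psd,
                                      ymax = .data$mean_psd + .data$sem_psd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(region ~ group) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}

#' Plot the walking-minus-resting difference statistic
#'
#' Fig.-7-style summary: per-band boxplots of the per-subject band-power
#' differences, regions on the x axis, groups as fill.
#'
#' @param diff Difference table from [state_difference()].
#' @param bands Optional subset of band labels to show.
#' @return A ggplot object.
#' @export
plot_state_difference <- function(diff, bands = NULL) {
  d <- if (is.null(bands)) diff else diff[diff$band %in% bands, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$diff,
                                  fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = expression(Delta ~ power ~ (walk - rest) ~ (mu * V^2))) +
    ggplot2::theme_minimal()
}

#' @method autoplot lfp_anova
#' @export
autoplot.lfp_anova <- function(object, ...) {
  eff <- object$effects
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$effect, y = .data$partial_eta_sq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = if (is.na(object$band)) NULL else paste("Band:", object$band),
                  x = NULL, y = expression(partial ~ eta^2)) +
    ggplot2::theme_minimal()
}
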