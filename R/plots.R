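#' Plot a bouton simulation trace
#'
#' Facetted time series of the main state variables: membrane voltage,
#' microdomain and cytosolic Ca2+, IP3, channel open fractions and the
#' instantaneous release rate.
#'
#' @param object a `bouton_sim` object.
#' @param variables trace columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bouton_sim <- function(object,
                                variables = c("V", "ca_az", "ca_cyt",
                                              "ip3", "po_vgcc",
                                              "release_rate"),
                                ...) {
  long <- tidy(object, variables = variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IP3R open-probability surface
#'
#' @param surface a tibble from [ip3r_po_surface()].
#' @return A ggplot object (Po vs Ca, one line per IP3 level).
#' @export
plot_po_surface <- function(surface) {
  ggplot2::ggplot(surface,
                  ggplot2::aes(x = .data$ca, y = .data$po,
                               colour = factor(.data$ip3))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Ca2+ (uM)", y = "open probability",
                  colour = "IP3 (uM)") +
    ggplot2::theme_minimal()
}

#' Plot per-pulse train statistics
#'
#' @param per_pulse the `per_pulse` tibble from [run_train()].
#' @return A ggplot object (release probability and peak sync/async
#'   rates vs pulse number).
#' @export
plot_train <- function(per_pulse) {
  long <- per_pulse |>
    dplyr::select("pulse", "pr", "peak_sync", "peak_async") |>
    tidyr::pivot_longer(-"pulse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pulse, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "pulse number", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot release-event phases against the AP train
#'
#' @param phases a tibble from [event_phases()].
#' @param bins histogram bins (default 50).
#' @return A ggplot object.
#' @export
plot_phases <- function(phases, bins = 50) {
  h <- phase_histogram(phases, bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 1 / bins) +
    ggplot2::labs(x = "event phase", y = "events") +
    ggplot2::theme_minimal()
}
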