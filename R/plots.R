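#' Plot a simulated trajectory
#'
#' Compartment counts against time; time is drawn on a log axis by default
#' because the decline phases are separated by orders of magnitude.
#'
#' @param object A `radcell_trajectory`.
#' @param log_time Use a log10 time axis (drops t = 0).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radcell_trajectory
#' @export
autoplot.radcell_trajectory <- function(object, log_time = TRUE, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x", "y", "w", "z"),
                              names_to = "compartment", values_to = "cells")
  long$compartment <- factor(long$compartment, levels = c("x", "y", "w", "z"),
                             labels = c("healthy (x)", "repairing (y)",
                                        "adapted (w)", "altered (z)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$cells,
                                          colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (model units)", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a dose-response curve
#'
#' `ln` surviving fraction against dose on a log dose axis, the standard
#' representation in which the HRS steep segment, the IRR shoulder and the
#' high-dose decline are visible.
#'
#' @param object A `radcell_drc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radcell_drc
#' @export
autoplot.radcell_drc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$dose, .data$ln_sf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "ln surviving fraction") +
    ggplot2::theme_minimal()
}

#' Plot a priming-ratio curve
#'
#' Ratio of altered cells (primed / unprimed) against the fold increase in
#' the failure probability at the challenge dose, with the neutral line at 1
#' and the interpolated threshold marked when present.
#'
#' @param object A `radcell_ratio_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radcell_ratio_curve
#' @export
autoplot.radcell_ratio_curve <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$n, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold increase in p at challenge dose",
                  y = "altered cells, primed / unprimed") +
    ggplot2::theme_minimal()
  n_star <- attr(object, "n_star")
  if (!is.null(n_star) && is.finite(n_star)) {
    p <- p + ggplot2::geom_vline(xintercept = n_star, linetype = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
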