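#' Plot component generator currents
#'
#' Line plot of the RI, SI, USI and total per-complex currents over time.
#'
#' @param current A generator-current tibble.
#' @return A ggplot object.
#' @export
plot_current <- function(current) {
  long <- tidyr::pivot_longer(
    current, c("i_RI", "i_SI", "i_USI", "i_total"),
    names_to = "component", values_to = "pA"
  )
  long$component <- factor(long$component,
                           levels = c("i_total", "i_SI", "i_USI", "i_RI"),
                           labels = c("total", "SI", "USI", "RI"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$pA,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "current (pA)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an instantaneous-firing-frequency trace
#'
#' @param iff An IFF tibble.
#' @param log_time Log-scale the time axis (the conventional view for
#'   adaptation over a long hold)?
#' @return A ggplot object.
#' @export
plot_iff <- function(iff, log_time = FALSE) {
  p <- ggplot2::ggplot(iff, ggplot2::aes(x = .data$time, y = .data$iff)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "IFF (Hz)") +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Raster plot of a spike train
#'
#' @param spikes A spike-train tibble.
#' @return A ggplot object; spikes are ticked by originating heminode.
#' @export
plot_spikes <- function(spikes) {
  ggplot2::ggplot(spikes, ggplot2::aes(x = .data$time,
                                       y = factor(.data$heminode))) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "time (s)", y = "heminode") +
    ggplot2::theme_minimal()
}

#' Overview plot of a full simulation run
#'
#' @param object An `sai_run` bundle from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object stacking stress, per-complex current and IFF.
#' @export
autoplot.sai_run <- function(object, ...) {
  stress <- tibble::tibble(time = object$stress$time,
                           value = object$stress$stress, panel = "stress (Pa)")
  cur <- tibble::tibble(time = object$current$time,
                        value = object$current$i_total,
                        panel = "per-complex current (pA)")
  iff <- tibble::tibble(time = object$iff$time, value = object$iff$iff,
                        panel = "IFF (Hz)")
  long <- dplyr::bind_rows(stress, cur, iff)
  long$panel <- factor(long$panel, levels = unique(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(data = long[long$panel != "IFF (Hz)", ]) +
    ggplot2::geom_point(data = long[long$panel == "IFF (Hz)", ], size = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
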