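#' Plot methods
#'
#' `autoplot()` methods for the package's result types: waveforms, ICP
#' estimate series and the Valsalva experiment summary (per-trial phase
#' means by method, rest vs maneuver).
#'
#' @param object a `nicp_wave`, `nicp_icp` or `vm_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @name nicp-autoplot
NULL

#' @rdname nicp-autoplot
#' @export
autoplot.nicp_wave <- function(object, ...) {
  units <- wave_units(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = if (nzchar(units)) units else "value"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname nicp-autoplot
#' @export
autoplot.nicp_icp <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$icp_mmHg))
  p <- if (identical(attr(object, "granularity"), "beat")) {
    p + ggplot2::geom_step()
  } else {
    p + ggplot2::geom_line()
  }
  p +
    ggplot2::labs(
      x = "time (s)", y = "estimated ICP (mmHg)",
      title = sprintf("%s estimate", toupper(attr(object, "method") %||% ""))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname nicp-autoplot
#' @export
autoplot.vm_experiment <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(object$trials, all_of(c("method", "trial", "rest_mean"))),
                  phase = "rest", icp = .data$rest_mean, rest_mean = NULL),
    dplyr::mutate(dplyr::select(object$trials, all_of(c("method", "trial", "vm_mean"))),
                  phase = "VM", icp = .data$vm_mean, vm_mean = NULL)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$icp)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ICP per trial (mmHg)") +
    ggplot2::theme_minimal()
}
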