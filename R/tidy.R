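#' Tidy methods for reconstruction objects
#'
#' `tidy()` on an `insitu_recon` or `oss_recon` returns the per-iteration
#' R-factor trace; `glance()` returns a one-row summary.
#'
#' @param x A reconstruction object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.insitu_recon <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$r_trace), r_factor = x$r_trace)
}

#' @rdname tidy
#' @export
tidy.oss_recon <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$r_trace), r_factor = x$r_trace)
}

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.insitu_recon <- function(x, ...) {
  tibble::tibble(n_frames = length(x$objects),
                 n_iter = length(x$r_trace),
                 final_r_factor = x$r_trace[length(x$r_trace)],
                 share_static = isTRUE(x$params$share_static))
}

#' @rdname tidy
#' @export
glance.oss_recon <- function(x, ...) {
  tibble::tibble(n_runs = length(x$run_r_factors),
                 best_run = x$best_run,
                 r_factor = x$r_factor)
}

#' Plot an FRC curve
#'
#' Correlation versus spatial frequency with the threshold line.
#'
#' @param object An `frc_curve` from [frc()].
#' @param threshold Threshold line to draw (default 1/e).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frc_curve <- function(object, threshold = exp(-1), ...) {
  df <- as.data.frame(object)
  xvar <- if (all(is.na(df$frequency))) "radius_px" else "frequency"
  xlab <- if (xvar == "frequency") "spatial frequency (1/m)" else
    "ring radius (px)"
  ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$frc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = xlab, y = "Fourier ring correlation") +
    ggplot2::coord_cartesian(ylim = c(min(0, min(df$frc)), 1))
}

#' @rdname autoplot.frc_curve
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot an R-factor convergence trace
#'
#' @param object An `insitu_recon` or `oss_recon`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.insitu_recon <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$iteration, .data$r_factor)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "Fourier R-factor")
}

#' @rdname autoplot.insitu_recon
#' @export
autoplot.oss_recon <- autoplot.insitu_recon

#' Plot the dose-reduction study
#'
#' Achieved resolution versus fluence for both arms.
#'
#' @param study Tibble from [run_dose_study()].
#' @return A ggplot.
#' @export
plot_dose_study <- function(study) {
  ggplot2::ggplot(study,
                  ggplot2::aes(.data$fluence, .data$resolution * 1e9,
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(fluence ~ (photons ~ mu * m^-2)),
                  y = "FRC 1/e resolution (nm)", colour = NULL)
}
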