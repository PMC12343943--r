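#' Plot a motion trace
#'
#' Displacement of the target centroid from its stationary reference over
#' time, one line per in-plane axis. Gaps (frames where segmentation
#' failed) break the lines.
#'
#' @param object A `motion_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(time_s = df$time_s, axis = "u (columns)", disp = df$du_mm),
    tibble::tibble(time_s = df$time_s, axis = "v (rows)", disp = df$dv_mm)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$disp,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time (s)", y = "displacement from reference (mm)",
                  colour = NULL,
                  title = sprintf("Target centroid motion (%s plane)",
                                  attr(object, "plane"))) +
    ggplot2::theme_minimal()
}

#' Display a frame as an image
#'
#' Quick-look raster display of a `geo_frame` with mm axes.
#'
#' @param object A `geo_frame`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geo_frame <- function(object, ...) {
  px <- object$pixels
  df <- expand.grid(r = seq_len(nrow(px)), c = seq_len(ncol(px)))
  df$u <- (df$c - 1) * object$spacing[["col"]]
  df$v <- (df$r - 1) * object$spacing[["row"]]
  df$intensity <- px[cbind(df$r, df$c)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)",
                  title = sprintf("%s frame", object$plane)) +
    ggplot2::theme_minimal()
}

#' Broom-style accessors for amplitude estimates
#'
#' `tidy()` returns the per-cycle amplitudes; `glance()` a one-row summary.
#'
#' @param x An `amplitude_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.amplitude_estimate <- function(x, ...) x$per_cycle

#' @rdname tidy.amplitude_estimate
#' @export
glance.amplitude_estimate <- function(x, ...) {
  tibble::tibble(mean_mm = x$mean_mm, sd_mm = x$sd_mm,
                 n_cycles = x$n_cycles, period_s = x$period_s, mode = x$mode)
}
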