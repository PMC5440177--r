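# ggplot2 graphics for the main result types.

#' Plot a plasma input function
#'
#' Parent plasma and whole blood against time, on a square-root time axis so
#' both the bolus peak and the tail are visible.
#'
#' @param object A `plasma_input`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plasma_input <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                            names_to = "curve", values_to = "activity")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s / 60, .data$activity,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/ml)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic fit
#'
#' Observed frame values and the model curve; for a Logan fit, the Logan
#' plot with the fitted line and the points actually used.
#'
#' @param object A `kinfit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinfit <- function(object, ...) {
  if (object$model == "logan") {
    pts <- object$points
    return(
      ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_point(ggplot2::aes(shape = .data$used)) +
        ggplot2::geom_abline(slope = object$params$slope,
                             intercept = object$params$intercept,
                             linetype = 2) +
        ggplot2::labs(
          x = expression(integral(ppIF * dt) / TAC),
          y = expression(integral(TAC * dt) / TAC),
          shape = "used"
        ) +
        ggplot2::theme_minimal()
    )
  }
  df <- augment.kinfit(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_mid / 60)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/ml)",
                  title = sprintf("%s fit: %s = %.3g", object$model,
                                  object$outcome, object$vt)) +
    ggplot2::theme_minimal()
}

#' Plot a spectral-analysis spectrum
#'
#' Non-zero components as stems on a log frequency axis.
#'
#' @param object A `pet_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pet_spectrum <- function(object, ...) {
  df <- object$spectrum[object$spectrum$alpha > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, .data$alpha)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$beta, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(beta ~ (s^-1)), y = expression(alpha),
                  title = sprintf("VT = %.3g", object$vt)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a parametric image
#'
#' @param object A `parametric_image`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parametric_image <- function(object, slice = NULL, ...) {
  d <- dim(object)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.numeric(unclass(object)[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = attr(object, "outcome"),
                  title = sprintf("slice z = %d", slice)) +
    ggplot2::theme_void()
}

#' Heatmap of per-region reliability metrics
#'
#' @param rel Output of [run_reliability()].
#' @param metric `"icc"`, `"ma_td"` or `"bs_cv"`.
#' @return A ggplot.
#' @export
plot_reliability <- function(rel, metric = c("icc", "ma_td", "bs_cv")) {
  metric <- match.arg(metric)
  df <- rel$per_region
  df$value <- df[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(.data$variant, .data$region,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = format(round_half_up(.data$value, if (metric == "icc") 2 else 0))
    ), size = 3) +
    ggplot2::scale_fill_viridis_c(name = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
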