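#' Plot filament length-over-time tracks
#'
#' One line per filament, with detected (or ground-truth) pauses shaded, the
#' standard way of displaying stalls in elongation.
#'
#' @param tracks Track tibble (`filament_id`, `time`, `length`).
#' @param pauses Optional pause tibble (`filament_id`, `start`, `end`), e.g.
#'   from [detect_pauses()].
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, pauses = NULL) {
  tracks <- check_tracks(tracks)
  p <- ggplot2::ggplot(tracks,
                       ggplot2::aes(.data$time, .data$length,
                                    group = .data$filament_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Time (s)", y = "Length (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(pauses) && nrow(pauses)) {
    p <- p + ggplot2::geom_rect(
      data = pauses,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.15)
  }
  p
}

#' @export
autoplot.freq_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_center, .data$count)) +
    ggplot2::geom_col(width = object$bin_width[1] * 0.9,
                      fill = "grey60") +
    ggplot2::labs(x = "Duration (s)", y = "Frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dist_fit <- function(object, ...) {
  curve_x <- seq(min(object$data$bin_center), max(object$data$bin_center),
                 length.out = 200)
  curve_y <- if (object$model == "gaussian") {
    object$params["A"] *
      exp(-0.5 * ((curve_x - object$params["mean"]) / object$params["sd"])^2)
  } else {
    (object$params["Y0"] - object$params["Dmax"]) *
      exp(-object$params["k"] * curve_x) + object$params["Dmax"]
  }
  autoplot(object$data) +
    ggplot2::geom_line(
      data = tibble(bin_center = curve_x, count = curve_y),
      ggplot2::aes(.data$bin_center, .data$count),
      color = "red", linewidth = 0.8) +
    ggplot2::labs(subtitle = sprintf("%s fit, r² = %.3f",
                                     object$model, object$r2))
}

#' Plot plus-end occupancy survival curves
#'
#' Step curves of the fraction of molecules still bound versus time since
#' binding, one per species.
#'
#' @param curve A [survival_curve()] result.
#' @return A ggplot object.
#' @export
plot_survival <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$time, .data$surv,
                                      color = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time on end (s)", y = "Fraction still bound",
                  color = "Species") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.oligomer_inference <- function(object, ...) {
  obs <- tibble(k = 1:4, prob = object$observed, what = "observed")
  pred <- mutate(object$pmfs, what = sprintf("n = %d", .data$n))
  ggplot2::ggplot(bind_rows(obs, select(pred, "k", "prob", "what")),
                  ggplot2::aes(.data$k, .data$prob, fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Bleaching steps", y = "Fraction of molecules",
                  fill = NULL,
                  subtitle = sprintf("best_n = %d at p = %.2f",
                                     object$best_n, object$p_label)) +
    ggplot2::theme_minimal()
}

#' Plot a two-channel spot field
#'
#' @param spots Spot tibble with `x`, `y`, `channel`.
#' @return A ggplot object.
#' @export
plot_spots <- function(spots) {
  spots <- check_spots(spots)
  ggplot2::ggplot(spots, ggplot2::aes(.data$x, .data$y,
                                      color = .data$channel)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
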