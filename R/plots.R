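# ggplot2 visualizations for each result type.

#' Plot a recruitment profile with its fitted model
#'
#' Mean +/- s.d. ribbon of one embryo's profile with the fitted model curve
#' overlaid.
#'
#' @param object A `recruit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recruit_fit
#' @export
autoplot.recruit_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_s = seq(object$window[1], object$window[2], length.out = 400))
  grid$fitted <- model_curve(object$model, object$par, grid$time_s)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "Time from CS (s)", y = "Intensity (a.u.)",
                  title = sprintf("%s fit (BIC %.1f)", object$model,
                                  object$bic)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_growth Plot the profile and the rise-then-plateau fit.
#' @param object A `growth_fit`.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::geom_vline(xintercept = object$period, linetype = "dashed") +
    ggplot2::labs(title = sprintf(
      "cartwheel growth: rate %.3g a.u./s, period %.0f s, size %.3g a.u.",
      object$rate, object$period, object$size))
}

#' @describeIn fit_oscillation Plot the profile and the selected oscillation
#'   model.
#' @param object An `oscillation_fit`.
#' @method autoplot oscillation_fit
#' @export
autoplot.oscillation_fit <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::geom_vline(xintercept = object$centre, linetype = "dashed") +
    ggplot2::labs(title = sprintf(
      "oscillation (%s): amplitude %.3g a.u., centre %.0f s",
      object$model, object$amplitude, object$centre))
}

#' @describeIn correlate_peak_with_sphase Scatter plot with the regression
#'   line and the r / strength annotation.
#' @param object An `sphase_cor`.
#' @method autoplot sphase_cor
#' @export
autoplot.sphase_cor <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$sphase_length,
                               y = .data$peak_centre)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "#b2182b") +
    ggplot2::labs(
      x = "S-phase length (s)", y = "Peak centre (s from CS)",
      title = sprintf("r = %.2f (%s), p = %.2g", object$r,
                      object$strength_label, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_ring Plot the image with the fitted ellipse overlaid.
#' @param object A `ring_fit` (must carry its image).
#' @method autoplot ring_fit
#' @export
autoplot.ring_fit <- function(object, ...) {
  if (is.null(object$image)) abort("this ring_fit carries no image to plot.")
  px <- object$image$pixels
  psize <- object$image$pixel_size
  n <- nrow(px)
  coord <- (seq_len(n) - (n + 1) / 2) * psize
  df <- tidyr::expand_grid(y = coord, x = coord)
  df$value <- as.numeric(px) # column-major: y fastest, matching expand_grid
  ang <- seq(0, 2 * pi, length.out = 200)
  ell <- tibble::tibble(
    x = object$center_x + object$a * cos(ang) * cos(object$theta) -
      object$b * sin(ang) * sin(object$theta),
    y = object$center_y + object$a * cos(ang) * sin(object$theta) +
      object$b * sin(ang) * cos(object$theta))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = ell, colour = "white", linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "a.u.") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("radius %.0f nm, ecc %.2f, w %.0f nm",
                                  object$mean_radius, object$eccentricity,
                                  object$w)) +
    ggplot2::theme_minimal()
}

#' Plot per-embryo recruitment profiles
#'
#' Mean +/- s.d. ribbons for every embryo in a preprocessed profile table.
#'
#' @param profiles Output of [preprocess_tracks()].
#' @return A ggplot object, faceted by embryo.
#' @export
plot_profiles <- function(profiles) {
  check_columns(profiles, c("embryo_id", "time_s", "mean", "sd"), "profiles")
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~embryo_id) +
    ggplot2::labs(x = "Time from CS (s)", y = "Mean intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a photon trace with its threshold
#'
#' @param traces A `pecos_traces` object or numeric count vector.
#' @param threshold Numeric threshold or a `pecos_threshold`.
#' @param trace Which trace to plot (default 1).
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, threshold = NULL, trace = 1) {
  lst <- as_trace_list(traces)
  counts <- lst[[trace]]
  bw <- if (inherits(traces, "pecos_traces")) traces$bin_width else 1
  df <- tibble::tibble(time_s = (seq_along(counts) - 0.5) * bw,
                       counts = counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$counts)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Photon counts / bin") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "pecos_threshold")) threshold$threshold
           else threshold
    p <- p + ggplot2::geom_hline(yintercept = thr, colour = "#b2182b",
                                 linetype = "dashed")
  }
  p
}
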