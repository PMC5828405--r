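# ggplot2 displays for the main result types.

#' @export
autoplot.hu_curve <- function(object, points = NULL, n = 200, ...) {
  x <- seq(object$domain[1], object$domain[2], length.out = n)
  d <- tibble::tibble(rho_zeff = x, hu = poly3_eval(object$coeffs, x))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rho_zeff, y = .data$hu)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(
      x = expression(rho * Z[eff] ~ (g / cm^3)), y = "CBCT number (HU)",
      title = "CBCT number vs density-Zeff product",
      subtitle = sprintf("cubic fit, R² = %.4f%s", object$r_squared,
                         if (object$monotonic) "" else " (non-monotonic!)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, shape = 4, size = 2)
  }
  p
}

#' @export
autoplot.tissue_db <- function(object, ...) {
  t <- object$tissues
  ggplot2::ggplot(t, ggplot2::aes(x = .data$target_rho_zeff)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hu_lo, ymax = .data$hu_hi),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hu_center), linewidth = 0.6) +
    ggplot2::coord_cartesian(ylim = range(t$hu_center) + c(-100, 100)) +
    ggplot2::labs(
      x = expression(rho * Z[eff] ~ (g / cm^3)), y = "CBCT number (HU)",
      title = sprintf("%d dose-equivalent tissues with their HU intervals", nrow(t))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gamma_result <- function(object, ...) {
  ij <- which(!is.na(object$gamma_map), arr.ind = TRUE)
  d <- tibble::tibble(x = ij[, 1], y = ij[, 2], gamma = object$gamma_map[ij])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(2, max(d$gamma)))) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Gamma map (DD %g%%, DTA %g mm): %.1f%% pass",
                      object$dd, object$dta, object$pass_rate),
      x = "pixel (x)", y = "pixel (y)", fill = expression(gamma)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dose_plane <- function(object, ...) {
  ij <- expand.grid(i = seq_len(nrow(object$values)), j = seq_len(ncol(object$values)))
  d <- tibble::tibble(
    x = object$origin[1] + (ij$i - 1) * object$spacing[1],
    y = object$origin[2] + (ij$j - 1) * object$spacing[2],
    dose = as.vector(object$values)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "dose (Gy)") +
    ggplot2::theme_minimal()
}

#' Plot one slice of a volume
#'
#' @param volume An [image_volume()] or [label_volume()].
#' @param z Slice index (1-based along the third axis); default the middle.
#' @return A ggplot.
#' @export
plot_slice <- function(volume, z = NULL) {
  v <- if (inherits(volume, "label_volume")) volume$labels else volume$values
  if (is.null(z)) z <- ceiling(dim(v)[3] / 2)
  sl <- v[, , z]
  ij <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  d <- tibble::tibble(
    x = volume$origin[1] + (ij$i - 1) * volume$spacing[1],
    y = volume$origin[2] + (ij$j - 1) * volume$spacing[2],
    value = as.vector(sl)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = if (inherits(volume, "label_volume")) "label" else "HU",
                  title = sprintf("slice z = %d", z)) +
    ggplot2::theme_minimal()
}
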