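# ggplot2 visualisations.

#' @import ggplot2
NULL

# circle outlines as polygon data
.circle_df <- function(x, y, r, id, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  tibble::tibble(
    x = rep(x, each = n + 1) + rep(r, each = n + 1) * cos(th),
    y = rep(y, each = n + 1) + rep(r, each = n + 1) * sin(th),
    id = rep(id, each = n + 1))
}

#' Plot a cylinder packing
#'
#' Axial view of the substrate tile with cylinders drawn to scale.
#'
#' @param object A `cylinder_packing`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cylinder_packing <- function(object, ...) {
  d <- .circle_df(object$centers[, 1], object$centers[, 2], object$radii,
                  seq_len(nrow(object$centers)))
  ggplot(d, aes(.data$x, .data$y, group = .data$id)) +
    geom_polygon(fill = "grey70", colour = "grey30", linewidth = 0.2) +
    annotate("rect", xmin = 0, xmax = object$tile[1], ymin = 0,
             ymax = object$tile[2], fill = NA, colour = "black",
             linetype = "dashed") +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)",
         title = sprintf("%s packing, φ = %.3f, p = %.3f",
                         object$packing_type, object$phi, object$p)) +
    theme_minimal()
}

#' Plot a diffusion spectrum
#'
#' Measured (or simulated) spectrum points with optional error bars and an
#' optional model curve overlay.
#'
#' @param spectrum Tibble with `frequency_hz`, `D_um2_per_ms`, optionally
#'   `se_um2_per_ms`.
#' @param model Optional tibble of the same shape (e.g. from
#'   [forward_predict()]) drawn as a line.
#' @param D_free Optional free-diffusivity reference line.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, model = NULL, D_free = NULL) {
  g <- ggplot(spectrum, aes(.data$frequency_hz, .data$D_um2_per_ms)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "frequency (Hz)", y = "D (µm²/ms)") +
    theme_minimal()
  if ("se_um2_per_ms" %in% names(spectrum) &&
      any(is.finite(spectrum$se_um2_per_ms)))
    g <- g + geom_errorbar(aes(ymin = .data$D_um2_per_ms - .data$se_um2_per_ms,
                               ymax = .data$D_um2_per_ms + .data$se_um2_per_ms),
                           width = 0.02)
  if (!is.null(model))
    g <- g + geom_line(data = model, colour = "firebrick")
  if (!is.null(D_free))
    g <- g + geom_hline(yintercept = D_free, linetype = "dotted")
  g
}

#' Plot a fitted spectrum
#'
#' Data points with the fitted model curve on a dense frequency grid.
#'
#' @param object An `eas_fit` or `eas_fit_nls`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eas_fit_nls <- function(object, ...) {
  sp <- object$spectrum
  fgrid <- 10^seq(log10(min(sp$frequency_hz)), log10(max(sp$frequency_hz)),
                  length.out = 200)
  om <- hz_to_radms(fgrid)
  D <- if (object$model == "single") eas_spectrum(object$params, om)
       else eas_spectrum_dist(object$params, om)
  plot_spectrum(sp, model = tibble::tibble(frequency_hz = fgrid,
                                           D_um2_per_ms = D))
}

#' @rdname autoplot.eas_fit_nls
#' @export
autoplot.eas_fit <- function(object, ...) {
  fit <- object$nls_init
  fit$params <- object$point
  autoplot.eas_fit_nls(fit)
}

#' Plot a pore segmentation
#'
#' Volume-weighted histogram of effective pore radii.
#'
#' @param object A `pore_segmentation`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pore_segmentation <- function(object, bins = 30, ...) {
  ggplot(object$pores, aes(.data$R_EAS, weight = .data$weight)) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    labs(x = expression(R[EAS] ~ (mu * m)), y = "volume weight") +
    theme_minimal()
}
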