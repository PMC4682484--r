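# broom-style tidiers for the package's result objects.

#' Tidy a cylinder packing
#'
#' @param x A `cylinder_packing`.
#' @param ... Unused.
#' @return A tibble with one row per cylinder (`x`, `y`, `radius`).
#' @export
tidy.cylinder_packing <- function(x, ...) {
  cx <- x$centers[, 1]; cy <- x$centers[, 2]; r <- x$radii
  tibble::tibble(x = cx, y = cy, radius = r)
}

#' @rdname tidy.cylinder_packing
#' @export
glance.cylinder_packing <- function(x, ...) {
  tibble::tibble(packing_type = x$packing_type, n_cylinders = nrow(x$centers),
                 tile_x = x$tile[1], tile_y = x$tile[2],
                 phi = x$phi, phi_max = x$phi_max, p = x$p,
                 L = x$L, R_tilde = x$R_tilde)
}

#' Tidy a pore segmentation
#'
#' @param x A `pore_segmentation`.
#' @param ... Unused.
#' @return `tidy()`: the per-pore tibble (`area`, `R_EAS`, `weight`);
#'   `glance()`: one-row summary with the volume-weighted mean/sd.
#' @export
tidy.pore_segmentation <- function(x, ...) x$pores

#' @rdname tidy.pore_segmentation
#' @export
glance.pore_segmentation <- function(x, ...) {
  tibble::tibble(n_pores = nrow(x$pores),
                 total_eas_area = x$total_eas_area,
                 weighted_mean_R_EAS = .wmean(x$pores$R_EAS, x$pores$weight),
                 weighted_sd_R_EAS = sqrt(.wvar(x$pores$R_EAS, x$pores$weight)),
                 n_degenerate_merged = x$n_degenerate_merged)
}

#' Tidy fitted exchange-model objects
#'
#' @param x An `eas_fit` (Metropolis-Hastings) or `eas_fit_nls` object.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with `estimate` (and `std.error`
#'   for posterior fits); `glance()`: one-row fit summary.
#' @export
tidy.eas_fit <- function(x, ...) {
  tibble::tibble(term = names(x$posterior_mean),
                 estimate = unname(x$posterior_mean),
                 std.error = unname(x$posterior_sd))
}

#' @rdname tidy.eas_fit
#' @export
glance.eas_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_draws = nrow(x$samples),
                 acceptance_rate = x$acceptance_rate,
                 converged = x$converged, seed = x$seed)
}

#' @rdname tidy.eas_fit
#' @export
tidy.eas_fit_nls <- function(x, ...) {
  nm <- if (x$model == "single") c("lambda", "R0", "rho") else
    c("lambda", "R0_mean", "R0_cv", "Rinf")
  tibble::tibble(term = nm, estimate = x$theta)
}

#' @rdname tidy.eas_fit
#' @export
glance.eas_fit_nls <- function(x, ...) {
  tibble::tibble(model = x$model, sse = x$sse, converged = x$converged,
                 n_points = nrow(x$spectrum))
}
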