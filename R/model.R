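# The exchange model for the EAS diffusion spectrum.
#
# D_EAS(w) = f_free D_free + (1 - f_free) D_cyl(R(w), w),   f_free = 1/lambda^2
# with a frequency-dependent effective pore radius
#   R(w) = Rinf + (R0 - Rinf) exp(-Lambda w),   Lambda = R0^2 / (2 D_free),
# i.e. Lambda is the diffusion time for one standard deviation of free
# displacement to reach R0. Particles alternate between free migration
# between pores (flat spectrum) and restriction within an effective cylinder.

#' Exchange-model parameters for the EAS spectrum
#'
#' Bundles the model parameters (free diffusivity, tortuosity, and the zero-
#' and infinite-frequency effective pore radii) and the derived quantities
#' `f_free = 1/lambda^2` and the radius decay constant
#' `Lambda = R0^2 / (2 D_free)` (ms per rad/ms).
#'
#' @param D_free Free diffusion coefficient (um^2/ms), > 0.
#' @param lambda Tortuosity, >= 1.
#' @param R0 Effective pore radius at omega = 0 (um), > 0.
#' @param Rinf Effective pore radius as omega -> Inf (um), 0 < Rinf <= R0.
#' @return An object of class `eas_params`.
#' @examples
#' eas_params(2, 1.6, 0.5, 0.3)
#' @export
eas_params <- function(D_free, lambda, R0, Rinf) {
  if (D_free <= 0) stop("D_free must be positive")
  if (lambda < 1) stop("lambda must be >= 1")
  if (R0 <= 0) stop("R0 must be positive")
  if (Rinf <= 0 || Rinf > R0 * (1 + 1e-12)) stop("need 0 < Rinf <= R0")
  structure(list(D_free = D_free, lambda = lambda, R0 = R0, Rinf = Rinf,
                 f_free = 1 / lambda^2,
                 Lambda_decay = R0^2 / (2 * D_free)),
            class = "eas_params")
}

#' @export
print.eas_params <- function(x, ...) {
  cat(sprintf(
    "<eas_params> D_free = %.3g um^2/ms, lambda = %.4g, R0 = %.4g um, Rinf = %.4g um\n  f_free = %.4g, Lambda = %.4g ms/(rad/ms)\n",
    x$D_free, x$lambda, x$R0, x$Rinf, x$f_free, x$Lambda_decay))
  invisible(x)
}

#' Frequency-dependent effective pore radius
#'
#' Exponential interpolation from `R0` at omega = 0 toward `Rinf` at high
#' frequency at rate `Lambda_decay`:
#' `R(omega) = Rinf + (R0 - Rinf) exp(-Lambda_decay * omega)`.
#'
#' @param omega Angular frequency (rad/ms), >= 0.
#' @param R0,Rinf Limiting radii (um).
#' @param Lambda_decay Decay constant (ms per rad/ms).
#' @return Radius in um.
#' @export
variable_radius <- function(omega, R0, Rinf, Lambda_decay) {
  if (any(omega < 0)) stop("omega must be nonnegative")
  Rinf + (R0 - Rinf) * exp(-Lambda_decay * omega)
}

#' EAS diffusion spectrum of the exchange model
#'
#' `f_free * D_free + (1 - f_free) * D_cyl(R(omega), omega)`, where `D_cyl`
#' is [cylinder_spectrum()] and `R(omega)` is [variable_radius()]. Equals
#' `D_free / lambda^2` at omega = 0 and approaches `D_free` at high
#' frequency; nondecreasing in omega.
#'
#' @param params An [eas_params()] object.
#' @param omega Angular frequency (rad/ms), vectorised.
#' @return D(omega) in um^2/ms.
#' @export
eas_spectrum <- function(params, omega) {
  stopifnot(inherits(params, "eas_params"))
  Rw <- variable_radius(omega, params$R0, params$Rinf, params$Lambda_decay)
  params$f_free * params$D_free +
    (1 - params$f_free) * cylinder_spectrum(Rw, params$D_free, omega)
}

#' Exchange-model parameters with a distribution of pore radii
#'
#' For random packings the zero-frequency radius `R0` follows a gamma
#' distribution (given by mean and standard deviation). The spectrum is
#' formed by volume-weighted averaging of per-pore signal attenuations at a
#' reference diffusion weighting `b_ref` and converting back to an effective
#' diffusivity.
#'
#' @inheritParams eas_params
#' @param R0_mean,R0_sd Mean and sd of the gamma R0 distribution (um), > 0.
#' @param b_ref Reference diffusion weighting (ms/um^2), > 0.
#' @return An object of class `eas_params_dist`.
#' @export
eas_params_dist <- function(D_free, lambda, R0_mean, R0_sd, Rinf, b_ref = 1) {
  if (D_free <= 0) stop("D_free must be positive")
  if (lambda < 1) stop("lambda must be >= 1")
  if (R0_mean <= 0 || R0_sd < 0) stop("R0_mean must be > 0 and R0_sd >= 0")
  if (Rinf <= 0) stop("Rinf must be positive")
  if (b_ref <= 0) stop("b_ref must be positive")
  structure(list(D_free = D_free, lambda = lambda, R0_mean = R0_mean,
                 R0_sd = R0_sd, Rinf = Rinf, b_ref = b_ref,
                 f_free = 1 / lambda^2),
            class = "eas_params_dist")
}

#' @export
print.eas_params_dist <- function(x, ...) {
  cat(sprintf(
    "<eas_params_dist> D_free = %.3g, lambda = %.4g, R0 ~ gamma(mean %.4g, sd %.4g) um, Rinf = %.4g um, b_ref = %.3g\n",
    x$D_free, x$lambda, x$R0_mean, x$R0_sd, x$Rinf, x$b_ref))
  invisible(x)
}

# Gauss-Legendre nodes/weights for the volume-weighted gamma R0 average,
# truncated at the 1e-6 and 1-1e-6 quantiles
.r0_quadrature <- function(R0_mean, R0_sd, n_nodes = 256) {
  shape <- (R0_mean / R0_sd)^2
  scale <- R0_sd^2 / R0_mean
  lo <- qgamma(1e-6, shape = shape, scale = scale)
  hi <- qgamma(1 - 1e-6, shape = shape, scale = scale)
  lo <- max(lo, 1e-8 * (R0_mean + R0_sd))   # keep nodes strictly positive
  gl <- pracma::gaussLegendre(n_nodes, lo, hi)
  w <- gl$w * dgamma(gl$x, shape = shape, scale = scale) * gl$x^2
  list(R0 = gl$x, F = w / sum(w))
}

#' EAS spectrum under a distribution of pore radii
#'
#' Volume-weighted average of per-pore signal attenuations
#' `E(omega) = sum_i F_i exp(-b_ref * D_i(omega))`, converted back via
#' `D = -log(E)/b_ref`. Each pore has its own decay constant
#' `Lambda_i = R0_i^2/(2 D_free)`; the weights `F` are the gamma density
#' times the pore volume (proportional to R0^2), normalised to sum to one.
#' Collapses to [eas_spectrum()] as `R0_sd -> 0`.
#'
#' @param params An [eas_params_dist()] object.
#' @param omega Angular frequency (rad/ms), vectorised.
#' @param n_nodes Quadrature nodes over the R0 distribution.
#' @return D(omega) in um^2/ms.
#' @export
eas_spectrum_dist <- function(params, omega, n_nodes = 256) {
  stopifnot(inherits(params, "eas_params_dist"))
  if (params$R0_sd < 1e-9 * params$R0_mean) {
    sp <- eas_params(params$D_free, params$lambda, params$R0_mean,
                     min(params$Rinf, params$R0_mean))
    return(eas_spectrum(sp, omega))
  }
  q <- .r0_quadrature(params$R0_mean, params$R0_sd, n_nodes)
  f <- params$f_free
  E <- numeric(length(omega))
  Dmat <- matrix(0, length(q$R0), length(omega))
  for (i in seq_along(q$R0)) {
    R0i <- q$R0[i]
    Rinf_i <- min(params$Rinf, R0i)      # per-pore radius cannot rise with w
    Li <- R0i^2 / (2 * params$D_free)
    Rw <- variable_radius(omega, R0i, Rinf_i, Li)
    Dmat[i, ] <- f * params$D_free +
      (1 - f) * cylinder_spectrum(Rw, params$D_free, omega)
  }
  for (j in seq_along(omega)) E[j] <- sum(q$F * exp(-params$b_ref * Dmat[, j]))
  -log(E) / params$b_ref
}

# ---- empirical geometry -> model parameter relations -----------------------

#' Model radii from regular-packing geometry
#'
#' Empirical relations tying the model's limiting radii to the packing
#' geometry. The zero-frequency radius has two regimes:
#' `R0 = max(R_EAS(p = 1), R_EAS(p) - R_EAS(p = 1))` — near abutment the
#' long-time restricted scale stays at the abutting pore radius (the narrow
#' channels add no effective room, so the geometric pore radius would
#' overestimate it), while for open packings it tracks the growing pore
#' radius. The two branches cross at a separation `p0` that falls close to
#' the point where the inter-cylinder gap `2R(p-1)` equals the abutting pore
#' radius. The high-frequency radius is surface-to-volume limited:
#' `Rinf = max(0.7 R_EAS(p = 1), 2 (1 - 1/lambda^2) / (S/V))` — for open
#' packings, the radius of a cylinder whose wall density matches the EAS
#' weighted by the restricted fraction (tending to the cylinder radius `R`
#' in the dilute limit), floored near abutment at a fixed fraction of the
#' abutting pore radius. The floor is calibrated against Monte Carlo fits at
#' tight separations, where straight inter-cylinder channels keep short-time
#' displacements from collapsing with the S/V estimate.
#'
#' @inheritParams pore_radius_regular
#' @return Radius in um.
#' @export
R0_from_geometry <- function(packing_type, p, R) {
  r1 <- pore_radius_regular(packing_type, 1, R)
  rp <- pore_radius_regular(packing_type, p, R)
  pmax(r1, rp - r1)
}

#' @rdname R0_from_geometry
#' @export
Rinf_from_geometry <- function(packing_type, p, R) {
  lam <- tortuosity_regular(packing_type, p)
  sv <- surface_to_volume(packing_type, p, R)
  pmax(0.7 * pore_radius_regular(packing_type, 1, R),
       2 * (1 - 1 / lam^2) / sv)
}

#' Crossover separation of the R0 branches
#'
#' Solves for `p0`, the fractional separation at which the abutting and
#' open-packing branches of the R0 relation are equal, and for `p_star`, the
#' separation at which the inter-cylinder gap `2R(p - 1)` equals the abutting
#' pore radius. The two correspond closely for both regular packings.
#'
#' @param packing_type "square" or "hexagonal".
#' @param n_rays Quadrature rays for the pore radius.
#' @return A list with `p0`, `p_star` and their relative difference.
#' @export
r0_branch_crossover <- function(packing_type, n_rays = 8192) {
  r1 <- pore_radius_regular(packing_type, 1, 1, n_rays)
  f <- function(p) pore_radius_regular(packing_type, p, 1, n_rays) - 2 * r1
  p0 <- uniroot(f, c(1.0001, 4), tol = 1e-10)$root
  p_star <- 1 + r1 / 2
  list(p0 = p0, p_star = p_star,
       rel_diff = abs(p0 - p_star) / p_star)
}

#' Forward-model prediction for a regular packing
#'
#' Chains the geometric relations — tortuosity, `R0`, `Rinf` — into the
#' exchange model and evaluates the predicted EAS spectrum on a frequency
#' grid. Only regular packings have a forward prediction; random packings
#' are handled by fitting the distribution model to data.
#'
#' @param packing A `cylinder_packing` of type square/hexagonal, or NULL if
#'   `packing_type`, `R_tilde` and `p` are given.
#' @param freq_hz Frequency grid in Hz.
#' @param D_free Free diffusivity (um^2/ms).
#' @param packing_type,R_tilde,p Alternative scalar descriptor.
#' @return A tibble with `frequency_hz` and `D_um2_per_ms`; the underlying
#'   [eas_params()] object is attached as attribute `"params"`.
#' @export
forward_predict <- function(packing = NULL, freq_hz, D_free = 2,
                            packing_type = NULL, R_tilde = NULL, p = NULL) {
  if (!is.null(packing)) {
    stopifnot(inherits(packing, "cylinder_packing"))
    if (!packing$packing_type %in% c("square", "hexagonal"))
      stop("forward prediction is defined for regular packings only")
    packing_type <- packing$packing_type
    p <- packing$p
    R <- packing$radii[1]
  } else {
    packing_type <- match.arg(packing_type, c("square", "hexagonal"))
    R <- switch(packing_type,
                square = R_tilde * sqrt(pi / (4 - pi)),
                hexagonal = R_tilde * sqrt(pi / (2 * sqrt(3) - pi)))
  }
  lam <- tortuosity_regular(packing_type, p)
  params <- eas_params(D_free, lam,
                       R0 = R0_from_geometry(packing_type, p, R),
                       Rinf = Rinf_from_geometry(packing_type, p, R))
  omega <- hz_to_radms(freq_hz)
  out <- tibble::tibble(frequency_hz = freq_hz,
                        D_um2_per_ms = eas_spectrum(params, omega))
  attr(out, "params") <- params
  out
}
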