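# The restricted-cylinder diffusion spectrum.
#
# For impermeable cylinders of radius R the velocity power spectrum of the
# transverse displacement has the mode expansion
#   D(w) = sum_k [2 D0 / (mu_k^2 - 1)] * w^2 / (w^2 + l_k^2),
#   l_k = mu_k^2 D0 / R^2,
# where mu_k are the positive roots of J1'(x) = 0. The weights satisfy
# sum_k 2/(mu_k^2 - 1) = 1 (so D -> D0 at high frequency) and the summed
# displacement variance is R^2/4, the variance of one coordinate over a disc.

# positive roots of J1'(x) = 0, computed on demand and cached
.j1p_roots <- function(n) {
  have <- .easpec_cache$j1p
  if (!is.null(have) && length(have) >= n) return(have[seq_len(n)])
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  start <- if (is.null(have)) 1L else length(have) + 1L
  roots <- c(have, numeric(n - length(have)))
  for (k in start:n) {
    guess <- (k - 0.25) * pi     # J1' zeros approach (k - 1/4) pi from below
    lo <- guess - 0.45 * pi; hi <- guess + 0.2 * pi
    if (k == 1) { lo <- 1.2; hi <- 2.5 }
    roots[k] <- uniroot(f, c(lo, hi), tol = 1e-13)$root
  }
  .easpec_cache$j1p <- roots
  roots
}

#' Diffusion spectrum of an impermeable cylinder
#'
#' Closed-form restricted diffusion spectrum for particles inside an
#' impermeable cylinder of radius `R`, measured transverse to its axis: a sum
#' of Lorentzian-type modes at rates `mu_k^2 D_free / R^2` with positive
#' weights `2 D_free / (mu_k^2 - 1)`, where `mu_k` are the positive roots of
#' the derivative of the Bessel function J1. `D(0) = 0` (restriction) and
#' `D -> D_free` as `omega -> Inf`. The series is truncated once the next
#' mode's relative contribution falls below `tol`.
#'
#' @param R Cylinder radius (um), > 0.
#' @param D_free Free diffusion coefficient (um^2/ms), > 0.
#' @param omega Angular frequency (rad/ms), >= 0; vectorised.
#' @param tol Relative truncation tolerance for the mode sum.
#' @return D(omega) in um^2/ms, same length as `omega`.
#' @examples
#' cylinder_spectrum(2, 2, 0)        # restricted: zero at omega = 0
#' cylinder_spectrum(2, 2, 1e6)      # -> D_free at high frequency
#' @export
cylinder_spectrum <- function(R, D_free, omega, tol = 1e-8) {
  if (any(R <= 0)) stop("R must be positive")
  if (D_free <= 0) stop("D_free must be positive")
  if (any(omega < 0)) stop("omega must be nonnegative")
  if (length(R) == 1) R <- rep(R, length(omega))
  if (length(R) != length(omega)) stop("R must be scalar or match omega")
  D <- numeric(length(omega))
  chunk <- 256L
  k0 <- 0L
  active <- omega > 0
  while (any(active)) {
    mu <- .j1p_roots(k0 + chunk)[(k0 + 1):(k0 + chunk)]
    wgt <- 2 * D_free / (mu^2 - 1)
    for (i in which(active)) {
      lk <- mu^2 * D_free / R[i]^2
      D[i] <- D[i] + sum(wgt * omega[i]^2 / (omega[i]^2 + lk^2))
    }
    k0 <- k0 + chunk
    mu_next <- .j1p_roots(k0 + 1L)[k0 + 1L]
    for (i in which(active)) {
      lk1 <- mu_next^2 * D_free / R[i]^2
      nxt <- 2 * D_free / (mu_next^2 - 1) * omega[i]^2 / (omega[i]^2 + lk1^2)
      if (nxt < tol * D[i]) active[i] <- FALSE
    }
    if (k0 >= 20000L) break
  }
  D
}
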