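# Tortuosity of the space around regular arrays of insulating cylinders,
# by the classical multipole (Rayleigh) method with lattice sums.
#
# The zero-frequency EAS diffusivity follows from the effective transverse
# conductivity sigma* of a composite with perfectly insulating cylinders:
# for tracers confined to the matrix phase,
#   D(0)/D_free = sigma*/(sigma0 (1 - phi)),   lambda^2 = (1 - phi)/sigma*.
# The dilute limit is lambda^2 = 1 + phi. sigma* is obtained by expanding the
# potential around one cylinder in odd multipoles, closing the system with
# lattice sums S_n (S_2 = pi/A; S_n by direct summation for n >= 4).

.lattice_sums <- function(packing_type, nmax, M = 150) {
  key <- sprintf("lsum_%s_%d", packing_type, nmax)
  have <- .easpec_cache[[key]]
  if (!is.null(have)) return(have)
  if (packing_type == "square") {
    a1 <- c(1, 0); a2 <- c(0, 1)
  } else {
    a1 <- c(1, 0); a2 <- c(0.5, sqrt(3) / 2)
  }
  A <- abs(a1[1] * a2[2] - a1[2] * a2[1])
  i <- rep(-M:M, times = 2 * M + 1); j <- rep(-M:M, each = 2 * M + 1)
  keep <- !(i == 0 & j == 0)
  z <- complex(real = i[keep] * a1[1] + j[keep] * a2[1],
               imaginary = i[keep] * a1[2] + j[keep] * a2[2])
  S <- numeric(nmax)
  S[2] <- pi / A
  for (n in seq(4, nmax, by = 2)) S[n] <- Re(sum(z^(-n)))
  out <- list(S = S, A = A)
  .easpec_cache[[key]] <- out
  out
}

.sigma_eff_regular <- function(packing_type, p, lmax = 121) {
  ls <- .lattice_sums(packing_type, 2 * lmax + 2)
  L <- 2 * p                         # lattice spacing for unit cylinder radius
  A <- ls$A * L^2
  odd <- seq(1, lmax, by = 2)
  n <- length(odd)
  S_scaled <- ls$S / L^(seq_along(ls$S))  # S_n for spacing L
  Mt <- matrix(0, n, n)
  for (ii in seq_len(n)) for (jj in seq_len(n)) {
    l <- odd[ii]; m <- odd[jj]
    Mt[ii, jj] <- choose(l + m - 1, m) * S_scaled[l + m]
  }
  diag(Mt) <- diag(Mt) + 1           # A_l = B_l R^{-2l}, R = 1
  rhs <- c(-1, rep(0, n - 1))
  B <- solve(Mt, rhs)
  as.numeric(1 + 2 * pi * B[1] / A)
}

#' Tortuosity of a regular cylinder array
#'
#' Zero-frequency tortuosity `lambda = sqrt(D_free / D(0))` of the space
#' around a square or hexagonal array of impermeable cylinders at fractional
#' separation `p`, from the classical multipole expansion with lattice sums.
#' `lambda -> 1` as `p -> Inf` and diverges as the cylinders come into
#' contact (`p -> 1`), where the EAS seals into isolated pores.
#'
#' @param packing_type "square" or "hexagonal".
#' @param p Fractional separation, >= 1; vectorised.
#' @param lmax Multipole truncation order (odd orders up to `lmax`).
#' @return Tortuosity lambda (dimensionless, >= 1).
#' @export
tortuosity_regular <- function(packing_type, p, lmax = 121) {
  packing_type <- match.arg(packing_type, c("square", "hexagonal"))
  if (any(p < 1)) stop("p must be >= 1")
  pm <- phi_max(packing_type)
  vapply(p, function(pi1) {
    phi <- pm / pi1^2
    s <- .sigma_eff_regular(packing_type, pi1, lmax)
    s <- max(s, 1e-8)                # truncated expansion at contact
    sqrt((1 - phi) / s)
  }, numeric(1))
}

#' Invert the tortuosity relation
#'
#' Finds the fractional separation `p` of a regular packing whose tortuosity
#' equals `lambda`. Errors when `lambda` is at or below 1 (no finite packing)
#' or above the value reached at contact.
#'
#' @param packing_type "square" or "hexagonal".
#' @param lambda Tortuosity, > 1.
#' @param p_hi Upper search bound for p.
#' @return Fractional separation p.
#' @export
p_from_tortuosity <- function(packing_type, lambda, p_hi = 200) {
  packing_type <- match.arg(packing_type, c("square", "hexagonal"))
  if (lambda <= 1 + 1e-10)
    stop("out-of-model: lambda <= 1 has no finite packing separation")
  lam_lo <- tortuosity_regular(packing_type, p_hi)
  lam_hi <- tortuosity_regular(packing_type, 1)
  if (lambda > lam_hi)
    stop(sprintf("out-of-model: lambda = %.3g exceeds the contact value %.3g",
                 lambda, lam_hi))
  if (lambda < lam_lo)
    stop(sprintf("out-of-model: lambda = %.3g below the dilute bound %.3g at p = %g",
                 lambda, lam_lo, p_hi))
  uniroot(function(p) tortuosity_regular(packing_type, p) - lambda,
          c(1, p_hi), tol = 1e-10)$root
}
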