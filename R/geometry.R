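# Periodic 2D substrates of packed parallel cylinders (axial cross-section).
# Lengths are in micrometres throughout; the tile is the half-open box
# [0, Wx) x [0, Wy) and all pair distances use the minimum-image convention.

#' Construct a cylinder packing object
#'
#' Low-level constructor; use [make_square_packing()], [make_hexagonal_packing()]
#' or [make_random_packing()] instead.
#'
#' @param packing_type One of "square", "hexagonal", "random".
#' @param centers Two-column matrix of cylinder centres (um).
#' @param radii Cylinder radii (um), recycled to the number of centres.
#' @param tile Length-2 numeric, periodic box dimensions (um).
#' @param L Centre-to-centre separation (um), regular packings only.
#' @param R_tilde Equivalent radius of the abutting EAS area (um), regular only.
#' @param phi_max Maximal area fraction for this packing type/distribution.
#' @param seed,dist Bookkeeping for random packings.
#' @return An object of class `cylinder_packing`.
#' @keywords internal
new_cylinder_packing <- function(packing_type, centers, radii, tile,
                                 L = NA_real_, R_tilde = NA_real_,
                                 phi_max, seed = NA_integer_, dist = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  radii <- rep_len(as.numeric(radii), nrow(centers))
  phi <- sum(pi * radii^2) / prod(tile)
  obj <- structure(list(
    packing_type = packing_type,
    centers = centers,
    radii = radii,
    tile = as.numeric(tile),
    L = L,
    R_tilde = R_tilde,
    phi = phi,
    phi_max = phi_max,
    p = sqrt(phi_max / phi),
    seed = seed,
    dist = dist
  ), class = "cylinder_packing")
  obj
}

#' @export
print.cylinder_packing <- function(x, ...) {
  cat(sprintf(
    "<cylinder_packing> %s: %d cylinder(s), tile %.3g x %.3g um\n  phi = %.4f, phi_max = %.4f, p = %.4f\n",
    x$packing_type, nrow(x$centers), x$tile[1], x$tile[2], x$phi, x$phi_max, x$p))
  invisible(x)
}

# minimum-image pair gap ratios; used by the overlap validator and step sizing
.pair_gaps <- function(packing) {
  n <- nrow(packing$centers)
  if (n < 2) return(numeric(0))
  W <- packing$tile[1]; H <- packing$tile[2]
  x <- packing$centers[, 1]; y <- packing$centers[, 2]
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  dx <- dx - W * round(dx / W); dy <- dy - H * round(dy / H)
  d <- sqrt(dx^2 + dy^2)
  s <- outer(packing$radii, packing$radii, "+")
  up <- upper.tri(d)
  d[up] - s[up]
}

#' Minimum inter-cylinder gap of a substrate
#'
#' Smallest surface-to-surface distance between any two cylinders under the
#' periodic minimum-image convention. For a regular packing this equals
#' `2 R (p - 1)`. Also considers each cylinder against its own periodic
#' images (relevant for a single-cylinder tile).
#'
#' @param packing A `cylinder_packing`.
#' @return Gap in um (can be ~0 for abutting packings).
#' @export
min_gap <- function(packing) {
  gaps <- .pair_gaps(packing)
  # self-image gaps: nearest image of a cylinder to itself is one tile away
  self_gap <- min(packing$tile) - 2 * max(packing$radii)
  min(c(gaps, self_gap))
}

#' Validate the geometric invariants of a packing
#'
#' Checks periodic non-overlap and consistency of the stored area fraction.
#'
#' @param packing A `cylinder_packing`.
#' @param tol Overlap tolerance (um).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_packing <- function(packing, tol = 1e-9) {
  gaps <- .pair_gaps(packing)
  if (length(gaps) && min(gaps) < -tol)
    stop("cylinder overlap detected (worst gap ", format(min(gaps)), " um)")
  phi <- sum(pi * packing$radii^2) / prod(packing$tile)
  if (abs(phi - packing$phi) > 1e-12 * max(1, phi))
    stop("stored phi inconsistent with geometry")
  invisible(TRUE)
}

#' Regular packings of uniform cylinders
#'
#' Build a periodic square or hexagonal (triangular-lattice) packing of
#' uniform cylinders. The spatial scale is set by `R_tilde`, the radius of a
#' circle with the same area as the extra-cylinder space (EAS) of one unit
#' cell in the *abutting* configuration (p = 1); the packing density is set by
#' the fractional separation `p = L / (2R)`, the centre-to-centre separation
#' over the cylinder diameter.
#'
#' For square packing the abutting EAS area per cell is `(4 - pi) R^2`, so
#' `R = R_tilde * sqrt(pi / (4 - pi))`; for hexagonal packing it is
#' `(2 sqrt(3) - pi) R^2` per cylinder, so `R = R_tilde * sqrt(pi / (2 sqrt(3) - pi))`.
#'
#' @param R_tilde Equivalent abutting EAS radius (um), > 0.
#' @param p Fractional separation, >= 1 (1 = abutting).
#' @return A `cylinder_packing`. The square tile holds one cylinder; the
#'   hexagonal tile is the rectangular `L x sqrt(3) L` cell holding two.
#' @examples
#' pk <- make_square_packing(1, 1)
#' pk$phi           # pi/4, the abutting square maximum
#' @export
make_square_packing <- function(R_tilde, p) {
  stopifnot(is.numeric(R_tilde), is.numeric(p))
  if (R_tilde <= 0) stop("R_tilde must be positive")
  if (p < 1) stop("p must be >= 1")
  R <- R_tilde * sqrt(pi / (4 - pi))
  L <- 2 * R * p
  new_cylinder_packing("square",
                       centers = matrix(c(L / 2, L / 2), ncol = 2),
                       radii = R, tile = c(L, L), L = L, R_tilde = R_tilde,
                       phi_max = pi / 4)
}

#' @rdname make_square_packing
#' @export
make_hexagonal_packing <- function(R_tilde, p) {
  stopifnot(is.numeric(R_tilde), is.numeric(p))
  if (R_tilde <= 0) stop("R_tilde must be positive")
  if (p < 1) stop("p must be >= 1")
  R <- R_tilde * sqrt(pi / (2 * sqrt(3) - pi))
  L <- 2 * R * p
  tile <- c(L, sqrt(3) * L)
  centers <- rbind(c(L / 4, sqrt(3) * L / 4),
                   c(3 * L / 4, 3 * sqrt(3) * L / 4))
  new_cylinder_packing("hexagonal", centers, R, tile, L = L,
                       R_tilde = R_tilde, phi_max = pi / (2 * sqrt(3)))
}

#' Gamma radius distribution for random packings
#'
#' Describes the cylinder radius distribution of a random packing: a gamma
#' distribution with given shape and scale, optionally scaled by an integer
#' multiplier (x1, x2, x3 of the base radii). Defaults approximate the axon
#' radius distribution of the genu of the human corpus callosum; they are a
#' documented stand-in and should be supplied explicitly when accuracy
#' matters.
#'
#' @param shape Gamma shape parameter (> 0), dimensionless.
#' @param scale Gamma scale parameter (um, > 0).
#' @param multiplier Radius multiplier (>= 1).
#' @return An object of class `radius_distribution`.
#' @export
radius_distribution <- function(shape = 3.3, scale = 0.18, multiplier = 1) {
  if (shape <= 0 || scale <= 0 || multiplier <= 0)
    stop("shape, scale and multiplier must be positive")
  structure(list(shape = shape, scale = scale, multiplier = multiplier),
            class = "radius_distribution")
}

#' @export
print.radius_distribution <- function(x, ...) {
  cat(sprintf("<radius_distribution> gamma(shape = %.3g, scale = %.3g um) x %g\n",
              x$shape, x$scale, x$multiplier))
  invisible(x)
}

.sample_radii <- function(dist, n) {
  dist$multiplier * rgamma(n, shape = dist$shape, scale = dist$scale)
}

#' Random periodic packing with gamma-distributed radii
#'
#' Draws `n_cylinders` radii from `dist`, sizes the periodic tile so the
#' cylinder area fraction equals `phi`, and places the cylinders by random
#' sequential addition (largest first). If sequential addition cannot place
#' every cylinder (dense packings), the placement is completed by
#' collective-rearrangement relaxation: overlapping pairs are pushed apart
#' until the configuration is feasible. The result is deterministic for a
#' given seed.
#'
#' @param dist A [radius_distribution()].
#' @param phi Target cylinder area fraction, 0 < phi <= phi_max.
#' @param n_cylinders Number of cylinders in the base tile.
#' @param seed Integer seed.
#' @param phi_max Maximal area fraction for this distribution. Defaults to an
#'   operational estimate from [phi_max()] (cached); pass a value to skip the
#'   estimation.
#' @param rsa_tries Placement attempts per cylinder before relaxation.
#' @param relax_sweeps Relaxation sweep budget.
#' @return A `cylinder_packing`.
#' @export
make_random_packing <- function(dist, phi, n_cylinders = 500, seed = 1,
                                phi_max = NULL, rsa_tries = 2000,
                                relax_sweeps = 20000) {
  stopifnot(inherits(dist, "radius_distribution"))
  if (n_cylinders < 1) stop("n_cylinders must be >= 1")
  if (is.null(phi_max)) phi_max <- phi_max("random", dist)
  if (phi <= 0 || phi > phi_max)
    stop(sprintf("phi must be in (0, %.3f] for this distribution", phi_max))
  set.seed(seed)
  radii <- .sample_radii(dist, n_cylinders)
  W <- sqrt(sum(pi * radii^2) / phi)
  res <- .pack_disks_cpp(radii, W, as.integer(rsa_tries), as.integer(relax_sweeps))
  if (!res$feasible) {
    achieved <- phi * res$min_gap_ratio^2
    stop(sprintf(
      "packing infeasible at phi = %.3f after %d relaxation sweeps (achieved phi ~ %.3f)",
      phi, res$sweeps, achieved))
  }
  new_cylinder_packing("random", res$centers, radii, c(W, W),
                       phi_max = phi_max, seed = as.integer(seed), dist = dist)
}

#' Maximal cylinder area fraction of a packing type
#'
#' `pi/4` for square packing and `pi/(2 sqrt(3))` for hexagonal packing
#' (abutting lattices). For random packings with a radius distribution no
#' closed form exists; the value is defined operationally as the densest
#' fraction the package's own packer achieves under a fixed bisection
#' schedule, and is cached per distribution.
#'
#' @param packing_type "square", "hexagonal" or "random".
#' @param dist A [radius_distribution()]; required for `"random"`.
#' @param n_cylinders,seed,tol Probe settings for the operational estimate.
#' @return Dimensionless area fraction.
#' @examples
#' phi_max("square")      # 0.7853982
#' phi_max("hexagonal")   # 0.9068996
#' @export
phi_max <- function(packing_type, dist = NULL, n_cylinders = 200, seed = 1,
                    tol = 0.005) {
  packing_type <- match.arg(packing_type, c("square", "hexagonal", "random"))
  if (packing_type == "square") return(pi / 4)
  if (packing_type == "hexagonal") return(pi / (2 * sqrt(3)))
  if (is.null(dist)) stop("dist is required for random packings")
  key <- sprintf("phimax_%.6g_%.6g_%.6g_%d_%d", dist$shape, dist$scale,
                 dist$multiplier, n_cylinders, seed)
  if (!is.null(.easpec_cache[[key]])) return(.easpec_cache[[key]])
  # note: the achievable fraction is scale-free (multiplier drops out)
  probe <- function(phi) {
    set.seed(seed)
    radii <- .sample_radii(dist, n_cylinders)
    W <- sqrt(sum(pi * radii^2) / phi)
    res <- .pack_disks_cpp(radii, W, 500L, 8000L)
    isTRUE(res$feasible)
  }
  lo <- 0.70; hi <- 0.90
  if (!probe(lo)) lo <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) lo <- mid else hi <- mid
  }
  .easpec_cache[[key]] <- lo
  lo
}

#' Fractional separation of a packing
#'
#' `p = sqrt(phi_max / phi)`: the linear margin by which a packing is looser
#' than its densest arrangement. `p = 1` for abutting cylinders; for regular
#' packings `p` also equals the centre-to-centre separation over the cylinder
#' diameter, `L / (2R)`.
#'
#' @param phi Cylinder area fraction, 0 < phi <= phi_max.
#' @param phi_max Maximal area fraction.
#' @return Dimensionless `p >= 1`.
#' @export
fractional_separation <- function(phi, phi_max) {
  if (any(phi <= 0)) stop("phi must be positive")
  if (any(phi > phi_max + 1e-12)) stop("phi exceeds phi_max")
  sqrt(phi_max / phi)
}

# ---- pore geometry of regular packings -------------------------------------

# vectorised first-intersection distance of rays from (0,0) with a circle
.ray_circle_dist <- function(ux, uy, cx, cy, r) {
  tc <- ux * cx + uy * cy
  d2 <- cx^2 + cy^2 - tc^2
  disc <- r^2 - d2
  t <- tc - sqrt(pmax(disc, 0))
  t[disc < 0 | t < 1e-12] <- Inf
  t
}

# distance of rays from origin to the line {x : n.x = h}, h > 0
.ray_line_dist <- function(ux, uy, nx, ny, h) {
  den <- ux * nx + uy * ny
  t <- h / den
  t[den <= 1e-15] <- Inf
  t
}

#' Effective pore radius of a regular packing
#'
#' Mean distance, over directions from the pore centre, to the nearest
#' cylinder wall, with rays capped at the straight throat lines bounding the
#' pore cell (for square packing the pore is the unit cell between four
#' cylinders; for hexagonal packing it is the curvilinear triangle between
#' three). At p = 1 the throat lines touch the walls, so the cap has no
#' effect. Computed by dense angular quadrature.
#'
#' @param packing_type "square" or "hexagonal".
#' @param p Fractional separation, >= 1.
#' @param R Cylinder radius (um), > 0.
#' @param n_rays Number of quadrature rays.
#' @return Effective pore radius R_EAS in um.
#' @export
pore_radius_regular <- function(packing_type, p, R, n_rays = 4096) {
  packing_type <- match.arg(packing_type, c("square", "hexagonal"))
  if (any(p < 1)) stop("p must be >= 1")
  if (any(R <= 0)) stop("R must be positive")
  if (length(p) > 1)
    return(vapply(p, pore_radius_regular, numeric(1),
                  packing_type = packing_type, R = R, n_rays = n_rays))
  L <- 2 * R * p
  th <- (seq_len(n_rays) - 0.5) / n_rays * 2 * pi
  ux <- cos(th); uy <- sin(th)
  d <- rep(Inf, n_rays)
  if (packing_type == "square") {
    for (sx in c(-1, 1)) for (sy in c(-1, 1))
      d <- pmin(d, .ray_circle_dist(ux, uy, sx * L / 2, sy * L / 2, R))
    d <- pmin(d, .ray_line_dist(ux, uy, 1, 0, L / 2),
              .ray_line_dist(ux, uy, -1, 0, L / 2),
              .ray_line_dist(ux, uy, 0, 1, L / 2),
              .ray_line_dist(ux, uy, 0, -1, L / 2))
  } else {
    verts <- rbind(c(0, 0), c(L, 0), c(L / 2, L * sqrt(3) / 2))
    ctr <- colMeans(verts)
    for (i in 1:3)
      d <- pmin(d, .ray_circle_dist(ux, uy, verts[i, 1] - ctr[1],
                                    verts[i, 2] - ctr[2], R))
    for (i in 1:3) {
      a <- verts[i, ] - ctr; b <- verts[(i %% 3) + 1, ] - ctr
      nrm <- c(-(b[2] - a[2]), b[1] - a[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      h <- sum(a * nrm)
      if (h < 0) { nrm <- -nrm; h <- -h }
      d <- pmin(d, .ray_line_dist(ux, uy, nrm[1], nrm[2], h))
    }
  }
  mean(d)
}

#' Surface-to-volume ratio of the EAS of a regular packing
#'
#' Cylinder perimeter per unit EAS cross-sectional area in one unit cell:
#' `2 pi R / (L^2 - pi R^2)` for square packing and
#' `2 pi R / ((sqrt(3)/2) L^2 - pi R^2)` per cylinder for hexagonal packing,
#' with `L = 2 R p`.
#'
#' @inheritParams pore_radius_regular
#' @return S/V in 1/um.
#' @export
surface_to_volume <- function(packing_type, p, R) {
  packing_type <- match.arg(packing_type, c("square", "hexagonal"))
  if (any(p < 1)) stop("p must be >= 1")
  if (any(R <= 0)) stop("R must be positive")
  L <- 2 * R * p
  eas_area <- switch(packing_type,
    square = L^2 - pi * R^2,
    hexagonal = (sqrt(3) / 2) * L^2 - pi * R^2)
  2 * pi * R / eas_area
}
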