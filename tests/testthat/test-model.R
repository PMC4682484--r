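test_that("parameter objects enforce their invariants", {
  p <- eas_params(2, 1.5, 0.5, 0.3)
  expect_equal(p$f_free, 1 / 1.5^2)
  expect_equal(p$Lambda_decay, 0.5^2 / (2 * 2))
  expect_error(eas_params(2, 0.9, 0.5, 0.3), "lambda")
  expect_error(eas_params(2, 1.5, 0.5, 0.6), "Rinf")
  expect_error(eas_params(-1, 1.5, 0.5, 0.3), "D_free")
  expect_error(eas_params_dist(2, 1.5, -1, 0.1, 0.3), "R0_mean")
})

test_that("variable radius interpolates between its limits", {
  expect_equal(variable_radius(0, 0.5, 0.2, 0.1), 0.5)
  expect_equal(variable_radius(1e9, 0.5, 0.2, 0.1), 0.2)
  expect_equal(variable_radius(c(0, 3, 1e9), 0.4, 0.4, 0.1),
               rep(0.4, 3))   # degenerate R0 = Rinf
})

test_that("the exchange model obeys its exact limits and monotonicity", {
  par <- eas_params(2, 1.6, 0.6, 0.25)
  # D(0) = D_free / lambda^2
  expect_equal(eas_spectrum(par, 0), 2 / 1.6^2, tolerance = 1e-8)
  # high-frequency limit D -> D_free
  expect_equal(eas_spectrum(par, 1e7) / 2, 1, tolerance = 1e-3)
  # lambda = 1: free diffusion at every frequency
  flat <- eas_params(2, 1, 0.6, 0.25)
  wg <- 10^seq(-1, 3, length.out = 50)
  expect_equal(eas_spectrum(flat, wg), rep(2, 50), tolerance = 1e-12)
  # nondecreasing, bounded by [0, D_free]
  D <- eas_spectrum(par, wg)
  expect_true(all(diff(D) >= -1e-10))
  expect_true(all(D >= 0 & D <= 2 + 1e-10))
})

test_that("model spectra are invariant under the diffusion scaling of lengths", {
  par <- eas_params(2, 1.6, 0.6, 0.25)
  s <- 3
  par_s <- eas_params(2, 1.6, s * 0.6, s * 0.25)
  wg <- 10^seq(-1, 3, length.out = 40)
  expect_equal(eas_spectrum(par_s, wg), eas_spectrum(par, s^2 * wg),
               tolerance = 1e-8)
})

test_that("the distribution spectrum collapses, brackets, and shows a Jensen gap", {
  wg <- 10^seq(-1, 2.5, length.out = 30)
  par <- eas_params(2, 1.5, 0.5, 0.3)
  # point mass equals the single-radius model
  pd0 <- eas_params_dist(2, 1.5, 0.5, 0, 0.3)
  expect_equal(eas_spectrum_dist(pd0, wg), eas_spectrum(par, wg),
               tolerance = 1e-10)
  # attenuation averaging bounds: between the per-pore minimum and maximum
  pd <- eas_params_dist(2, 1.5, 0.5, 0.15, 0.3)
  q <- easpec:::.r0_quadrature(0.5, 0.15, 256)
  Dp <- t(vapply(q$R0, function(R0)
    eas_spectrum(eas_params(2, 1.5, R0, min(0.3, R0)), wg),
    numeric(length(wg))))
  D <- eas_spectrum_dist(pd, wg)
  expect_true(all(D >= apply(Dp, 2, min) - 1e-9 &
                    D <= apply(Dp, 2, max) + 1e-9))
  # attenuation averaging depends on b (Jensen gap), vanishing as sd -> 0
  pd_b2 <- eas_params_dist(2, 1.5, 0.5, 0.15, 0.3, b_ref = 2)
  gap_wide <- max(abs(eas_spectrum_dist(pd, wg) - eas_spectrum_dist(pd_b2, wg)))
  expect_gt(gap_wide, 1e-4)
  pd_n <- eas_params_dist(2, 1.5, 0.5, 1e-4, 0.3, b_ref = 1)
  pd_n2 <- eas_params_dist(2, 1.5, 0.5, 1e-4, 0.3, b_ref = 2)
  gap_narrow <- max(abs(eas_spectrum_dist(pd_n, wg) - eas_spectrum_dist(pd_n2, wg)))
  expect_lt(gap_narrow, 1e-7)
  # direct quadrature oracle: dense trapezoid over the gamma R0 distribution
  shape <- (0.5 / 0.15)^2; scale <- 0.15^2 / 0.5
  r <- seq(qgamma(1e-7, shape, scale = 1) * scale,
           qgamma(1 - 1e-7, shape, scale = 1) * scale, length.out = 1500)
  f <- dgamma(r, shape, scale = scale) * r^2
  f <- f / sum(f)
  wg_sub <- wg[seq(1, length(wg), by = 4)]
  Dp <- t(vapply(r, function(R0)
    eas_spectrum(eas_params(2, 1.5, R0, min(0.3, R0)), wg_sub),
    numeric(length(wg_sub))))
  E_or <- as.numeric(f %*% exp(-1 * Dp))
  expect_equal(eas_spectrum_dist(pd, wg_sub), -log(E_or), tolerance = 2e-3)
})

test_that("geometric radius relations behave as the packing opens", {
  for (type in c("square", "hexagonal")) {
    R <- 0.8
    r1 <- pore_radius_regular(type, 1, R)
    # abutting: R0 equals the abutting pore radius
    expect_equal(R0_from_geometry(type, 1, R), r1, tolerance = 1e-10)
    # both radii scale linearly with R at fixed p
    for (p in c(1, 1.2, 1.8)) {
      expect_equal(R0_from_geometry(type, p, 2 * R),
                   2 * R0_from_geometry(type, p, R), tolerance = 1e-8)
      expect_equal(Rinf_from_geometry(type, p, 2 * R),
                   2 * Rinf_from_geometry(type, p, R), tolerance = 1e-6)
    }
    # Rinf never exceeds R0 over the working range
    for (p in c(1, 1.06, 1.12, 1.5, 2, 4)) {
      expect_lte(Rinf_from_geometry(type, p, R),
                 R0_from_geometry(type, p, R) + 1e-9)
    }
    # unique branch crossover in (1, 2), near the gap = abutting-pore-radius point
    cx <- r0_branch_crossover(type, n_rays = 4096)
    expect_gt(cx$p0, 1); expect_lt(cx$p0, 2)
    expect_lt(cx$rel_diff, 0.06)
  }
})

test_that("forward prediction obeys endpoint limits and length-frequency scaling", {
  freqs <- 10^seq(1.5, 5, length.out = 25)
  fp <- forward_predict(packing_type = "square", R_tilde = 0.5, p = 1.12,
                        freq_hz = freqs)
  par <- attr(fp, "params")
  expect_equal(fp$D_um2_per_ms[1], 2 / par$lambda^2, tolerance = 1e-3)
  expect_equal(forward_predict(packing_type = "square", R_tilde = 0.5,
                               p = 1.12, freq_hz = 1e10)$D_um2_per_ms / 2,
               1, tolerance = 1e-3)
  # scaling: s x lengths  <=>  frequencies / s^2
  s <- 2
  fp_s <- forward_predict(packing_type = "square", R_tilde = 0.5 * s,
                          p = 1.12, freq_hz = freqs / s^2)
  expect_equal(fp_s$D_um2_per_ms, fp$D_um2_per_ms, tolerance = 1e-8)
  # no forward prediction for random packings
  pk <- make_random_packing(radius_distribution(), 0.4, 50, seed = 1,
                            phi_max = test_phi_max())
  expect_error(forward_predict(pk, freqs), "regular")
})
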