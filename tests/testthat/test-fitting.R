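test_that("NLS recovers exchange-model parameters from noiseless spectra", {
  freqs <- 10^seq(2, 4.8, length.out = 14)
  for (lam in c(1.2, 1.6)) for (R0 in c(0.3, 1)) {
    truth <- eas_params(2, lam, R0, 0.55 * R0)
    fit <- fit_nls(model_spectrum(truth, freqs), "single", D_free = 2)
    expect_equal(fit$params$lambda, lam, tolerance = 0.01)
    expect_equal(fit$params$R0, R0, tolerance = 0.01)
    expect_equal(fit$params$Rinf, 0.55 * R0, tolerance = 0.01)
    expect_true(fit$converged)
  }
})

test_that("flat spectra fit as free diffusion", {
  freqs <- 10^seq(2, 4.5, length.out = 10)
  sp <- tibble::tibble(frequency_hz = freqs, D_um2_per_ms = rep(2, 10))
  fit <- fit_nls(sp, "single", D_free = 2)
  expect_equal(fit$params$lambda, 1, tolerance = 1e-3)
  expect_lt(1 - fit$params$f_free, 1e-3)   # restricted fraction ~ 0
})

test_that("degenerate distribution data yield a near-zero spread estimate", {
  freqs <- 10^seq(2, 4.8, length.out = 14)
  truth <- eas_params(2, 1.4, 0.5, 0.3)
  fit <- fit_nls(model_spectrum(truth, freqs), "distribution", D_free = 2)
  expect_lt(fit$theta[3] * fit$theta[2], 0.01)  # implied sd below grid scale
  expect_equal(fit$theta[2], 0.5, tolerance = 0.02)
})

test_that("Metropolis-Hastings covers the truth and agrees with NLS", {
  freqs <- 10^seq(2, 4.8, length.out = 14)
  truth <- eas_params(2, 1.35, 0.5, 0.3)
  sp <- model_spectrum(truth, freqs)
  nls <- fit_nls(sp, "single", D_free = 2)
  mh <- fit_mh(sp, "single", D_free = 2, nls_init = nls, seed = 9,
               n_burn = 2000, n_keep = 5000)
  tr <- c(1.35, 0.5, 0.6)   # (lambda, R0, rho)
  for (k in 1:3) {
    expect_lt(abs(mh$posterior_mean[k] - tr[k]),
              2 * mh$posterior_sd[k] + 1e-8)
  }
  # posterior mean agrees with the NLS point on clean data
  expect_equal(unname(mh$posterior_mean["lambda"]), nls$theta[1], tolerance = 0.02)
  expect_equal(unname(mh$posterior_mean["R0"]), nls$theta[2], tolerance = 0.02)
  expect_gte(mh$acceptance_rate, 0.05)
  expect_lte(mh$acceptance_rate, 0.8)

  # seeded chains are identical
  mh2 <- fit_mh(sp, "single", D_free = 2, nls_init = nls, seed = 9,
                n_burn = 2000, n_keep = 5000)
  expect_identical(mh$samples, mh2$samples)
})

test_that("microstructure recovery round-trips the generating geometry", {
  freqs <- 10^seq(1.5, 5.5, length.out = 16)
  for (type in c("square", "hexagonal")) {
    for (Rt in c(0.1, 1)) for (p in c(1.03, 1.12, 1.5)) {
      pk <- if (type == "square") make_square_packing(Rt, p)
            else make_hexagonal_packing(Rt, p)
      R <- pk$radii[1]
      f_c <- radms_to_hz(2 * 2 / R0_from_geometry(type, p, R)^2)
      dat <- forward_predict(pk, freqs * f_c / 1000, 2)
      fit <- fit_nls(dat, "single", D_free = 2)
      rec <- recover_microstructure(fit$params, type)
      truth_reas <- pore_radius_regular(type, p, R)
      expect_equal(rec$p, p, tolerance = 0.1)
      expect_equal(rec$L, pk$L, tolerance = 0.1 * pk$L)
      expect_equal(rec$R_EAS, truth_reas, tolerance = 0.1 * truth_reas)
    }
  }
})

test_that("recovery scales linearly and rejects out-of-model tortuosity", {
  par <- eas_params(2, 1.35, 0.5, 0.3)
  rec1 <- recover_microstructure(par, "square")
  par2 <- eas_params(2, 1.35, 1.0, 0.6)
  rec2 <- recover_microstructure(par2, "square")
  expect_equal(rec2$R / rec1$R, 2, tolerance = 1e-6)
  expect_equal(rec2$L / rec1$L, 2, tolerance = 1e-6)
  expect_equal(rec2$p, rec1$p, tolerance = 1e-9)
  expect_error(recover_microstructure(eas_params(2, 1, 0.5, 0.3), "square"),
               "out-of-model")
})

test_that("fitted R0 distributions close the loop against a segmentation", {
  dist <- radius_distribution()
  pk <- make_random_packing(dist, 0.5, 150, seed = 9, phi_max = test_phi_max())
  seg <- segment_pores(pk, resolution = 384, n_rays = 512)
  m <- easpec:::.wmean(seg$pores$R_EAS, seg$pores$weight)
  s <- sqrt(easpec:::.wvar(seg$pores$R_EAS, seg$pores$weight))
  # gamma whose volume-weighted (R0^2) moments match the segmentation's:
  # weighting gamma(shape, scale) by R0^2 gives gamma(shape + 2, scale)
  shape_w <- (m / s)^2
  shape <- max(shape_w - 2, 0.5)
  scale <- m / shape_w
  pd <- eas_params_dist(2, 1.5, shape * scale, sqrt(shape) * scale, 0.3 * m)
  freqs <- 10^seq(log10(radms_to_hz(4 / m^2)) - 1.4,
                  log10(radms_to_hz(4 / m^2)) + 1.6, length.out = 14)
  sp <- tibble::tibble(frequency_hz = freqs,
                       D_um2_per_ms = eas_spectrum_dist(pd, hz_to_radms(freqs)))
  fit <- fit_nls(sp, "distribution", D_free = 2)
  cmp <- compare_r0_distribution(fit, seg)
  expect_lt(abs(cmp$mean_rel_diff), 0.05)

  # point-mass input: fitted spread consistent with zero
  par0 <- eas_params(2, 1.4, m, 0.3 * m)
  sp0 <- model_spectrum(par0, freqs)
  fit0 <- fit_nls(sp0, "distribution", D_free = 2)
  expect_lt(fit0$theta[3], 0.02)       # cv ~ 0
})
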