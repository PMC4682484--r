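test_that("cylinder spectrum has restricted limits and the known low-frequency law", {
  expect_equal(cylinder_spectrum(2, 2, 0), 0)
  expect_equal(cylinder_spectrum(0.5, 3, 0), 0)
  # asymptote to D_free at high frequency
  expect_equal(cylinder_spectrum(2, 2, 1e7), 2, tolerance = 1e-3)
  # low-frequency expansion D ~ (7/96) w^2 R^4 / D0
  w <- 1e-3
  expect_equal(cylinder_spectrum(2, 2, w) / (w^2 * 2^4 / 2), 7 / 96,
               tolerance = 1e-4)
  # monotone nondecreasing on a dense grid
  wg <- 10^seq(-2, 3, length.out = 200)
  expect_true(all(diff(cylinder_spectrum(1.3, 2, wg)) >= -1e-12))
  # scale invariance D(w; sR) = D(s^2 w; R)
  s <- 2.7
  expect_equal(cylinder_spectrum(s * 1.1, 2, wg),
               cylinder_spectrum(1.1, 2, s^2 * wg), tolerance = 1e-10)
})

test_that("intracylinder Monte Carlo matches the closed-form spectrum", {
  pk <- intra_packing(2)
  cfg <- mc_config(n_walkers = 3000, n_steps = 60000, seed = 11, D_free = 2,
                   compartment = "intracylinder")
  freqs <- c(150, 400, 1000)
  sp <- simulate_spectrum(pk, freqs, cfg, n_periods = 8, max_duration_low = 60)
  Dan <- cylinder_spectrum(2, 2, hz_to_radms(freqs))
  z <- (sp$D_um2_per_ms - Dan) / sp$se_um2_per_ms
  expect_true(all(abs(z) < 3))
})

test_that("lattice tortuosity has correct limits and dilute behaviour", {
  # free-diffusion limit
  expect_equal(tortuosity_regular("square", 500), 1, tolerance = 1e-4)
  expect_equal(tortuosity_regular("hexagonal", 500), 1, tolerance = 1e-4)
  # dilute effective-medium law lambda^2 -> 1 + phi for tracers in the pore
  # space (matrix-phase normalisation of the composite conductivity)
  for (type in c("square", "hexagonal")) {
    pm <- phi_max(type)
    for (phi in c(0.01, 0.03, 0.05)) {
      p <- sqrt(pm / phi)
      expect_equal(tortuosity_regular(type, p)^2, 1 + phi, tolerance = 0.01)
    }
  }
  # monotone increasing toward contact
  ps <- c(1.03, 1.12, 1.25, 1.5, 2, 4, 10)
  lam <- tortuosity_regular("square", ps)
  expect_true(all(diff(lam) < 0))
  # inversion round trip
  for (p in c(1.05, 1.3, 2.5)) {
    lam <- tortuosity_regular("hexagonal", p)
    expect_equal(p_from_tortuosity("hexagonal", lam), p, tolerance = 1e-6)
  }
  expect_error(p_from_tortuosity("square", 1), "out-of-model")
})

test_that("EAS Monte Carlo plateau matches the lattice tortuosity at low frequency", {
  pk <- make_square_packing(0.5, 2)
  lam <- tortuosity_regular("square", 2)
  cfg <- mc_config(n_walkers = 2500, n_steps = 80000, seed = 3, D_free = 2)
  sp <- simulate_spectrum(pk, 25, cfg, n_periods = 6, max_duration_low = 300)
  ratio <- sp$D_um2_per_ms * lam^2 / 2
  expect_true(abs(sp$D_um2_per_ms - 2 / lam^2) < 3 * sp$se_um2_per_ms ||
                (ratio > 0.9 && ratio < 1.1))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})
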