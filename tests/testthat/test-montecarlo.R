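test_that("free walkers obey the Einstein relation", {
  cfg <- mc_config(n_walkers = 4000, seed = 2, D_free = 2, compartment = "free")
  wk <- run_walk(NULL, cfg, duration_ms = 20, dt_ms = 0.02)
  t <- wk$duration
  for (d in list(wk$disp_x, wk$disp_y)) {
    msd <- mean(d^2)
    se <- sd(d^2) / sqrt(length(d))
    expect_lt(abs(msd - 2 * 2 * t), 3 * se)   # <x^2> = 2 D t per axis
  }
})

test_that("walkers stay in their compartment", {
  pk <- intra_packing(1.5)
  cfg <- mc_config(n_walkers = 500, seed = 5, D_free = 2,
                   compartment = "intracylinder")
  wk <- run_walk(pk, cfg, duration_ms = 5, dt_ms = 0.005, record_every = 50)
  box <- 2.5 * 1.5 + 10 * sqrt(4 * 2 * 0.005)
  r <- sqrt((wk$rec_x - box / 2)^2 + (wk$rec_y - box / 2)^2)
  expect_lte(max(r), 1.5 + 1e-9)

  eas <- make_square_packing(1, 1.4)
  cfg2 <- mc_config(n_walkers = 500, seed = 5, D_free = 2, compartment = "eas")
  wk2 <- run_walk(eas, cfg2, duration_ms = 5, dt_ms = 0.002, record_every = 50)
  cx <- eas$centers[1, 1]; cy <- eas$centers[1, 2]; W <- eas$tile[1]
  dx <- abs(wk2$rec_x - cx); dx <- pmin(dx, W - dx)
  dy <- abs(wk2$rec_y - cy); dy <- pmin(dy, W - dy)
  expect_gte(min(dx^2 + dy^2), eas$radii[1]^2 - 1e-9)
})

test_that("signal simulation is deterministic and inverts correctly", {
  pk <- make_square_packing(1, 1.5)
  wf <- synthesize_apodized_cosine(500, 8, b_target = 1)
  cfg <- mc_config(n_walkers = 300, seed = 42, D_free = 2)
  s1 <- simulate_signal(pk, wf, cfg)
  s2 <- simulate_signal(pk, wf, cfg)
  expect_identical(s1$E, s2$E)

  # zero-amplitude waveform: E = 1 exactly
  wf0 <- wf; wf0$samples <- wf$samples * 0
  s0 <- simulate_signal(pk, wf0, cfg)
  expect_identical(s0$E, 1)

  # conversion helpers
  expect_equal(signal_to_D(exp(-1 * 2), 1)$D_um2_per_ms, 2)
  expect_equal(signal_to_D(1, 0.5)$D_um2_per_ms, 0)
  expect_equal(signal_to_D(0.5, 1, se_E = 0.01)$se_um2_per_ms, 0.01 / 0.5)
  expect_error(signal_to_D(-0.1, 1), "E must be")
  expect_error(signal_to_D(0.5, -1), "b must be")
})

test_that("free diffusion gives the Gaussian attenuation and a flat spectrum", {
  cfg <- mc_config(n_walkers = 6000, seed = 8, D_free = 2, compartment = "free")
  wf <- synthesize_apodized_cosine(250, 16, b_target = 1)
  s <- simulate_signal(NULL, wf, cfg)
  expect_lt(abs(s$E - exp(-1 * 2)), 3 * s$se_E)

  # flat at D_free across three decades of frequency
  sp <- simulate_spectrum(NULL, c(20, 200, 2000, 20000), cfg)
  z <- (sp$D_um2_per_ms - 2) / sp$se_um2_per_ms
  expect_true(all(abs(z) < 3))
})

test_that("spectrum runs are reproducible and sorted with SE", {
  pk <- make_square_packing(1, 2)
  cfg <- mc_config(n_walkers = 400, n_steps = 30000, seed = 21, D_free = 2)
  sp1 <- simulate_spectrum(pk, c(2000, 500), cfg)
  sp2 <- simulate_spectrum(pk, c(500, 2000), cfg)
  expect_identical(sp1$D_um2_per_ms, sp2$D_um2_per_ms)
  expect_true(all(diff(sp1$frequency_hz) > 0))
  expect_true(all(sp1$se_um2_per_ms > 0))
})

test_that("MC spectra respect the length-frequency diffusion scaling", {
  s <- 2
  cfg <- mc_config(n_walkers = 3000, n_steps = 60000, seed = 13, D_free = 2)
  pk1 <- make_square_packing(1, 1.5)
  pk2 <- make_square_packing(1 * s, 1.5)
  f <- 600
  sp1 <- simulate_spectrum(pk1, f, cfg, n_periods = 8)
  sp2 <- simulate_spectrum(pk2, f / s^2, cfg, n_periods = 8)
  dz <- (sp1$D_um2_per_ms - sp2$D_um2_per_ms) /
    sqrt(sp1$se_um2_per_ms^2 + sp2$se_um2_per_ms^2)
  expect_lt(abs(dz), 3)
})

test_that("too-coarse step budgets trigger the displacement warning", {
  pk <- make_square_packing(0.1, 1.03)   # very narrow gaps
  cfg <- mc_config(n_walkers = 10, n_steps = 500, seed = 1, D_free = 2)
  expect_warning(simulate_spectrum(pk, 5000, cfg), "displacement")
})
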