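test_that("regular packings reproduce the abutting area fractions and radii", {
  sq <- make_square_packing(1, 1)
  expect_equal(sq$phi, pi / 4, tolerance = 1e-12)
  expect_equal(sq$radii[1], sqrt(pi / (4 - pi)), tolerance = 1e-12)
  expect_equal(sq$p, 1, tolerance = 1e-12)

  hx <- make_hexagonal_packing(1, 1)
  expect_equal(hx$phi, pi / (2 * sqrt(3)), tolerance = 1e-12)
  expect_equal(hx$radii[1], sqrt(pi / (2 * sqrt(3) - pi)), tolerance = 1e-12)

  # p from Eq.-12-style area ratio equals L / (2R) for regular packings
  for (p in c(1, 1.12, 1.5, 2, 4)) {
    pk <- make_square_packing(1, p)
    expect_equal(pk$p, pk$L / (2 * pk$radii[1]), tolerance = 1e-10)
    expect_equal(fractional_separation(pk$phi, pk$phi_max), p, tolerance = 1e-10)
    hk <- make_hexagonal_packing(0.7, p)
    expect_equal(hk$p, hk$L / (2 * hk$radii[1]), tolerance = 1e-10)
  }

  # quadrupling the area margin doubles p
  pk <- make_square_packing(1, 2)
  expect_equal(pk$phi, pi / 16, tolerance = 1e-12)
  expect_equal(fractional_separation(pi / 16, pi / 4), 2, tolerance = 1e-12)

  expect_error(make_square_packing(-1, 1), "positive")
  expect_error(make_square_packing(1, 0.9), ">= 1")
  expect_error(fractional_separation(0.9, pi / 4), "exceeds")
  expect_error(fractional_separation(-0.1, pi / 4), "positive")
})

test_that("maximal packing fractions are correct and admit the dense random case", {
  expect_equal(phi_max("square"), pi / 4, tolerance = 1e-12)
  expect_equal(phi_max("hexagonal"), pi / (2 * sqrt(3)), tolerance = 1e-12)
  expect_gt(test_phi_max(), 0.73)  # densest simulated random case must fit
  expect_error(phi_max("random"), "dist")
})

test_that("random packings are seeded, feasible and at the requested density", {
  dist <- radius_distribution()
  pm <- test_phi_max()
  a <- make_random_packing(dist, 0.3, 100, seed = 7, phi_max = pm)
  b <- make_random_packing(dist, 0.3, 100, seed = 7, phi_max = pm)
  expect_identical(a$centers, b$centers)
  expect_identical(a$radii, b$radii)

  for (seed in 1:4) {
    pk <- make_random_packing(dist, 0.5, 150, seed = seed, phi_max = pm)
    expect_true(validate_packing(pk))          # periodic non-overlap
    expect_gte(min_gap(pk), -1e-9)
    expect_equal(pk$phi, 0.5, tolerance = 1e-3)
  }

  dense <- make_random_packing(dist, 0.73, 300, seed = 3, phi_max = pm)
  expect_gte(min_gap(dense), -1e-9)
  expect_error(make_random_packing(dist, 0.99, 100, seed = 1, phi_max = pm),
               "phi")
})

test_that("pore radius: scale invariance, hex < square, brute-force ray oracle", {
  # R_EAS / R is scale invariant
  r1 <- pore_radius_regular("square", 1, 1)
  expect_equal(pore_radius_regular("square", 1, 3.7) / 3.7, r1, tolerance = 1e-12)

  # hexagonal pores are smaller than square pores at equal R
  expect_lt(pore_radius_regular("hexagonal", 1, 1), r1)

  # brute-force dense-ray oracle at the abutting configuration
  oracle <- pore_radius_regular("square", 1, 1, n_rays = 1e6)
  expect_equal(pore_radius_regular("square", 1, 1, n_rays = 4096), oracle,
               tolerance = 1e-3)

  expect_error(pore_radius_regular("square", 0.5, 1), ">= 1")
  expect_error(pore_radius_regular("square", 1, -1), "positive")
})

test_that("surface-to-volume follows the unit-cell formulas and scales as 1/length", {
  expect_equal(surface_to_volume("square", 2, 1), 2 * pi / (16 - pi),
               tolerance = 1e-12)
  # abutting limit
  expect_equal(surface_to_volume("square", 1 + 1e-12, 1),
               2 * pi / (4 - pi), tolerance = 1e-6)
  # all lengths doubled -> S/V halves; phi, p unchanged
  for (type in c("square", "hexagonal")) {
    expect_equal(surface_to_volume(type, 1.3, 2),
                 surface_to_volume(type, 1.3, 1) / 2, tolerance = 1e-12)
  }
})

test_that("uniform dilation leaves dimensionless descriptors unchanged", {
  dist <- radius_distribution()
  pk <- make_random_packing(dist, 0.4, 80, seed = 5, phi_max = test_phi_max())
  s <- 3.5
  big <- easpec:::new_cylinder_packing("random", pk$centers * s, pk$radii * s,
                                       pk$tile * s, phi_max = pk$phi_max)
  expect_equal(big$phi, pk$phi, tolerance = 1e-12)
  expect_equal(big$p, pk$p, tolerance = 1e-12)
  expect_equal(min_gap(big), s * min_gap(pk), tolerance = 1e-9)
})
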