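test_that("pore areas conserve the analytic EAS area", {
  # 2-cylinder toy tile
  toy <- easpec:::new_cylinder_packing("random",
    centers = rbind(c(2, 2), c(6, 6)), radii = c(1.2, 0.8),
    tile = c(8, 8), phi_max = 0.85)
  seg <- segment_pores(toy, resolution = 256, n_rays = 512)
  eas <- prod(toy$tile) - sum(pi * toy$radii^2)
  expect_equal(sum(seg$pores$area), eas, tolerance = 1e-6)
  expect_equal(sum(seg$pores$weight), 1, tolerance = 1e-12)
  expect_true(all(seg$pores$R_EAS > 0))

  dist <- radius_distribution()
  pk <- make_random_packing(dist, 0.5, 120, seed = 9, phi_max = test_phi_max())
  seg2 <- segment_pores(pk, resolution = 384, n_rays = 512)
  expect_equal(sum(seg2$pores$area), prod(pk$tile) - sum(pi * pk$radii^2),
               tolerance = 1e-6)
})

test_that("a square lattice segments into congruent pores matching the analytic radius", {
  sq <- make_square_packing(1, 1.3)
  L <- sq$L
  grid <- as.matrix(expand.grid((0:3) * L + L / 2, (0:3) * L + L / 2))
  lattice <- easpec:::new_cylinder_packing("random", grid, sq$radii[1],
                                           c(4 * L, 4 * L), phi_max = pi / 4)
  seg <- segment_pores(lattice, resolution = 512, n_rays = 1024)
  expect_equal(nrow(seg$pores), 16L)
  expect_lt(diff(range(seg$pores$area)) / mean(seg$pores$area), 1e-6)
  expect_lt(diff(range(seg$pores$R_EAS)) / mean(seg$pores$R_EAS), 1e-6)
  # matches the capped ray-quadrature definition used for regular packings
  expect_equal(mean(seg$pores$R_EAS),
               pore_radius_regular("square", 1.3, sq$radii[1]),
               tolerance = 0.02)
})

test_that("volume-weighted pore radii grow as packing density drops; dense case unimodal", {
  dist <- radius_distribution()
  pm <- test_phi_max()
  seg_hi <- segment_pores(make_random_packing(dist, 0.73, 250, seed = 11,
                                              phi_max = pm),
                          resolution = 384, n_rays = 512)
  seg_lo <- segment_pores(make_random_packing(dist, 0.3, 250, seed = 11,
                                              phi_max = pm),
                          resolution = 384, n_rays = 512)
  m_hi <- easpec:::.wmean(seg_hi$pores$R_EAS, seg_hi$pores$weight)
  m_lo <- easpec:::.wmean(seg_lo$pores$R_EAS, seg_lo$pores$weight)
  expect_gt(m_lo, 2 * m_hi)

  # dense packing: unimodal volume-weighted distribution
  d <- stats::density(seg_hi$pores$R_EAS, weights = seg_hi$pores$weight,
                      bw = stats::bw.nrd0(seg_hi$pores$R_EAS))
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  expect_equal(sum(d$y[peaks] > 0.1 * max(d$y)), 1L)
})
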