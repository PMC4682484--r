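# shared fixtures for the test suite (built in code, desk-scale budgets)

# memoised operational phi_max for the default genu-like distribution
test_phi_max <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- phi_max("random", radius_distribution(),
                                      n_cylinders = 120, seed = 2)
    val
  }
})

# a single impermeable cylinder of radius R, for intracylinder walks
intra_packing <- function(R = 2) {
  structure(list(packing_type = "square",
                 centers = matrix(c(0, 0), ncol = 2), radii = R,
                 tile = c(10 * R, 10 * R), L = NA_real_, R_tilde = NA_real_,
                 phi = pi * R^2 / (100 * R^2), phi_max = pi / 4, p = 1,
                 seed = NA_integer_, dist = NULL),
            class = "cylinder_packing")
}

# noiseless model spectrum as a tibble
model_spectrum <- function(params, freq_hz) {
  tibble::tibble(frequency_hz = freq_hz,
                 D_um2_per_ms = eas_spectrum(params, hz_to_radms(freq_hz)))
}
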