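Package: easpec
Title: Diffusion Spectra of the Extra-Axonal Space Around Packed Cylinders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the temporal diffusion spectrum D(omega) of water in the
    extra-axonal space surrounding packed parallel cylinders, as probed by
    oscillating-gradient spin-echo (OGSE) encoding. Provides construction and
    description of periodic cylinder substrates (square, hexagonal and random
    gamma-radius packings), the restricted-cylinder diffusion spectrum, lattice
    tortuosity of regular arrays, an empirical exchange model with a
    frequency-dependent effective pore radius, a compiled Monte Carlo
    random-walk engine with OGSE phase encoding as ground truth, nonlinear
    least-squares and Metropolis-Hastings model fitting, recovery of
    microstructural descriptors (pore radius, cylinder separation, packing
    density), and a config-driven experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
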