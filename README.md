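# easpec

Diffusion spectra of the extra-axonal space around packed parallel
cylinders.

## What this is for

Oscillating-gradient spin-echo (OGSE) diffusion MRI measures the temporal
diffusion spectrum D(ω) — the velocity power spectrum of diffusing water —
near the gradient oscillation frequency. For water *inside* axons
(impermeable cylinders) D(ω) has a classical closed form; for the
extra-axonal space (EAS) between packed axons it does not, yet its shape
encodes tortuosity, pore size and packing density. `easpec` is aimed at
people modelling white-matter microstructure with OGSE: it provides an
empirical exchange model for the full EAS spectrum, the Monte Carlo
simulation machinery that serves as ground truth, and the fitting steps
that turn measured spectra back into geometry.

The model mixes free and restricted behaviour,

    D_EAS(ω) = D_free/λ² + (1 − 1/λ²) · D_cyl(R(ω), ω)
    R(ω) = R∞ + (R0 − R∞) · exp(−Λω),   Λ = R0²/(2 D_free)

where `D_cyl` is the restricted spectrum of an impermeable cylinder (a
positive-weight sum of Lorentzian-type Bessel modes) and the effective
pore radius decays from its long-time value `R0` to its short-time value
`R∞`. For regular packings all three parameters follow from geometry:
λ(p) from the classical multipole expansion for insulating-cylinder
lattices, `R0` from the pore radius via a two-branch relation with a
crossover where the inter-cylinder gap matches the abutting pore radius,
and `R∞` from the surface-to-volume ratio. For random packings `R0`
becomes a gamma distribution and the model averages per-pore attenuations.

The package covers:

* **Geometry** — square/hexagonal lattices and random gamma-radius
  packings (`make_square_packing()`, `make_hexagonal_packing()`,
  `make_random_packing()`), descriptors (`phi_max()`,
  `fractional_separation()`, `pore_radius_regular()`,
  `surface_to_volume()`), and periodic watershed pore segmentation
  (`segment_pores()`).
* **Spectra** — `cylinder_spectrum()`, `tortuosity_regular()`,
  `eas_spectrum()`, `eas_spectrum_dist()`, `forward_predict()`.
* **Monte Carlo** — compiled 2D random-walk engine with specular
  reflection and OGSE phase encoding (`simulate_spectrum()`,
  `simulate_signal()`, `run_walk()`, `synthesize_apodized_cosine()`).
* **Fitting** — bounded least squares (`fit_nls()`), Metropolis–Hastings
  (`fit_mh()`), microstructure inversion (`recover_microstructure()`,
  `compare_r0_distribution()`), with broom-style `tidy()`/`glance()` and
  `autoplot()` methods.
* **Experiments** — config-driven grids with residual and recovery tables
  (`experiment_config()`, `enumerate_cases()`, `run_comparison()`,
  `run_recovery()`, `run_experiment()`), plus a thin CLI at
  `inst/scripts/eas`.

## Worked example

```r
library(easpec)

pk <- make_square_packing(R_tilde = 0.5, p = 1.12)   # R = 0.957 µm, L = 2.14 µm
freqs <- c(300, 1000, 3000, 10000, 30000)

# forward model from geometry alone
fp <- forward_predict(pk, freqs, D_free = 2)
attr(fp, "params")
#> <eas_params> D_free = 2 um^2/ms, lambda = 1.347, R0 = 0.4883 um, Rinf = 0.3418 um
#>   f_free = 0.5508, Lambda = 0.0596 ms/(rad/ms)

# Monte Carlo ground truth at desk scale
cfg <- mc_config(n_walkers = 2000, n_steps = 250000, seed = 1, D_free = 2)
mc <- simulate_spectrum(pk, freqs, cfg)

# fit the model back and invert to geometry
fit <- fit_nls(mc, "single", D_free = 2)
recover_microstructure(fit$params, "square")
#> # A tibble: 1 × 4
#>       p     R     L R_EAS
#>   <dbl> <dbl> <dbl> <dbl>
#> 1  1.11  1.14  2.54 0.844
```

The fitted tortuosity λ ≈ 1.35 means the zero-frequency EAS diffusivity is
D_free/λ² ≈ 1.10 µm²/ms; R0 ≈ 0.49 µm is the long-time effective pore
radius (the abutting pore radius at this tight separation). The recovery
step returns the separation p, cylinder radius R, centre-to-centre
distance L and pore radius R_EAS implied by the fit: the true values here
are p = 1.12, R = 0.957 µm, L = 2.14 µm, R_EAS = 0.717 µm, so this small
Monte Carlo budget (2,000 walkers) recovers the packing density to ~1% and
the length scales to ~20%. On noiseless model input the same chain
round-trips the generating geometry exactly, and the test suite holds the
noiseless recovery to 10%.

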