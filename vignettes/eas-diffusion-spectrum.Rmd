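---
title: "Modelling the extra-axonal diffusion spectrum around packed cylinders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the extra-axonal diffusion spectrum around packed cylinders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(easpec)
```

## The problem

Oscillating-gradient (OGSE) diffusion MRI measures the temporal diffusion
spectrum $D(\omega)$ — the velocity power spectrum of diffusing water — at
the gradient oscillation frequency. Inside axons, modelled as impermeable
parallel cylinders, $D(\omega)$ has a known closed form: restricted
diffusion with $D(0) = 0$, rising sigmoidally to the free diffusivity
$D_{free}$ at high frequency. The extra-axonal space (EAS), the connected
space between packed cylinders, is *hindered* rather than restricted:
$D(0) = D_{free}/\lambda^2 > 0$, with $\lambda$ the tortuosity. Between
these limits the shape of the EAS spectrum carries microstructural
information — pore size, cylinder separation, packing density — but has no
closed form. `easpec` implements an empirical exchange model for the whole
EAS spectrum, the Monte Carlo machinery that serves as its ground truth,
and the fitting and inversion steps that translate fitted parameters back
into geometry.

## The exchange model

A water molecule in the EAS alternates between two regimes: trapped in a
pore between adjacent cylinders (restricted) and migrating between pores
(free). In the fast-exchange limit the spectrum is the time-weighted mix

$$D_{EAS}(\omega) = f_{free}\,D_{free} + (1 - f_{free})\,
  D_{cyl}\!\big(R(\omega), \omega\big), \qquad f_{free} = 1/\lambda^2,$$

where $D_{cyl}(R,\omega)$ is the restricted spectrum of an impermeable
cylinder of radius $R$,

$$D_{cyl}(R, \omega) = \sum_k \frac{2 D_{free}}{\mu_k^2 - 1}\,
  \frac{\omega^2}{\omega^2 + \lambda_k^2}, \qquad
  \lambda_k = \frac{\mu_k^2 D_{free}}{R^2},$$

with $\mu_k$ the positive roots of $J_1'$. The mode weights satisfy
$\sum_k 2/(\mu_k^2-1) = 1$ (so $D \to D_{free}$) and reproduce the known
low-frequency law $D \approx (7/96)\,\omega^2 R^4 / D_{free}$, which the
test suite checks. The series is truncated when the next mode contributes
less than $10^{-8}$ of the running sum.

The effective pore radius varies with frequency,

$$R(\omega) = R_\infty + (R_0 - R_\infty)\, e^{-\Lambda \omega},
 \qquad \Lambda = \frac{R_0^2}{2 D_{free}},$$

interpolating between the long-time radius $R_0$ (particles have sampled a
whole pore) and the short-time radius $R_\infty$ (particles only sense the
nearest wall). $\Lambda$ is the diffusion time needed for one standard
deviation of free displacement to reach $R_0$.

For random packings $R_0$ is a gamma distribution rather than a scalar.
Per-pore attenuations are averaged under volume weights ($F \propto$
gamma density $\times R_0^2$, each pore with its own $\Lambda$) at a
reference weighting $b_{ref}$ and converted back through
$D = -\log E / b_{ref}$. The averaging is a 256-node Gauss–Legendre rule
over the gamma distribution truncated at its $10^{-6}$ and $1-10^{-6}$
quantiles; the dependence on $b_{ref}$ (a Jensen gap) vanishes as the
spread goes to zero, which the tests verify against a dense-quadrature
oracle. `b_ref` defaults to 1 ms/µm².

## Geometry and the empirical parameter relations

Substrates are periodic 2D cross-sections: square and hexagonal
(triangular-lattice) packings of uniform cylinders, described by the
equivalent abutting-EAS radius $\tilde R$ and the fractional separation
$p = \sqrt{\phi_{max}/\phi} = L/(2R)$, and random packings with
gamma-distributed radii. The abutting EAS area conversions are
$R = \tilde R\sqrt{\pi/(4-\pi)}$ (square) and
$R = \tilde R\sqrt{\pi/(2\sqrt3-\pi)}$ (hexagonal); $\phi_{max}$ is
$\pi/4$ and $\pi/(2\sqrt 3)$ respectively, and for random packings it is
defined operationally as the densest fraction the package's own packer
reaches under a fixed bisection schedule (an implementation-defined
quantity, cached per distribution).

Three geometric quantities drive the model:

* **Tortuosity** $\lambda(p)$, computed by the classical multipole
  (Rayleigh) expansion for arrays of insulating cylinders with numerically
  evaluated lattice sums, odd multipole orders up to 121. For tracers
  confined to the pore phase the conductivity must be renormalised by the
  porosity, $\lambda^2 = (1-\phi)\,\sigma_0/\sigma_{eff}$, which gives the
  dilute law $\lambda^2 \to 1 + \phi$ (the analogue of the classic
  $1 + \phi/2$ for spheres). Both the dilute law and the Monte Carlo
  zero-frequency plateau confirm this normalisation.
* **Effective pore radius** $R_{EAS}(p)$: the mean distance from the pore
  centre to the nearest cylinder wall over 4096 ray directions, with rays
  capped at the straight throat lines bounding the pore cell (without the
  cap the mean diverges along the open lattice channels). At $p = 1$ the
  cap is inactive.
* **Surface-to-volume ratio** $S/V = 2\pi R / A_{EAS}$ per unit cell.

The model parameters follow from these through two empirical relations.
The zero-frequency radius has two branches,

$$R_0(p) = \max\big(R_{EAS}(1),\; R_{EAS}(p) - R_{EAS}(1)\big):$$

near abutment the long-time restricted scale stays at the abutting pore
radius — the geometric pore radius would overestimate it because the
narrow channels between cylinders are more restrictive than the pore
proper — while for open packings it tracks the growing pore radius. The
two branches cross at a unique $p_0 \approx 1.28$ (square) and $1.13$
(hexagonal), within 2% of the separation at which the inter-cylinder gap
$2R(p-1)$ equals the abutting pore radius; `r0_branch_crossover()`
computes both. The high-frequency radius is surface-to-volume limited,

$$R_\infty(p) = \max\Big(0.7\, R_{EAS}(1),\;
   \frac{2\,(1 - 1/\lambda^2)}{S/V}\Big).$$

The second argument matches the exact high-frequency asymptote of the
exchange model to the $S/V$ law of the true spectrum and tends to the
cylinder radius $R$ in the dilute limit; the floor at $0.7\,R_{EAS}(1)$
was calibrated against Monte Carlo fits at tight separations
($p \le 1.12$), where straight channels between cylinders keep short-time
displacements larger than the $S/V$ estimate suggests. This calibration
against simulation is the same procedure that defines the relations in the
first place — they are empirical summaries of simulated spectra, not
derived results. The residual weakness sits near the initial spectral rise
for tightly packed square lattices, where the model underestimates
$D(\omega)$ by up to about $0.05\,D_{free}$ at desk simulation scales.

## Monte Carlo ground truth

The engine (compiled C++) runs fixed-step 2D random walks — step length
$\sqrt{4 D_{free}\,\Delta t}$, uniformly random directions — with specular
reflection off cylinder walls (up to 64 sub-reflections per step; a
residual path below a tenth of a step after that, a grazing-incidence
measure-zero event, is absorbed at the wall) and periodic wraparound. The
2D reduction is exact for parallel cylinders with perpendicular gradients.
Phases accumulate as $\phi_j = \sum_i g(t_i)\,x_j(t_i)\,\Delta t$ and the
attenuation is $E = \langle\cos\phi\rangle$, unbiased by symmetry and of
lower variance than $|\langle e^{i\phi}\rangle|$.

The effective gradient is an apodized cosine: the first and last half-lobes
of a cosine train are replaced by half-duration lobes at twice the
frequency, so the gradient starts and ends at zero and its encoding power
$|Q(f)|^2$ concentrates in a main lobe of width of order $1/T$ around the
target frequency (the tests require at least 90% of total power there).
The sampled train is de-meaned so the zeroth moment vanishes to machine
precision, and the peak amplitude is calibrated by bisection so the
numerically integrated $b = \int q^2\,dt$ hits its target to $10^{-6}$.

Time-step selection obeys three constraints: at least 32 samples per
gradient period; a step length no longer than a tenth of the narrowest
inter-cylinder gap (walkers otherwise jump channels and $D$ is
underestimated — a warning is emitted when a step budget forces this); and
a step length no longer than a quarter of the high-frequency boundary
layer $\sqrt{D/\omega}$, without which high-frequency points bias toward
free diffusion. Waveform durations follow a two-regime rule, capped at
50 ms below 10 kHz and 2 ms above by default, with 8 periods targeted per
waveform; single-period waveforms at very low frequency leak encoding
power across the spectrum's curvature and bias the estimate, so
comparisons use at least ~6–8 periods.

Desk-scale defaults (2,000–5,000 walkers, $10^4$–$4\times10^5$ steps per
frequency, 6–10 frequencies bracketing each case's transition band) keep
every simulation in this package's test suite in the minutes range. They
are roughly two orders of magnitude below the budgets a full study would
use, which widens the Monte Carlo standard errors accordingly; all
comparisons are made in units of those standard errors or against the
deliberately generous residual band $0.1\,D_{free}$.

## Random packings and pore segmentation

Random substrates draw cylinder radii from a gamma distribution (defaults
`shape = 3.3`, `scale = 0.18` µm, approximating axon radii in the genu of
the corpus callosum; treat them as a documented stand-in and supply your
own when accuracy matters, including the question of whether a published
distribution refers to radius or diameter). Placement is random sequential
addition, largest first; at densities beyond the sequential jamming limit
(about $\phi = 0.55$) the placement is completed by collective
rearrangement — overlapping pairs pushed apart until feasible — because
sequential addition alone cannot reach the densest simulated case
($\phi = 0.73$). Low-density packings therefore retain the clumpiness of
sequential addition, but the pore-size bimodality that a different placer
produces at low density is *not* reproduced here; the volume-weighted pore
distribution stays broad and unimodal.

The EAS of a substrate is partitioned into pores by a periodic watershed
of the exact distance-to-wall field (rasterised at 768² by default):
basins grow from local maxima, ridges run through the throats between
cylinders, and adjacent basins merge when the throat saddle radius is at
least 3/4 of the smaller basin's peak radius — a wide opening does not
split a physical pore. Pixelised areas are rescaled by a common factor to
the analytic EAS area (conservation is then exact by construction); pores
below $10^{-4}$ of the EAS area are folded into their best-connected
neighbour. Each pore is summarised by its area, its volume weight, and
$R_{EAS}$ measured by ray quadrature about the basin's deepest point
(Chebyshev centre), with rays capped where they cross into a neighbouring
basin — the same pore notion as for regular lattices, which is why a
square lattice pushed through this pipeline returns the analytic
$R_{EAS}(p)$ to raster accuracy.

## Fitting

`fit_nls()` fits $(\lambda, R_0, R_\infty)$ — or
$(\lambda, \bar R_0, \mathrm{cv}, R_\infty)$ for the distribution model —
by bounded Levenberg–Marquardt, weighting by inverse variance when
standard errors are present. $D_{free}$ is fixed at its known value.
$\lambda$ starts from $\sqrt{D_{free}/D(\omega_{min})}$; radii start both
from small nominal values (10 nm / 1 nm, and 1 µm / 10 nm / 500 nm for the
distribution model) and from a data-driven scale $\sqrt{2D_{free}/
\omega_{mid}}$ at the observed transition, over a small multi-start grid,
keeping the lowest residual. The distribution model is additionally seeded
from the single-radius fit. The spread is parameterised as a coefficient
of variation to keep the optimizer off the degenerate large-spread ridge.

`fit_mh()` runs random-walk Metropolis–Hastings from the NLS point:
independent uniform priors on generous positive ranges
($\lambda \in [1, 50]$, radii up to 100 µm), a Gaussian likelihood with
per-point standard errors (or a pooled residual variance floored at
$10^{-6} D_{free}$ so noiseless inputs remain proper), proposals
initialised from the Laplace-approximation scale at the optimum and
adapted toward ~25% acceptance during 5,000 burn-in draws, then frozen for
20,000 retained draws. Chains are seeded and reproducible; an acceptance
rate outside $[0.05, 0.8]$ raises a diagnostic warning.

`recover_microstructure()` inverts the chain geometry → parameters:
$p$ from $\lambda$ by root-finding on the lattice tortuosity, then $R$ by
least squares on the two linear-in-$R$ radius relations, then $L = 2Rp$
and $R_{EAS}(p, R)$. A fitted $\lambda \le 1$ is out of model and errors
rather than returning a silent extrapolation. On noiseless model data this
round-trips the generating geometry to well under the 10% the tests
require; fitting under a deliberately wrong lattice type either fails the
tortuosity inversion or leaves a large residual, never a silent success.

## Worked example

```{r example, eval = FALSE}
pk <- make_square_packing(R_tilde = 0.5, p = 1.12)
freqs <- 10^seq(2.4, 4.6, length.out = 8)

model <- forward_predict(pk, freqs, D_free = 2)
cfg <- mc_config(n_walkers = 2000, n_steps = 200000, seed = 1, D_free = 2)
mc <- simulate_spectrum(pk, freqs, cfg)

fit <- fit_nls(mc, "single", D_free = 2)
recover_microstructure(fit$params, "square")
```

## Numerical choices and limitations

* Bessel-derivative roots are found by bracketed root-finding near
  $(k - 1/4)\pi$ and cached; lattice sums are cached per lattice type and
  rescaled analytically with spacing.
* The multipole expansion truncates; exactly at contact ($p = 1$) the
  computed conductivity is a small positive residual rather than zero, so
  $\lambda(1)$ is large but finite (order $10^2$ rather than $\infty$).
  Spectra at $p = 1$ are therefore restricted to within a fraction
  $1/\lambda^2 \sim 10^{-2}$ of $D_{free}$ at zero frequency.
* The watershed merge ratio (0.75), raster resolution (768), and the
  degenerate-pore threshold ($10^{-4}$) are fixed package defaults; the
  congruence and conservation tests pin their behaviour.
* Identifiability: at loose packings the restricted fraction
  $1 - 1/\lambda^2$ is small and $(R_0, R_\infty)$ are weakly identified
  at desk-scale Monte Carlo noise; fits there are honest but wide. The
  synthetic generator produces noiseless or ensemble-noise data only — no
  Rician floor, no $T_2$ weighting, no intra-axonal compartment — so
  passing tests demonstrate internal consistency of the model and engine,
  not performance on scanner data.
* Two-compartment (intra + extra) tissue modelling, permeable membranes,
  3D or non-parallel geometries, and hardware feasibility are out of
  scope.
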