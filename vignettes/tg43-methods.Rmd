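---
title: "Methods: TG-43U1 seed dosimetry in tg43seed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TG-43U1 seed dosimetry in tg43seed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tg43seed)
```

## The formalism

A low-energy brachytherapy seed is characterised by the TG-43U1
factorisation of its 2D dose-rate distribution,

$$\dot D(r,\theta) = S_K\,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g(r)\, F(r,\theta),$$

with the reference point at $r_0 = 1$ cm on the transverse axis
($\theta_0 = 90^\circ$). The factorisation is exact by construction: the
geometry function $G$ carries the purely geometric inverse-square
behaviour of the extended source, $g(r)$ carries the transverse-axis
attenuation/scatter of the medium relative to 1 cm, and $F(r,\theta)$
carries everything angular at fixed radius (capsule end-cap filtration,
source distribution) relative to the transverse axis. Because $g$ and
$F$ are defined as double ratios of measured or simulated dose rates,
extracting them and then re-multiplying reproduces the input grid at
its lattice points identically — a property the test suite exercises as
an exact round trip, and a useful internal-consistency check for any
dataset.

The same structure implies scale invariance: multiplying a dose grid by
any positive constant leaves $g$, $F$, and the ratio $\Lambda = \dot
D(r_0,\theta_0)/S_K$ unchanged. Both normalisations,
$g(r_0) = 1$ and $F(r,90^\circ) = 1$, are enforced exactly (the
reference entries are set to 1 rather than left to floating-point
cancellation).

## Geometry function

For the line model of active length $L$,

$$G_L(r,\theta) = \frac{\beta}{L\,r\sin\theta}, \qquad
  \beta = \operatorname{atan2}(r\sin\theta,\, r\cos\theta - L/2)
        - \operatorname{atan2}(r\sin\theta,\, r\cos\theta + L/2).$$

Two numerical choices matter here:

- $\beta$ is formed from **two-argument arctangents**, so obtuse
  configurations ($r\cos\theta < L/2$, the point "past the end" of the
  line) are handled without branch errors.
- On the long axis $\sin\theta \to 0$ makes $\beta/(L r\sin\theta)$ a
  0/0 form; whenever $|\sin\theta| < 10^{-6}$ the closed limiting value
  $1/(r^2 - L^2/4)$ is used instead. The limit is the correct
  continuous extension — the conventional tables tabulate $F$ at
  $0^\circ$, so $G_L$ must be finite and positive there — and the
  $10^{-6}$ switchover keeps the relative error of either branch below
  $10^{-9}$ while avoiding catastrophic cancellation. Points with
  $r \le L/2$ at axial angles lie inside the source extent and are
  rejected as domain errors.

The implementation is validated against an independent brute-force
oracle — numerical quadrature of the uniform-line inverse-square
integral $\int_{-L/2}^{L/2} ds / (L\,d(s)^2)$ — to $10^{-6}$ relative
over $r \in [0.25, 5]$ cm, $\theta \in [1^\circ, 179^\circ]$, and
against the point model to $10^{-8}$ at $L = 10^{-6}$ cm.

## Interpolation and evaluation conventions

Tabulated $g(r)$ is evaluated by **piecewise-linear interpolation** in
$r$, and $F(r,\theta)$ by **bilinear interpolation** on its $(r,\theta)$
lattice; both are exact at the tabulated nodes. Out-of-range requests
raise an error — there is deliberately **no silent extrapolation**, as
extrapolated dosimetry parameters have no physical warrant. Linear
rules are the conservative standard where no interpolation convention
is published for a dataset; higher-order schemes can overshoot between
the coarse angular nodes near the seed axis, where $F$ varies by a
factor of ten over 20 degrees.

Angles are degrees at every interface (matching how such tables are
published) and radians internally.

## Air-kerma strength and the dose-rate constant

$S_K$ is estimated as $K(r)\,r^2$ from a vacuum ring-kerma profile and
averaged **unweighted** over the tabulated distances, with a
distance-independence diagnostic: if the relative spread
$(\max - \min)/\mathrm{mean}$ of the per-distance estimates exceeds a
tolerance (default 1%, configurable) the result is flagged as
non-converged. The unweighted mean is used because a correctly scored
far-field profile is distance-independent by construction; weighting
would only hide a profile that is not. For a finite line of length
$L$, $K r^2$ approaches its asymptote from below as
$1 - L^2/(12 r^2) + O(L^4/r^4)$, which at 150 cm for $L = 3$ mm is
within $10^{-7}$ — the basis of the far-field check in the tests.

The consensus dose-rate constant is the plain arithmetic mean of the
experimental and Monte Carlo values — the recommended single-dataset
rule when exactly one measurement and one calculation exist; no
literature-weighting scheme is applied.

## Polynomial model of g(r)

`fit_gl_polynomial()` performs an ordinary least-squares fit of $g$ as
a raw polynomial in $r$ (default degree 5) and reports
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean of the
$g$ values (the standard definition). A constant table has
$SS_{tot} = 0$; if the fit is also exact, $R^2$ is reported as 1. With
seven support points a fifth-order fit has one residual degree of
freedom; the fit is a compact parametrisation for treatment-planning
use over the fitted range only (evaluation outside `r_range` errors),
not a physical model.

The packaged reference coefficients — $a_0 = 2.43$, $a_1 = -2.81$,
$a_2 = 2.02$, $a_3 = -0.766$, $a_4 = 0.139$, $a_5 = -0.00948$, at
$R^2 = 0.9998$ — derive from the **Perspex Monte Carlo column** of the
packaged radial-dose fixture; the water and TLD columns give different
coefficients ($a_0 = 2.31$ and $2.66$ respectively) and are available
via `ir06_radial_dose()` for fitting separately.

## TLD reduction

The reading-to-dose chain per chip is

$$\frac{\dot D(r,\theta)}{S_K} =
  \frac{(R_{det} - \bar R_{bkg})/s_i}
       {t_{eff}\; S_K\; \varepsilon_\lambda\; E(r,\theta)}$$

- **Background**: the arithmetic mean of the experiment's background
  chips is subtracted from every reading.
- **Sensitivity** $s_i$: each chip's reading under a flat Co-60
  irradiation divided by the batch mean, so the factors average to
  exactly 1.
- **Effective exposure time**: a chip exposed for $T$ to a source
  decaying with $\lambda = \ln 2 / T_{1/2}$ integrates
  $t_{eff} = (1 - e^{-\lambda T})/\lambda$ hours' worth of the initial
  dose rate. This is the standard decay correction for converting an
  integrated reading to an initial dose rate; it reduces to $T$ for
  short exposures and to $T_{1/2}/\ln 2$ for infinite ones. The
  default Pd-103 half-life is 16.991 d (overridable).
- **Energy response** $E(r,\theta)$ defaults to 1; measured correction
  tables are user-supplied (as an exact-position lookup table or a
  function), since they are reader- and chip-type-specific.
- **Negative corrected readings** (chips statistically below
  background, expected at 5 cm from a Pd-103 seed) are clamped to zero
  with a warning rather than erroring: a large experiment should not
  die on one cold chip, but the clamp must be visible.
- **Type A**: replicate chips at a position are averaged; the reported
  `type_a_pct` is the relative sample standard deviation of the
  replicates — the $k=1$ single-measurement dispersion conventionally
  quoted for TLD work — with the standard error of the reported mean
  also available as `type_a_mean_pct = type_a_pct / sqrt(n)`.
- **Combination**: total relative uncertainty is the quadrature sum
  $\sqrt{u_A^2 + u_B^2}$ of type A and type B components.

Doses are reported in the measurement medium; no solid-phantom-to-water
conversion factor is applied (such factors are seed- and
phantom-specific and belong to the user's calibration chain).

## The synthetic generator

`simulate_dose_grid()`, `simulate_ring_kerma()` and
`simulate_tld_experiment()` replace a transport code with an analytic
kernel whose implied TG-43 parameters are known in closed form:

$$D(r,\theta) = S \cdot G_L(r,\theta) \cdot
  e^{-\mu r}\bigl(1 + b_1 \mu r\, e^{-b_2 \mu r}\bigr) \cdot
  e^{-\mu_{Ti}\,(t(\theta) - t(90^\circ))}$$

so that $g_{true}(r)$ is the medium factor normalised at 1 cm,
$F_{true}(\theta)$ is the capsule factor, $S_K^{true} = S$ (the vacuum
ring profile omits the medium factor, and the capsule factor is 1 on
the transverse axis by normalisation), and
$\Lambda_{true} = G_L(1, 90^\circ)\,A_{med}(1)$.

Choices behind the kernel:

- The **capsule path** $t(\theta) = \sqrt{(t_{cap}\cos\theta)^2 +
  (t_{wall}\sin\theta)^2}$ is a smooth effective titanium thickness
  interpolating between the end cap on the long axis and the side wall
  on the transverse axis. A literal straight-ray trace through the
  capsule shell is *non-monotone* near the end-cap cone edge (the path
  grows as $1/\cos\theta$ before the ray switches to the side wall),
  which would put a small unphysical dip into $F$ near $0^\circ$;
  published anisotropy tables are monotone there because scatter
  smooths the shadow. The smooth form keeps $F$ strictly increasing on
  $(0^\circ, 90^\circ)$, matching the qualitative shape the generator
  is meant to emulate.
- **Defaults are calibrated once to the packaged seed's dataset**:
  $\mu = 0.437997$ cm⁻¹, $b_1 = 6.191829$, $b_2 = 8.125831$ solve
  $g(0.5) = 1.42$, $g(5) = 0.161$ and $\Lambda_{true} = 0.690$
  cGy·h⁻¹·U⁻¹ simultaneously, and $\mu_{Ti} = 29.2625$ cm⁻¹ puts
  $F(0^\circ)$ at 0.2. These are *effective proxy coefficients*, not
  physical attenuation data: the generator's only contract is
  structural mimicry of a real low-energy seed dataset with known
  truth.
- **Noise is multiplicative lognormal** (dose tallies and TLD
  responses are positive), parameterised so the mean is exactly 1 and
  the relative standard deviation exactly the requested sigma. Default
  tally noise is 1% (a typical relative tally uncertainty at a few cm);
  TLD reading noise defaults to 2.9%, the dispersion level typical of
  replicate low-energy TLD measurements. All stochastic output is a
  pure function of (config, seed).
- The default grid lattice (0.25–5 cm; 0–90° in 10° steps), the
  ring-profile distances (5–150 cm in 5 cm steps), and the TLD layout
  (four chips at each of 0.5–5 cm on the transverse axis, with a
  0–330°/30° full-circle option via `fold_angles()`) mirror the
  standard ring-detector and spiral-phantom layouts for seed
  characterisation.
- An optional **discrete-bead mode** replaces the line geometry factor
  by an equal-weight five-point sum at the bead centres (equal
  activity per bead is assumed), letting tests probe line-vs-discrete
  source differences; they are sub-0.1% beyond 5 cm but visible at
  0.25 cm.

What the generator does *not* emulate: photon spectra and their
hardening with depth, scatter buildup anisotropy, inter-seed and
phantom-boundary effects, volume-averaging over detector size, or any
radius dependence in $F$ (the kernel's capsule factor is purely
angular, whereas real anisotropy tables flatten slowly with $r$).
Passing the parameter-recovery tests therefore demonstrates the
*analysis chain* is unbiased and correctly normalised under controlled
conditions — not that any transport physics is reproduced.

## Statistical test design

Stochastic properties are tested at fixed seeds with pre-committed
envelopes. Pointwise recovery of $g$ and $F$ under 1% tally noise is
judged against the propagated ratio uncertainty
$\sigma_g \approx \sigma\sqrt 2$ with a family-wise 4-sigma bound over
the ~90 lattice points (a pointwise 3-sigma bound would falsely fail a
fifth of all seeds by chance), plus a median-deviation check that the
errors are centred. The dose-rate-constant recovery averages 50 seeded
TLD experiments (within 1% of truth); the type-A check pools 50
experiments of 7 positions × 4 replicates and allows for the
$c_4(4) \approx 0.92$ small-sample bias of the SD estimator. These
problem sizes keep the full suite under a few seconds while leaving
the acceptance margins comfortably resolved.

## Data formats

Consensus datasets live in a human-diffable structured-text format
(sections `[source]`, `[lambda]`, `[geometry]`, `[nuclide]`,
`[g_table]`, `[F_table]`) with units recorded in the file; numeric
fields are written at full double precision so write/load round trips
are bit-identical. Grids travel as CSV with a `r_cm` column and
`theta_<deg>` columns. The sparse TLD-measured anisotropy points
(angles 0°, 30°, 60° only, at four radii) are kept as a separate sparse
fixture rather than merged into the dense Monte Carlo table: the two
methods have different angular support, and merging them would force
either invented values or NA holes into a dense lattice.

## Known limitations

- The 1D anisotropy factor $\phi_{an}(r)$ and along-away tables are
  not computed.
- No DICOM-RT or treatment-planning-system export.
- The synthetic kernel's $F$ has no radius dependence (see above).
- Bilinear interpolation of $F$ is only as good as the angular
  resolution of the table near the axis; users needing sub-degree
  axial accuracy should supply finer tables.
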