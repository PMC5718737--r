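# tg43seed

TG-43U1 dosimetric analysis for low-energy interstitial brachytherapy
seeds, built around a packaged consensus dataset for a Pd-103 seed
(five resin beads in a 4.7 mm titanium capsule, 3 mm active length).

Low-energy seeds (Pd-103, I-125) are characterised for clinical use by
the AAPM TG-43U1 formalism, which factors the 2D dose-rate distribution
around a seed as

    D(r, θ) = S_K · Λ · [G_L(r, θ) / G_L(r₀, θ₀)] · g(r) · F(r, θ)

with reference point (r₀ = 1 cm, θ₀ = 90°), where

- **S_K** is the air-kerma strength, `K(r)·r²` in vacuum on the
  transverse axis (unit U = cGy·cm²·h⁻¹);
- **Λ** is the dose-rate constant, the dose rate to water at the
  reference point per unit S_K (cGy·h⁻¹·U⁻¹);
- **G_L(r, θ) = β / (L·r·sinθ)** is the line-source geometry function
  (β the angle the active line subtends at the point; `1/(r² − L²/4)`
  on the long axis; `1/r²` for the point model);
- **g(r)** is the radial dose function (attenuation and scatter in the
  medium, geometry removed);
- **F(r, θ)** is the 2D anisotropy function (capsule self-filtration).

The package implements every stage of a seed characterisation:

- extraction of g(r) and F(r, θ) from polar dose-rate grids (Monte
  Carlo tallies or measurements), with angle folding for full-circle
  measurement layouts;
- S_K estimation from vacuum ring-kerma profiles with a
  distance-independence diagnostic;
- dose-rate constants and the experimental/Monte-Carlo consensus
  average, plus comparison reports against published seeds;
- fifth-order polynomial modelling of g(r) with R²;
- the TLD reading-reduction chain: background subtraction, per-chip
  sensitivity normalisation, Co-60 calibration, decay-corrected
  effective exposure time, energy-response correction, and quadrature
  (type A ⊕ type B) uncertainty combination;
- a synthetic generator of Monte-Carlo-like dose grids, ring-kerma
  profiles and TLD experiments with closed-form ground truth
  (`g_true`, `F_true`, `S_K`, `Λ`), so the whole pipeline is testable
  without a transport code;
- forward dose-rate reconstruction from a consensus dataset.

## Worked example

```r
library(tg43seed)

ds <- ir06_dataset()                       # packaged Pd-103 seed dataset
consensus_lambda(ds$lambda_exp, ds$lambda_mc)
#> [1] 0.69

fit <- fit_gl_polynomial(ds$g_table)       # fifth-order model of g(r)
signif(fit$coefficients, 3)
#>       a0       a1       a2       a3       a4       a5
#>  2.43000 -2.81000  2.02000 -0.76600  0.13900 -0.00948
round(fit$r_squared, 4)
#> [1] 0.9998

# dose rate at 2 cm, 30 degrees off-axis, for a 0.5 U seed
reconstruct_dose_rate(ds, sk = 0.5, r = 2, theta = 30)
#> [1] 0.04055076   # cGy/h
```

The consensus dose-rate constant 0.690 cGy·h⁻¹·U⁻¹ is the mean of the
TLD-measured (0.689 ± 0.058) and Monte Carlo (0.691 ± 0.021) Perspex
values; the polynomial models g(r) over 0.5–5 cm at R² = 0.9998; the
reconstructed dose rate combines the interpolated g and F tables with
the line-source geometry factor and scales linearly with S_K.

A full synthetic characterisation, from simulated tallies back to the
dose-rate constant:

```r
cfg <- simulator_config(noise_relative_sigma = 0.01, random_seed = 1)
sim <- simulate_dose_grid(cfg)             # polar grid, 0.25-5 cm x 0-90 deg
g   <- extract_radial_dose(sim$grid, geometry_model("line", L = 0.3))
round(g$g_values, 4)
#> [1] 1.6794 1.4245 1.0000 0.7722 0.6066 0.3916 0.2528 0.1621

sk <- air_kerma_strength(simulate_ring_kerma(cfg))
round(sk$sk, 6); sk$converged
#> [1] 0.999984
#> [1] TRUE
```

The extracted g matches the generator's analytic truth to within the
1% tally noise, and the ring estimator recovers the emission strength
(the true S_K) to better than 0.01%.

## Command line

A thin wrapper over the same functions ships at `inst/cli/tg43.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tg43.R", package = "tg43seed"))')" \
    consensus --exp 0.689 --mc 0.691
#> 0.69
```

Subcommands: `consensus`, `lambda`, `sk`, `extract-g`, `extract-f`,
`fit-poly`, `dose`, `reduce-tld`, `simulate`, `render`. Grids and
tables are exchanged as CSV (`r_cm,theta_<deg>` columns), datasets in
the structured-text format of `inst/extdata/ir06.tg43`. Errors exit
nonzero with one-line JSON on stderr.
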