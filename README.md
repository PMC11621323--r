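# aquafluct

Analysis of supercritical density fluctuations and structural heterogeneity
in supercooled aqueous solutions.

Deeply supercooled water — and dilute aqueous solutions such as
glycerol-water at 3.2 mol% (14.5 wt%) — shows anomalously growing density
fluctuations on cooling, the thermodynamic fingerprint of a hypothesized
liquid-liquid critical point and its Widom line. `aquafluct` is an R package
for the people who quantify that behavior from small/wide-angle X-ray
scattering (SAXS/WAXS) curves and molecular-simulation configurations: it
turns particle coordinates and S(q) curves into isothermal
compressibilities, Ornstein-Zernike correlation lengths, critical power-law
parameters, HDL/LDL structural populations, and evaporative-cooling droplet
temperatures.

## What it computes

* **Structure factors.** Minimum-image g(r) from periodic configurations
  (heavy atoms only), transformed with a truncation window:
  S(q) ≃ 1 + 4πρ̄ ∫₀^{r_max} w(r) r [g(r) − 1] sin(qr)/q dr.
* **SAXS decomposition.** S(q) = S_PY(q; R, η) + S_A(0)/(1 + ξ²q²): an
  analytic Percus-Yevick hard-sphere background (closed Wertheim form,
  S_PY(0) = (1−η)⁴/(1+2η)²) plus an Ornstein-Zernike anomalous component;
  fitted over 0.15–0.7 Å⁻¹ with R = 1.78 Å fixed by default, giving the
  extrapolated S(0).
* **Response functions.** κ_T = S(0)/(n k_B T) from scattering, or
  κ_T = ⟨δV²⟩/(k_B ⟨V⟩⟨T⟩) from NPT volume fluctuations; critical power
  laws κ_T = κ_T,0 ε^−γ and ξ = ξ₀ ε^−ν with ε = (T − T_s)/T_s, plus an
  R²-based low-temperature exclusion scan that flags Widom-line deviations.
* **Local structure index.** LSI_i = (1/n_i) Σ (Δ_ij − ⟨Δ⟩)² over gaps in
  the sorted O-O neighbor distances (cutoff 3.7 Å); HDL/LDL classification
  at 0.114 Å² and the population-crossing temperature.
* **WAXS observables.** Gaussian first-peak positions q₁(T), the maximum of
  dq₁/dT from smoothing splines, isosbestic points of S(q) families.
* **Droplet cooling.** Knudsen free-molecular evaporation coupled to a
  lumped energy balance for binary microdroplets in vacuum.
* **Synthetic data.** Seeded generators for every input class (ideal gas,
  hard spheres, water-like configurations with controllable LSI
  bimodality, SAXS curves, power-law series, volume series) with known
  ground truth — the package is fully testable without external data.

Everything is tidyverse-shaped: tabular inputs are data frames, outputs are
tibbles, fits have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Decompose a (synthetic) SAXS curve at 240 K, extrapolate S(0), convert to a
compressibility, and fit the critical power law:

```r
library(aquafluct)

q <- seq(0.15, 0.7, by = 0.005)
curve <- generate_saxs_curve(R = 1.78, eta = 0.40, SA0 = 0.02, xi = 2.5,
                             q_grid = q, noise_sd = 1e-4, seed = 42,
                             temperature = 240)
fit <- fit_saxs(curve)   # window 0.15-0.7 A^-1, R fixed at 1.78 A
fit
#> <saxs_fit> S(q) = S_PY(q; R, eta) + SA0 / (1 + xi^2 q^2)
#>   R    = 1.7800 A (fixed)
#>   eta  = 0.3999 +/- 0.0001
#>   SA0  = 0.02002 +/- 0.00006
#>   xi   = 2.519 A +/- 0.021
#>   S(0) = 0.06007 +/- 0.00008
```

The fit recovers the generating parameters (η = 0.40, S_A(0) = 0.02,
ξ = 2.5 Å) and extrapolates the structure factor to S(0) ≈ 0.060 — the
value that sets the density fluctuations. With the molecular number density
of the solution this becomes a compressibility:

```r
n <- number_density(1.03, chi_g = 0.032)   # 0.03043 molecules / A^3
kappa <- compressibility_from_S0(extrapolate_S0(fit)$S0, n, T = 240)
kappa_to_microbar(kappa)
#> [1] 59.58   # x 1e-6 bar^-1
```

A κ_T(T) series fitted to the divergence law yields the critical exponent
and divergence temperature:

```r
ser <- generate_powerlaw_series(20, 0.36, 224,
                                c(232, 238, 244, 250, 258, 268, 280, 295),
                                noise_rel = 0.01, seed = 42)
fit_powerlaw(ser, "kappa")
#> <powerlaw_fit> kappa(T) = kappa_T,0 * ((T - T_s)/T_s)^-gamma
#>   kappa_T,0 = 20.4523 +/- 0.46
#>   gamma = 0.3430 +/- 0.0157
#>   T_s = 224.99 +/- 0.72 K
#>   R^2 = 0.99954
```

A single noisy 8-point series pins γ to within a few hundredths and T_s to
within a kelvin; averaged over many realizations the estimates are
unbiased (see below).

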