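---
title: "Density fluctuations in supercooled aqueous solutions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density fluctuations in supercooled aqueous solutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquafluct)
```

## The scientific problem

Supercooled water is believed to host a liquid-liquid critical point (LLCP)
buried below its homogeneous-nucleation limit. Above that point, at ambient
pressure, the liquid behaves as a supercritical mixture of high-density
(HDL-like) and low-density (LDL-like) local environments, and its
thermodynamic response functions -- notably the isothermal compressibility
$\kappa_T$ -- grow anomalously on cooling and peak on the Widom line. Dilute
aqueous solutions (the package's reference system is a glycerol-water
mixture at $\chi_g = 3.2$ mol%, i.e. 14.5 wt%) inherit this behavior in a
shifted, damped form.

`aquafluct` implements the full analysis chain by which such behavior is
quantified from X-ray scattering and simulation data:

1. pair correlations $g(r)$ and structure factors $S(q)$ from periodic
   particle configurations;
2. decomposition of the small-angle (SAXS) region into a normal-liquid
   background plus an anomalous critical component, extrapolating $S(0)$;
3. response functions ($\kappa_T$ from $S(0)$ or from NPT volume
   fluctuations), critical power-law fits, and a goodness-of-fit exclusion
   scan that flags Widom-line deviations;
4. HDL/LDL structural populations via the local structure index (LSI);
5. the Knudsen evaporative-cooling model that assigns temperatures to
   microdroplets travelling in vacuum.

Because the underlying XFEL and microsecond-MD data sets are not
redistributable, a synthetic-data module generates every input class with
known ground truth; all tests run against those generators.

## Models

### Structure factor from $g(r)$

For an orthorhombic periodic box the radial distribution function is a
minimum-image pair histogram normalized by the ideal-gas shell count. Only
heavy atoms enter (hydrogens are excluded; heavy atoms dominate the X-ray
cross-section), and all heavy species are treated as one indistinguishable
set: in the dilute limit a single unweighted $g(r)$ is the appropriate
approximation, and per-element form-factor weighting is deliberately not
implemented. The transform is

$$S(q) \simeq 1 + 4\pi\bar\rho \int_0^{r_{max}} w(r)\, r\,[g(r)-1]\,
\frac{\sin qr}{q}\, dr, \qquad r_{max} = \tfrac{1}{2}\min(L_x,L_y,L_z),$$

with the piecewise-quadratic truncation window

$$w(r) = \begin{cases} 1 - 3(r/r_{max})^2, & r < r_{max}/3\\
\tfrac{3}{2}\left[1 - 2r/r_{max} + (r/r_{max})^2\right], & r_{max}/3 \le r \le r_{max}\\
0, & r > r_{max}.\end{cases}$$

$w$ is continuous, equals 1 at the origin, $2/3$ at the branch boundary and
0 at $r_{max}$; it suppresses the truncation ripples of the finite-range
sine transform.

Numerical choices: the default bin width is 0.02 Å (resolves the 2.75 Å
first O-O peak without amplifying bin noise); the quadrature is trapezoidal
on bin centers; $q = 0$ is refused by the transform because the $q \to 0$
limit of a closed, finite system is biased by the canonical-ensemble
constraint -- $S(0)$ is instead obtained by the SAXS-model extrapolation
below. The shell normalization uses the pair density $(N-1)/V$, which makes
$g(r)$ (and hence $S(q)$) exactly unbiased for an uncorrelated finite-$N$
configuration; this matters at small $q$, where the naive $N/V$ convention
produces an $O(1)$ deficit that does not vanish with system size.

### SAXS decomposition

The low-$q$ structure factor is modelled as the sum of a normal-liquid and
an anomalous component,

$$S(q) = S_{PY}(q; R, \eta) + \frac{S_A(0)}{1 + \xi^2 q^2},$$

where $S_{PY}$ is the analytic (Wertheim/Thiele) Percus-Yevick structure
factor of hard spheres with radius $R$ and packing fraction $\eta$, and the
Lorentzian Ornstein-Zernike term carries the critical density fluctuations
with correlation length $\xi$ and amplitude $S_A(0)$. At $q \to 0$ the PY
form reduces to the compressibility-route value
$S_{PY}(0) = (1-\eta)^4/(1+2\eta)^2$, so
$S(0) = S_A(0) + (1-\eta)^4/(1+2\eta)^2$.

Implementation notes:

* The PY inverse structure factor is evaluated from its exact rational
  series in $(2qR)^2$ (derived symbolically from the same closed form)
  whenever $2qR < 0.1$, because the trigonometric expression suffers
  catastrophic cancellation at small argument ($\sim \epsilon_{mach}/x^6$).
  Both branches agree to about $10^{-10}$ at the switchover.
* The default fit window is $0.15 \le q \le 0.7$ Å$^{-1}$ (the
  experimentally accessible SAXS range) and the hard-sphere radius is fixed
  by default at $R = 1.78$ Å, temperature-independent; both are arguments.
* Weights are uniform unless the curve supplies per-point standard errors.
* Bounds: $\eta \in [0, 0.74)$, $S_A(0) \in [0, 5]$, $\xi \in [0, 100]$ Å.
  The non-negativity of $S_A(0)$ is a documented choice: the anomalous
  term is a fluctuation excess. The objective has a local valley in which a
  flattened Lorentzian ($\xi \to 0$) trades against a shifted $\eta$, so
  the fit is multi-started on a small grid of $\eta$, $\xi$ and $S_A(0)$
  values and the lowest-residual solution kept. A fit that pins
  $S_A(0)$ at zero is flagged `anomalous_absent` ($\xi$ is then
  unidentifiable and its standard error is reported as `NA`).

### Response functions and power laws

Two independent routes to the isothermal compressibility are implemented:

$$\kappa_T = \frac{S(0)}{n k_B T} \qquad \text{and} \qquad
\kappa_T = \frac{\langle \delta V^2\rangle_{NPT}}{k_B \langle V\rangle \langle T\rangle},$$

with $n$ the molecular number density from the mass density and mean molar
mass. The volume-fluctuation variance is the population ($1/N$) variance,
matching ensemble-average semantics. Internally $\kappa_T$ is SI
(Pa$^{-1}$); `kappa_to_microbar()` converts to the field's display unit of
$10^{-6}$ bar$^{-1}$. Both routes agree on matched synthetic data within
the sampling error of a variance estimate
($\mathrm{sd} \approx \sqrt{2/N}$, about 0.45% at $N = 10^5$).

Apparent critical divergences are fitted as

$$\kappa_T(T) = \kappa_{T,0}\,\epsilon^{-\gamma}, \qquad
\xi(T) = \xi_0\,\epsilon^{-\nu}, \qquad \epsilon = \frac{T - T_s}{T_s},$$

with amplitude, exponent and divergence temperature $T_s$ all free. The fit
is a full nonlinear least squares in linear space with an analytic Jacobian
(a log-log transform would not linearize the problem because $T_s$ is
unknown), multi-started over $T_s \in \{\min T - 5, \min T - 15,
\min T - 30\}$ K since the objective is multimodal in $T_s$; $T_s$ is
bounded below the lowest fitted temperature. $R^2$ is
$1 - SS_{res}/SS_{tot}$ over the included points only. A near-zero
exponent leaves $T_s$ unidentifiable and the fit is flagged degenerate.
For any pair of fits `exponent_ratio()` reports $\nu/\gamma$ with
first-order propagated uncertainty; fed the Ising exponents
($\nu = 0.6$, $\gamma = 1.2$) it returns exactly $0.5$, the benchmark for
proximity to a true critical point.

The exclusion scan refits the power law after dropping the $0 \ldots k$
lowest-temperature points. Near a Widom line the response function bends
away from the divergence law as its maximum is approached, so exclusion of
the lowest-$T$ point(s) improves $R^2$ markedly for bent data and
negligibly for a true power law; the deviation flag fires when the
improvement exceeds a margin (default 0.01, configurable).

### Local structure index

For oxygen $i$, with all minimum-image O-O distances sorted ascending and
$n_i$ of them inside the cutoff $r_c^{OO} = 3.7$ Å,

$$LSI_i = \frac{1}{n_i} \sum_{j=1}^{n_i} \left[\Delta_{ij} -
\langle\Delta_i\rangle\right]^2, \qquad \Delta_{ij} = r_{i,j+1} - r_{i,j}.$$

The gap list runs to $j = n_i$, so the last gap spans the cutoff and the
first neighbor beyond 3.7 Å participates -- the convention of the LSI
literature, adopted here because the defining sum is ambiguous on this
point; it is what makes the index sensitive to an empty interstitial shell.
Ties in the distance sort are broken by particle index, so results are
deterministic. Molecules with no neighbor inside the cutoff, or whose
first neighbor beyond it would exceed the half-box (minimum-image sphere),
are excluded and reported. The index is sharpest on quenched
(inherent-structure) coordinates; the package operates on whatever
coordinates it is given and performs no energy minimization, so thermal
configurations yield broader distributions.

Classification uses the threshold $0.114$ Å$^2$ -- the local minimum of the
bimodal inherent-structure LSI distribution -- with $LSI \le 0.114$ Å$^2$
HDL-like (the boundary value inclusive on the HDL side). The
population-crossing temperature is the root of a smoothing-spline fit of
the LDL fraction minus $1/2$; with several roots the one nearest the
median temperature is returned with a warning.

### Evaporative cooling

A droplet travelling in vacuum loses water by free-molecular (Knudsen)
evaporation,

$$J = \alpha\, p_{vap}(T)\, a_w \sqrt{\frac{M_w}{2\pi R_{gas} T}},$$

with evaporation coefficient $\alpha = 1$ by default, Raoult water activity
$a_w = 1 - \chi_g$, and the Murphy-Koop correlation for the vapor pressure
of supercooled water (exported over 150-320 K). The coupled balance

$$\frac{dm_w}{dt} = -4\pi r^2 J, \qquad
\frac{dT}{dt} = -\frac{J L(T)\, 4\pi r^2}{m\, c_p(T, \chi_g)}$$

is integrated with a fixed-step classical Runge-Kutta (RK4) scheme
(default step 1 µs), glycerol treated as non-volatile so $\chi_g$ rises as
water leaves, uniform internal temperature (lumped capacitance), and the
radius recomputed each step from the total mass and an ideal-volume-mixing
density. The latent heat follows the Murphy-Koop molar form; the liquid
water heat capacity uses an empirical expression reproducing the
supercooling rise (75.3 J mol$^{-1}$ K$^{-1}$ at 298 K growing to roughly
93 at 229 K), glycerol a constant 218.9 J mol$^{-1}$ K$^{-1}$, mixed
ideally. Radiative and residual-gas conduction are neglected (chamber
pressures of order 1 Pa). For an 18.7 µm droplet at $\chi_g = 0.032$ the
model cools from ambient into the 230 K range within a couple of
milliseconds -- consistent with the 229-259 K range reported for real
microdroplet trains -- but exact endpoint agreement is not claimed: the
thermophysical parameterization of real glycerol-water microdroplet
experiments is not public, and all correlations here are stated, swappable
choices.

## The synthetic-data module

Every generator takes an explicit integer seed, is byte-identical under it,
and restores the caller's RNG state.

* **Ideal gas** -- uniform independent positions; the exact null model for
  $g \equiv 1$, $S \equiv 1$.
* **Hard spheres** -- random sequential insertion followed by Metropolis
  relaxation sweeps (default 30); packing fractions up to 0.45. Used to
  exercise the PY background with a known $S(0)$.
* **Water-like configurations** -- the LDL-like population is a
  diamond-cubic oxygen lattice with nearest-neighbor distance 2.75 Å and
  Gaussian jitter: four equidistant neighbors, an empty interstitial
  shell, and the next shell at 4.49 Å give a large terminal gap and hence
  high LSI. The HDL-like population is a dense disordered hard-core
  packing (core 2.4 Å, number density 0.037 Å$^{-3}$) whose neighbor
  distances fill the interstitial region continuously, giving small, even
  gaps and low LSI. A single inserted fifth neighbor at 3.2-3.5 Å was
  evaluated and rejected during design: hand evaluation of the gap
  variance shows one `interstitial` still leaves $LSI \approx 0.22$
  Å$^2$ -- above the 0.114 Å$^2$ threshold -- because the large gap to the
  second shell dominates; a continuum of interstitial distances is what
  the low-LSI mode actually requires. The two populations occupy slabs of
  one periodic box separated by 1.8 Å vacuum gaps so that interface
  molecules keep the neighbor statistics of their own population.
* **SAXS curves** -- the same `saxs_model()` used by the fitter (one shared
  implementation, so generator and fit agree identically) plus additive
  Gaussian noise.
* **Power-law series** -- multiplicative relative Gaussian noise; the
  amplitude is the prefactor, i.e. the value at $\epsilon = 1$.
* **Volume series** -- i.i.d. Gaussian volumes with the
  fluctuation-dissipation variance $\kappa_T k_B T \langle V\rangle$.

What the generators do *not* emulate: real interaction physics (no
TIP4P/2005 forces), hydrogen positions, inherent-structure quenches,
detector geometry, form-factor normalization, or correlated sampling noise.
Passing tests therefore demonstrate the correctness of the estimators and
fitters under controlled truth, not the faithfulness of any water model.

## Study conditions used by the tests and the acceptance script

The power-law recovery studies use the glycerol-water critical parameters
($\gamma = 0.36$, $T_{s,\kappa} = 224$ K; $\nu = 0.26$, $T_{s,\xi} = 221$
K) on the 8-point temperature grid {232, 238, 244, 250, 258, 268, 280,
295} K spanning the experimentally accessible range, with 1% relative
noise and 100 seeds. The amplitudes are not printed quantities; the
package fixes $\kappa_{T,0} = 20 \times 10^{-6}$ bar$^{-1}$ and $\xi_0 =
1.2$ Å once as physically plausible magnitudes (they put $\kappa_T$ at
about $30$-$66 \times 10^{-6}$ bar$^{-1}$ and $\xi$ at 1.3-2.6 Å across
the grid); exponent and $T_s$ recovery is invariant to this choice.

Structure-factor sanity checks run at $N = 1000$ particles: 40 ideal-gas
frames for the $S \equiv 1$ null, and 60 hard-sphere frames at
$\eta = 0.2$ -- enough frames that the comparison against the closed-form
PY $S(0)$ is limited by the windowed-transform bias (about 10% at
$q = 0.15$ Å$^{-1}$, about 3% after the model extrapolation), not by
sampling noise. LSI studies use 300-512 molecules per configuration.

## Known limitations

* $S(0)$ from a single closed simulation cell is intrinsically biased; the
  package's answer is the model extrapolation from the SAXS window, and
  the direct transform refuses $q = 0$ rather than return a biased number.
* The PY + Ornstein-Zernike decomposition assumes monodisperse hard
  spheres for the normal component; no polydispersity, no alternative
  closures.
* The LSI module classifies the coordinates it is given; without an
  inherent-structure quench the HDL/LDL separation is blurred.
* The cooling model is lumped and radiation-free, with literature
  correlations for pure-water properties and ideal mixing; it is designed
  for qualitative trajectory work (tens of kelvin per millisecond), not
  calorimetric accuracy.
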