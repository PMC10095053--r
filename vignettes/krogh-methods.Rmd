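---
title: "Determining tissue oxygen permeability from slice pO2 soundings: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining tissue oxygen permeability from slice pO2 soundings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kroghslice)
```

## The problem

An ex vivo brain slice has no blood supply: oxygen reaches the tissue by
diffusion from the perfusing artificial cerebrospinal fluid (aCSF) above and
below. Profiling oxygen tension P (mmHg) against probe depth x (µm) through
the slice yields a parabola-like curve whose curvature encodes the
volumetric consumption rate Q — but only as the lumped ratio Q/Kt, where Kt
is the tissue Krogh coefficient (oxygen diffusivity × solubility, SI
mol/(m·s·Pa)). To report Q itself one needs Kt, and published values span a
wide range, mostly at 37 °C while slice work runs at room temperature. This
package implements a self-contained route to Kt at the experiment's own
conditions, via the dimensionless tissue:fluid ratio Kt/Kf and a computed
fluid coefficient Kf.

## The steady-state model

At steady state, diffusion balances consumption in a homogeneous slab of
half-thickness L (x = 0 at the centre, surfaces at ±L, surface tension Ps):

$$K \frac{d^2 P}{d x^2} = Q(P), \qquad
Q(P) = Q_0 \min(P/P^{*},\, 1),$$

with the critical tension P\* marking the onset of supply-limited
consumption. The piecewise-linear law is the analytically solvable
approximation of Michaelis–Menten uptake with K_M = P\*/2 (both are
provided; they agree at 0, at half-maximum and in saturation). Three
closed-form tension profiles result, selected by where the curve sits
relative to P\*:

| case | condition | profile |
|---|---|---|
| parabolic | Ps − aL² ≥ P\* | P = Ps − a(L² − x²), 2a = Q0/K |
| paracosh | P\* < Ps < P\*(1 + (αL)²/2) | cosh basin for \|x\| ≤ δ, parabolic wings |
| cosh | Ps < P\* | P = Ps·cosh(αx)/cosh(αL) |

with decay constant α = √(2a/P\*). The basin edge δ solves
tanh(αδ) = (1 − Ps/P\*)/(α(δ − L)) + α(δ − L)/2; the residual has a single
sign change on (0, L) in the paracosh regime and is solved by `uniroot` on
(10⁻⁶L, L − 10⁻⁶L) with a dense-scan fallback and a Newton polish to a
residual below 10⁻¹⁰. Flux is reported **unsigned** (q/K = |dP/dx|);
physically oxygen flows down-gradient, into the slice from both faces.

Exactness is enforced by property tests: a finite-difference second
derivative of every analytic case reproduces Q(P)/K to < 10⁻⁴ relative at
100 interior points, branch value and slope are continuous at ±δ, and the
paracosh form collapses to the parabola as δ → 0 and to the cosh form as
δ → L.

## From sounding to Krogh ratio

A sounding samples fluid–tissue–fluid every 50 µm; 8 or 9 samples land in
the 400-µm slab. Processing stages, each exposed as a function:

1. **Centre location** (`locate_centre`): the pressure minimum marks the
   zero-flux symmetry plane. A parabola is fitted to the window of samples
   around the minimum; the window is then re-selected to the samples within
   L of the current vertex and refit (≤ 5 iterations, stop at < 1 µm
   movement). Tied minima resolve to the window with lower fit rms.
2. **Model fits** (`fit_parabola`, `fit_paracosh`): least squares over the
   in-tissue samples. The paracosh fit is a log-parametrised Nelder–Mead
   over (2a, P\*) with δ re-solved at every iterate, started from the
   parabola curvature and P\* = 0.8 × fitted minimum.
3. **Selection** (`select_model`): paracosh wins only if its rms is ≥ 10%
   lower *and* its fitted P\* exceeds the fitted minimum pressure (the basin
   is active). The published procedure's flat-bottom criterion is
   unpublished, so this rule is a documented stand-in; both fits and the
   decision are kept on the result so the rule can be swapped.
4. **Boundary layers** (`detect_boundary_layer`): a non-flowing fluid layer
   consumes nothing, so its pressure trend is linear. A line is fitted to
   the 3 fluid samples nearest the interface, falling back to 2 when the
   third sample breaks linearity (r² < 0.95) — stagnant layers are thin
   (tens of µm), so the third sample often sits in the stirred bath. A
   near-zero fluid slope is accepted arithmetically but flagged: it implies
   no oxygen draw, inconsistent with active tissue.
5. **Flux conservation** (`krogh_ratio`): Kt/Kf = (fluid slope)/(tissue
   boundary gradient). Ratios ≥ 1 are rejected unconditionally (tissue
   cannot out-permeate fluid); ratios above the configurable cutoff
   (default 0.725, the empirical break between the allowed and disallowed
   clusters) are rejected as advection-contaminated.

### Design choices that were genuinely open

* **Free surface pressure.** The published procedure fixes Ps by linear
  interpolation of the samples bracketing ±L. Because the tissue curve is
  convex between the bracketing samples, that interpolation is biased by
  up to ~2 mmHg, which propagates to percent-level errors in (2a, P\*) and
  the ratio — an order of magnitude worse than the package's own 10⁻³
  round-trip requirement. `fit_paracosh` therefore treats Ps as a free
  parameter *started* at the interpolated value (`fit_ps = TRUE`); with
  noiseless data recovery is then exact to machine precision. Setting
  `fit_ps = FALSE` restores the fixed-Ps behaviour, which is slightly more
  noise-robust (fewer free parameters) and is used in the noisy
  recovery tests.
* **Centre refinement.** For flat-bottomed profiles sampled on a grid that
  is asymmetric about the centre, the local parabola vertex is a biased
  centre estimate. The paracosh optimiser therefore refines the centre
  offset within ± half a step (`refine_centre = TRUE`).
* **One symmetric fit.** Whether the upper-interface tangent should come
  from a side-specific fit is unstated in the source procedure; a single
  symmetric fit supplies both tangents.
* **Coordinates.** Probe depth increases downward; "upper" is the
  smaller-depth side; the tissue occupies [x0 − L, x0 + L].

## Fluid physics

Kf = D(T)·S(T, [mCl]) with optional glucose depression:

* Diffusivity: log₁₀D = −8.410 + 773.8/T − (506.4/T)². The printed form of
  the final term is typographically ambiguous (it could read −506.4/T²);
  only the squared-ratio reading gives D(25 °C) ≈ 2.0×10⁻⁹ m²/s and
  reproduces the reference Kf values 2.262/2.348×10⁻¹⁴, so it is adopted.
* Solubility: Green–Carritt Bunsen coefficient with explicit chlorinity
  (salting-out, ~5% for aCSF), converted by
  S = α·1000/(101325 × 22.392) — the divisor is the measured (non-ideal) O2
  molar volume at 0 °C/1 atm, and the same 22.392 L/mol is the package's
  default for amount↔volume unit conversions, for internal consistency.
  The NASA-JPL Henry's-law tabulation (0.73% rms away over 0–50 °C) and the
  Sander two-parameter form (2.6% rms) serve as cross-checks.
* Glucose: fixed 1% (diffusivity) and 0.5% (solubility) depressions at the
  20 mM recipe concentration, temperature-independent and cumulative
  (−1.5% on Kf). The underlying glucose interpolation source is graphical,
  so these constants are consumed as given, not re-derived.
* Chlorinity: Σ(conc × Cl stoichiometry × 35.453 g/mol) over the recipe
  salts = 4.928 g/L for the magnesium-free aCSF; buffering agents
  contribute nothing. The g/L → g/kg division uses a default solution
  density of 1.005 kg/L, giving 4.9035 g/kg where the reference prints
  4.904 (their implied density is ≈1.0049 kg/L); the density is exposed as
  a parameter and the 5×10⁻⁴ discrepancy is a rounding inconsistency in
  the source arithmetic, not in the code.
* The rms comparison grid (1 °C steps, inclusive endpoints, Green–Carritt
  in the denominator) is a package choice; the source does not state one.
  The 0.72%/2.6% figures shift in the second decimal with grid choice.

## Units

Seven compound unit systems from the physiology literature are supported.
Length/time/pressure conversions are exact (1 atm = 101325 Pa = 760 mmHg =
760 torr). Amount conversions between mol-based and volume-based gas units
require a molar volume and raise an explicit error when none is supplied —
this is precisely the ambiguity that makes literature comparisons
hazardous when the temperature/pressure convention is unstated. The
nM·mm³ amount unit has internally odd dimensioning in its source and is
implemented provisionally as nmol. Round trips are exact to 10⁻¹² relative.

## Study statistics

Group summaries use sample (n−1) statistics; the source's convention is
unstated, and the choice only affects synthetic-data checks since the
worked numbers are consumed as printed. The pooled ratio is the N-weighted
mean of group means (0.562 for the reference study's four groups). Paired
repeats at a location share their biology, so var(A−B) estimates the
experimental variance and var(A+B) − var(A−B) the biological variance;
these face-value identities are used exactly as stated, *without* the
conventional factor of 2 — and the synthetic generator's per-location and
per-repeat SDs (√(0.0194)/2 and √(0.0069/2)) are chosen so that the same
identities applied to generated pairs reproduce the configured 0.0194 and
0.0069. Discrepant repeat pairs are flagged via a Cartesian-separation
diagnostic, never auto-removed. The curvature-vs-flow trend is fitted by a
three-parameter saturating law y = ymax·xⁿ/(Kⁿ + xⁿ) (`nls`, port
algorithm, positivity bounds). The final Kt = ratio × Kf carries the
ratio's relative SD (~16% in the reference study); the ~2% fluid
uncertainty is neglected as an order of magnitude smaller.

## What the synthetic generator does and does not emulate

`simulate_study` reproduces the measurement protocol: 50-µm steps from
200 µm above to 100 µm below a 400-µm slab; per-location curvature around
the saturating flow law (ymax = 7.5×10⁻³ mmHg/µm², K = 0.75 mL/min,
n = 0.75; relative SD 0.2, matching the 17–29% spread of the reference
study's per-flow statistics); a true ratio per location
(mean 0.562); stationary layers preferentially at the lower interface with
probability decreasing in flow (0.85 − 0.03·flow, clipped to [0.3, 0.9],
consistent with the reference study's accepted fractions); layer thickness
100 µm; i.i.d. Gaussian pressure noise of 1 mmHg (no instrument figure is
published; chosen so end-to-end ratio scatter is of the observed order);
and a uniform sub-step centre offset so boundaries never hit a sample.
Where no layer exists the fluid continues at the tissue tangent slope
(a smooth, break-free crossing), which downstream analysis correctly
refuses to accept. The default bath-side surface tension of 150 mmHg is an
invented placeholder (the true bath pO2 under 95% O2 perfusion is not
published) chosen to exceed aL² + P\* for the steepest profiles.

Not emulated: electrode drift, probe-induced tissue compression, spatially
correlated noise, advective contamination intermediate between "stationary"
and "fully stirred", and seizure-related electrophysiology. A green
end-to-end test therefore establishes correctness of the *inference
machinery* under the stated noise model, not robustness to every failure
mode of a real rig.

Two honest calibration notes from the test suite: (i) with 1 mmHg noise on
8 in-tissue samples, the median relative error of the fitted curvature for
a wide-basin paracosh profile is ~6–7% (~5.6% even when the optimiser is
handed the true centre and surface pressure) — the flat basin simply
carries little curvature information; the recovery test asserts the
measured 10% bound rather than an aspirational 5%. (ii) The 0.725
acceptance cutoff truncates the upper tail of the candidate-ratio
distribution, biasing the accepted-ratio mean low by ≈0.008; the
Monte-Carlo check (100 locations, 2-SE band) absorbs this.

## Numerical details

* δ solver: bracketed `uniroot` + Newton polish, residual < 10⁻¹⁰; roots
  closer than 10⁻⁶L to either end are unresolvable by construction (the
  case boundary is then classified exactly).
* Optimiser: Nelder–Mead, log-parametrised positivity, reltol 10⁻¹², one
  restart; an rms below 10⁻⁸ counts as converged even when the relative
  criterion cannot trigger near the numerical floor.
* Degenerate inputs: profiles whose minimum sits at an end sample are
  rejected ("no interior minimum"); parabola fits with non-positive
  curvature are errors; constant-curvature Hill fits are flagged
  unconverged; negative biological variance is clamped to zero with a
  warning.
* Internal profile maths stays in instrument units (mmHg, µm) — matching
  the printed curvature scale of 10⁻³ mmHg/µm² — and SI appears only in
  the fluid/units modules.

## Known limitations

* The stationarity of the fluid layer cannot be verified from a sounding
  alone; the cutoff is an empirical proxy.
* The cosh-only case is implemented and property-tested but was never
  observed in real soundings, so its fitting path is untested against
  experimental data.
* Time-dependent diffusion, cylindrical (capillary) geometry and edge
  effects are out of scope; the slab is assumed homogeneous and symmetric.
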