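# kroghslice

Oxygen permeability of living tissue — the **Krogh coefficient**,
K = D·S (diffusivity × solubility), SI units mol/(m·s·Pa) — determined from
microelectrode pO2-vs-depth soundings through thin perfused slices.

The package is written for slice electrophysiologists and tissue-metabolism
modellers who profile oxygen tension through a submerged cortical slice and
want tissue oxygen consumption Q, which the profile curvature only yields as
the lumped ratio Q/Kt. It implements the full chain from raw soundings to a
dimensioned tissue coefficient Kt:

1. **Steady-state slab model.** At steady state, K·d²P/dx² = Q(P) in a slab
   of half-thickness L with surface tension Ps at x = ±L. With the
   piecewise-linear uptake law Q(P) = Q0·min(P/P\*, 1), the tension profile
   is closed-form: *parabolic* (P everywhere above the critical tension P\*),
   *paracosh* (a cosh basin for |x| ≤ δ joined smoothly to parabolic wings),
   or *cosh* (Ps < P\*). The critical depth δ solves a transcendental
   matching equation, handled by a bracketed root finder.
2. **Profile fitting.** The slice centre is located from the pressure
   minimum; the in-tissue samples are fitted to the parabola and the
   paracosh model; curvature 2a = Q0/K and the boundary gradient
   (∂P/∂x)|x=L follow.
3. **Flux conservation.** Where a stationary (non-flowing) fluid layer hugs
   an interface, the pressure trend in the fluid is linear and the same flux
   crosses both media, so Kt/Kf = (fluid gradient)/(tissue boundary
   gradient). Candidate ratios ≥ 1 are biologically impossible; ratios above
   the empirical cutoff 0.725 are treated as advection-contaminated.
4. **Fluid physics.** Kf for the perfusate from temperature, chlorinity
   (salting-out) and glucose content: Kf(no-Mg aCSF) = 2.262–2.348 ×10⁻¹⁴
   mol/(m·s·Pa) over 20–25 °C.
5. **Statistics.** Per-flow summaries, pooled ratio, and a paired-repeat
   variance decomposition separating experimental from biological variance
   (var(A−B) vs var(A+B) identities).
6. **Synthetic data.** A seeded generator with flux conservation built in,
   so the whole pipeline is testable against exact ground truth.

## Worked example

```r
library(kroghslice)

## fluid Krogh coefficient of no-Mg aCSF at 20 degC
kf <- krogh_fluid(t = 293.15, mcl = 4.904, glucose = TRUE)
#> 2.261555e-14            # mol/(m s Pa)

## simulate a repeat-pair study (6 locations x 2 soundings at 0.5 mL/min)
cfg <- preset_study("v5")
sim <- simulate_study(cfg, seed = 42)
res <- fit_profiles(sim$profiles, kf = kf)

groups <- summarize_groups(res)
#>   group_id curvature_mean ratio_mean   ratio_sd ratio_n
#> 1      0.5    0.003927798  0.5721639 0.07981548      10

pool <- pooled_ratio(groups$ratio_mean, groups$ratio_sd, groups$ratio_n)
final_kt(pool$mean, pool$stdev, kf)
#> $kt      1.29398e-14     # mol/(m s Pa)
#> $kt_sd   1.805071e-15
```

Reading: 10 of the 12 simulated soundings produced an accepted
lower-interface Krogh ratio; their mean 0.572 recovers the generator's
configured truth (0.562) within one standard error, and multiplying by the
fluid coefficient dimensions the tissue permeability at ≈1.29×10⁻¹⁴
mol/(m·s·Pa). Unit remappings for literature comparison:

```r
convert_krogh(krogh_value(1.29e-14, "si"), "mL_cm_min_atm")
#> 1.7561e-05 mL/(cm.min.atm)
```

## Command line

`inst/cli/krogh.R` wraps the exported functions:

```sh
Rscript inst/cli/krogh.R convert 1.29e-14 --from si --to mL_cm_min_atm
Rscript inst/cli/krogh.R simulate --preset v5 --seed 7 --out study/
Rscript inst/cli/krogh.R fit study/*.csv --kf 2.30e-14 --out results.json
Rscript inst/cli/krogh.R aggregate results.json --kf 2.30e-14
```

See `vignettes/krogh-methods.Rmd` for the model assumptions, parameter
choices, numerical details and known limitations.
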