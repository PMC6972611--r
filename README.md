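# llpsnmr

Quantitative NMR analysis of liquid–liquid phase separation (LLPS) as a
precursor to crystal nucleation of a weak-acid drug, with ibuprofen in water
as the model system.

Supersaturated solutions of poorly soluble acidic drugs can demix into a
dilute **mother phase** and a drug-rich **dense liquid phase** before any
crystal forms. Because every ¹H resonance of the drug then appears twice
(the dense-phase twin shifted by a few tenths of a ppm), solution NMR can
quantify the precursor phase directly. `llpsnmr` implements that analysis
chain for spectroscopists and crystallization researchers:

- **Speciation** — protolysis equilibrium IbuH ⇌ Ibu⁻ + H⁺; the forward
  titration model solves charge balance + mass action + conservation, so
  supersaturation follows from pH (`solve_titration_state()`,
  `protonated_fraction()`).
- **Partitioning & phase boundaries** — the lever rule splits the invariant
  total `c_tot` by peak-integral ratio
  (`n*/V = c_tot · I_a*/(I_a + I_a*)`); the mother-phase composition
  `c(IbuH)` vs. the dense-phase amount `n*` rises linearly and saturates,
  and a continuous two-segment fit `c = a + b·min(n*, x₀)` returns the
  **binodal** (intercept `a`) and **spinodal** (plateau `a + b·x₀`)
  limits of the miscibility gap (`fit_spinodal()`).
- **Translational diffusion** — Stejskal–Tanner analysis of PFG-STE decays,
  `ln(I/I₀) = −b·D`, `b = (γgδ)²(Δ − δ/3)`, per phase, plus the contrast
  ratio `D/D*` (`fit_stejskal_tanner()`, `diffusion_ratio()`).
- **Rotational dynamics** — inversion of `T1/T2` through the like-spin
  dipolar spectral-density ratio with `J(ω) = 2τc/(1 + ω²τc²)`, yielding
  rotational correlation times τc and the dense/mother slowdown factor
  (`tauc_from_t1t2()`, `tauc_contrast()`).
- **Interproton distances** — NOESY cross-peak calibration
  `d = (I_ref/I)^{1/6}·d_ref` against the 2.456 Å intramolecular reference,
  and comparison with published crystal-contact distances
  (`noe_distance_table()`, `compare_noe_to_crystal()`,
  `min_group_distances()`).
- **Synthetic data** — seeded generators for every input format
  (`scenario_config()`, `simulate_scenario()`), so the full chain is
  testable by parameter recovery without any instrument data.

## Worked example

Simulate a complete measurement set for the replication scenario (3 mM
total, binodal 0.43 mM, spinodal 0.71 mM, four compositions with measured
D/D\* pairs, a 6-fold rotational slowdown, dense-phase distances
2.04/2.71 Å) and run every stage:

```r
library(llpsnmr)
cfg_path <- simulate_scenario(scenario_config(), "scenario", seed = 3)
report <- run_pipeline(cfg_path)
report
#> llpsnmr pipeline report
#>   binodal 0.420 mM, spinodal 0.698 mM
#>   diffusion: 4 compositions, D/D* 34, 94, 200, 239
#>   tau_c contrast (dense/mother): 5.93
#>   NOE distances: a*-b* 2.037; b*-c* 2.720 A
#>   skipped stages: contacts
```

Reading the numbers: the phase-boundary fit recovers the 0.43/0.71 mM
ground truth to within the noise of a 12-point series; translational
diffusion is 34-fold slower in the dense phase at the first composition and
~240-fold at the last, while rotation slows only ~6-fold — the signature
that the two motions do not sense the same microviscosity; and the
dense-phase interproton distances (≈2.0 and 2.7 Å) are crystal-like, which
is what marks the dense liquid as a densified nucleation precursor.
`write_pipeline_report(report, "report.json")` serializes everything with
provenance (seed, config hash, package version).

A thin CLI wrapper with the same stages lives in
`inst/scripts/llps-cli.R`:

```sh
Rscript inst/scripts/llps-cli.R simulate --out-dir scenario --seed 3
Rscript inst/scripts/llps-cli.R pipeline --config scenario/pipeline.yaml --out report.json
```

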