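---
title: "Methods: NMR characterization of a dense liquid precursor phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR characterization of a dense liquid precursor phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpsnmr)
```

## The scientific problem

Poorly water-soluble acidic drugs such as ibuprofen can demix from
supersaturated aqueous solution into a dilute *mother phase* and a drug-rich
*dense liquid phase* before any crystal nucleates. That dense liquid is a
candidate precursor in a nonclassical nucleation pathway: densification
first, structural ordering later. `llpsnmr` implements the quantitative
chain that characterizes such a precursor with solution NMR:

1. **Speciation** — the protolysis equilibrium IbuH ⇌ Ibu⁻ + H⁺ links pH to
   the concentration of the sparingly soluble protonated form, so
   supersaturation can be dialed in by titration.
2. **Partitioning** — when both phases coexist in one tube, every resonance
   appears twice; integral ratios split the invariant total concentration
   between the phases (lever rule).
3. **Phase boundaries** — the mother-phase composition plotted against the
   dense-phase amount rises linearly and then saturates; the extrapolated
   intercept is the *binodal* limit and the plateau the *spinodal* limit of
   the liquid–liquid miscibility gap.
4. **Translational dynamics** — PFG-STE echo decays give per-phase diffusion
   coefficients `D` (mother) and `D*` (dense); their ratio quantifies the
   slowdown inside the dense phase.
5. **Rotational dynamics** — T1/T2 ratios of the phase-resolved peaks invert
   into rotational correlation times τc.
6. **Structure** — NOESY cross-peak intensities calibrate into interproton
   distances via the r⁻⁶ law, compared against published crystal contacts.

## Speciation model

`solve_titration_state()` solves, for a homogeneous solution, the coupled
system of mass action (`Ka·[IbuH] = [Ibu⁻][H⁺]`), water autoprotolysis,
mass conservation of the drug, and charge balance
`[Na⁺] + [H⁺] = [Cl⁻] + [OH⁻] + [Ibu⁻]`.

Assumptions, stated once:

* **Ideal dilute solution.** Activity coefficients are unity; total
  concentrations stay at the few-mM level, where this is a sub-percent
  approximation.
* **Volume additivity** of the titrant dosing.
* **pKa is an input.** The default 4.4 is a commonly quoted literature value
  for ibuprofen in water; it is configurable everywhere and should be
  treated as a required field for other compounds or media.
* The mother-phase concentration computed from a measured pH,
  `mother_phase_ibuh()`, is plain mass action rearranged for the protonated
  species. The small volume lost by the mother phase to the dense phase is
  neglected, consistent with the partitioning bookkeeping below.

Numerically, the charge-balance residual is strictly monotone in pH, so the
root is bracketed on pH ∈ [0, 14] (`uniroot`, tol 1e-12) and polished with
three Newton steps on [H⁺]; returned states are validated to residuals below
1e-10 on the molar scale and the solver errors out otherwise.

## Partitioning and the two-segment boundary fit

`partition_from_integrals()` is the exact lever rule: with mother- and
dense-phase integrals `I_a` and `I_a*`,
`n*(Ibu)/V_tot = c_tot · I_a*/(I_a + I_a*)`, and the mother-phase total is
computed as the algebraic complement so the two outputs sum to `c_tot` to
machine precision by construction. Only integral *ratios* enter, making all
downstream estimates invariant to spectrometer scaling.

The boundary estimator `fit_spinodal()` fits the continuous two-segment
model

c(IbuH)(n\*) = a + b·min(n\*, x₀),

i.e. a linear rise joined to a constant plateau at breakpoint x₀. For fixed
x₀ the model is linear in `min(n*, x₀)`, so the profile RSS is computed in
closed form over a 201-point breakpoint grid and then polished with 1-D
optimisation; on noiseless piecewise data this recovers a, b, x₀ exactly
(the RSS has a unique zero). The binodal is the intercept `a`, the spinodal
the plateau level `a + b·x₀`; standard errors come from the conditional
linear fit and therefore do not propagate breakpoint uncertainty — a
deliberate simplification flagged here.

Design choices that were genuinely open:

* **Coupling binodal and spinodal through one changepoint fit.** No rule is
  given for which "low concentration" points feed the linear fit; scanning
  the breakpoint removes that arbitrariness. `fit_binodal()` retains the
  manual-breakpoint path for users who want the plain restricted OLS.
* **Hard changepoint, not smooth saturation.** The plateau is modelled as an
  abrupt joint; a smooth crossover model would add a nuisance width
  parameter the data cannot constrain at a dozen points.
* **Unweighted OLS**, since integral noise is taken as homoscedastic.
* The abscissa is the dense-phase amount per total volume `n*(Ibu)/V_tot`
  (not the mother-phase concentration); with this choice the conservation
  constraint and the saturation reading of the spinodal are both natural.
* If the best breakpoint sits at the data edge (fewer than two points beyond
  it) no plateau is claimed: the spinodal is reported undetermined with a
  warning instead of an extrapolated number.

## PFG-STE diffusion

For rectangular gradient pulses the echo attenuates as
`ln(I/I₀) = −b·D` with `b = (γgδ)²(Δ − δ/3)` (`b_factor()`). Following
standard practice the default fit is linear least squares of `ln I` on `b`
(`fit_stejskal_tanner()`); a nonlinear exponential refit seeded by the
log-linear estimates is available as a robustness option. Pulse-sequence-
specific b corrections are supported by supplying a precomputed `b` column.
Defaults: ¹H γ = 2.675×10⁸ rad s⁻¹ T⁻¹, δ = 2 ms, Δ = 100 ms.

Contracts worth knowing: non-positive intensities are an error (the log is
undefined); a series whose total fitted decay is at rounding-error level is
reported as `D = 0` with `ok = FALSE` rather than a spurious positive
coefficient. `diffusion_ratio()` reports `D/D*` and rounds to an integer for
display, the convention used when quoting these contrasts.

## T1/T2 inversion into rotational correlation times

For like-spin (¹H–¹H) dipolar relaxation with isotropic tumbling,

* 1/T1 ∝ J(ω₀) + 4J(2ω₀)
* 1/T2 ∝ (3/2)J(0) + (5/2)J(ω₀) + J(2ω₀)

with Lorentzian spectral densities J(ω) = 2τc/(1 + ω²τc²). The coupling
prefactor cancels in T1/T2, which depends only on ω₀τc, equals 1 in extreme
narrowing and increases monotonically — so `tauc_from_t1t2()` can invert it
by bracketed root-finding on a log scale (tolerance such that the roundtrip
identity holds to < 1e-9 relative over six decades of τc). We invert the
exact spectral-density ratio rather than a published closed-form
approximation of it; the exact inversion subsumes the approximation and
differs from it at the few-percent level at intermediate ω₀τc. CSA and
heteronuclear contributions are ignored, consistent with the like-spin
dipolar assumption.

A measured T1/T2 of exactly 1 sits on the extreme-narrowing boundary where
τc is unidentifiable; it is reported as below detection with the bound
τc < 0.1/ω₀. Ratios below 1 are rejected as unphysical for this mechanism.
The spectrometer frequency is a required input for real data; 400 MHz is
the synthetic-scenario default.

## NOE distance calibration

In the initial-rate regime the NOESY cross-peak intensity scales as the
interproton distance to the −6 power, so with an intramolecular reference
pair of known geometry, `d = (I_ref/I)^{1/6} · d_ref` (`noe_distance()`).
The default reference is the fixed 2.456 Å distance between the α-methyl
(a) and isopropyl-methyl (c) protons of ibuprofen, with the dense-phase
(a\*)–(c\*) cross peak as `I_ref`; its own minor intermolecular
contributions are neglected, the same simplification the calibration
assumes. When several contacts feed one cross peak their intensities add
(`noe_intensity_from_distances()`), so an inverted summed peak yields the
r⁻⁶-weighted effective distance — dominated by, but not equal to, the
closest contact. Distances beyond the ≈5 Å NOE ceiling are flagged, not
discarded. No relaxation-matrix (spin-diffusion) treatment is attempted.

`min_group_distances()` computes exhaustive minimum intra- and
intermolecular distances from explicit Cartesian proton clusters (extended
XYZ with molecule ids and group labels); crystallographic symmetry expansion
is out of scope, and the published crystal-contact values shipped in
`crystal_reference_distances()` are clearly labelled literature constants
used only for comparison.

## What the synthetic generator emulates

`scenario_config()` fixes the replication scenario: total concentration
3 mM; binodal 0.43 mM and spinodal 0.71 mM; the four measured
per-composition (D, D\*) pairs from 555×10⁻¹² down to 2.05×10⁻¹² m² s⁻¹;
dense-phase interproton distances 2.04 Å (a\*–b\*) and 2.71 Å (b\*–c\*)
against the 2.456 Å reference; and a titration with 15 mM HCl and 6 mM
drug-salt titrants dosed at 0.2 mL min⁻¹ each (double dosing keeps the
total drug concentration exactly invariant). Quantities the study
conditions do not pin down were fixed once, as follows:

* **Rising-segment slope 0.5** for c(IbuH) vs n\*, which puts the plateau
  onset at (0.71−0.43)/0.5 = 0.56 mM, inside the sampled composition range.
* **Sampling design**: half the compositions below the plateau onset, half
  beyond it, up to 2.2 mM — a design a spectroscopist would choose to pin
  both segments.
* **Noise model**: multiplicative Gaussian on all NMR intensities
  (integrals 2%, decay points 1%, relaxation times 2%, NOESY 2%) and
  additive Gaussian 0.01 pH units on pH readings. No noise figures are
  reported for the original instrumentation; these levels make recovery
  non-trivial but reliable and are all config-exposed.
* **τc ground truths 0.3 ns (mother) and 1.8 ns (dense)** — a 6-fold
  contrast, the midpoint of the observed 5–7× rotational slowdown, placed
  where both phases sit outside extreme narrowing so the inversion is
  well-conditioned, mirroring that τc was measurable in both phases.
* **Dense-phase peaks shifted upfield** by 0.3 ppm (aliphatic) / 0.5 ppm
  (aromatic) in the nominal peak table; only the magnitude of the shift is
  established, and the sign convention is documented here.
* **Gradient schedules** auto-scale so the strongest gradient attenuates
  the echo by e⁻⁴ for the target D, giving every decay the same
  well-conditioned dynamic range.
* Every generator is a deterministic function of (config, seed), and the
  fixture writer derives per-stage seeds from one base seed by fixed
  offsets.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify about real data: spectral lineshapes, baseline and
phasing artefacts, t₁ noise in NOESY, exchange broadening, convection in
diffusion experiments, pulse-sequence b-factor corrections, and any smooth
(non-changepoint) saturation of the partitioning curve. A mismatched smooth
generator would stress the changepoint estimator; that robustness study is
left to the user via the config-exposed truth model.

## Problem sizes and determinism

The shipped checks run at desk scale: 50 seeds × 12-point partition series
for the boundary recovery, 200 seeds × 16-point decays for diffusion
recovery, 100 seed pairs for the rotational contrast, a 10⁶-point grid as
the inversion oracle, and 100 random titration configurations against a
1.4×10⁵-point pH-grid oracle. These sizes were chosen so Monte-Carlo error
is comfortably below the tolerances being asserted while the whole suite
runs in seconds.

## Known limitations

* Boundary standard errors are conditional on the fitted breakpoint.
* The speciation model is single-phase; past the binodal it serves as the
  bookkeeping baseline, not as a two-phase equilibrium model.
* No bulk viscosity is inferred from D or τc: translational and rotational
  slowdowns differ by an order of magnitude here, so the two motions do not
  sense a common viscosity and Stokes–Einstein/Stokes–Debye inversion would
  be misleading by construction.
* Raw spectra (FIDs, peak picking, integration) are upstream of this
  package; integrals, relaxation times and cross-peak intensities are
  inputs.

## A worked end-to-end run

```{r pipeline}
dir <- tempfile("scenario")
cfg_path <- simulate_scenario(scenario_config(), dir, seed = 3)
report <- run_pipeline(cfg_path)
report
```

The report carries the full provenance block (package version, seed, config
hash) and serializes with `write_pipeline_report()`.
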