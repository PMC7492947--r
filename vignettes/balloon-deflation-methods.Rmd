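---
title: "Methods: balloon-deflation trial statistics and gap-flow hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balloon-deflation trial statistics and gap-flow hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentflow)
```

## The question

During primary PCI for ST-elevation myocardial infarction, the stent
balloon is conventionally deflated abruptly.  A slower deflation (the
clinical protocol bleeds pressure at 2 atm/s) has been proposed to
reduce the hemodynamic disturbance in the culprit artery and, with it,
the risk of no-reflow.  Two quantitative questions follow:

1. **Trial statistics.**  In a 1:1 randomized comparison (105 rapid /
   106 slow), does slow deflation improve coronary flow — measured by
   the corrected TIMI frame count (cTFC) — and reduce infarct size
   (peak CK/CK-MB/troponin, CK-MB release AUC), and how do 30-day
   major adverse cardiac events (MACE) compare?
2. **Mechanism.**  What happens to flow velocity and wall shear
   stress (WSS) in the thin annular gap between the collapsing balloon
   and the vessel wall, as a function of deflation velocity?

The package implements both: a seeded synthetic-cohort generator with
the trial's arm-level statistical structure (the patient-level data are
not public), every statistic of the trial analysis, and a transparent
quasi-one-dimensional model of the gap flow.

## Synthetic cohort generator

`arm_spec()` holds, per arm: sample size, mean/SD pairs for each
continuous endpoint, probabilities for binary endpoints, categorical
distributions (infarct artery, baseline TIMI grade, Killip class),
enzyme-curve parameters, and daily hazards for the five 30-day event
types.  `default_arm_specs()` reads `inst/extdata/trial.cfg`, which
encodes the printed arm summaries of the trial report.

Modelling choices, and what they do and do not emulate:

* **Independent zero-truncated normals** for continuous endpoints.
  Only means and SDs are published, so no covariance is modelled; in
  particular the real correlation between cTFC and enzyme peaks is
  absent.  Passing tests therefore validate marginal structure, not
  joint structure.  The truncation location is calibrated
  (`uniroot` on the truncated-normal mean) so the *truncated*
  distribution has exactly the published mean — without this, heavy
  left-tail endpoints (CK-MB 272 ± 212 U/L, BNP 160 ± 146 pg/mL) would
  be biased upward by tens of units.
* **Frame counts are stored raw.**  The generator draws the target
  corrected count and stores the raw count (LAD values multiplied by
  1.7) plus per-timepoint occlusion flags, so the analysis path always
  exercises the `ctfc()` correction rule.  Baseline occlusion is
  coupled to a drawn TIMI grade of 0 (79/105 and 87/106), and occluded
  baselines score 100 frames; as a consequence the baseline-cTFC arm
  mean is the one endpoint whose published value (88 ± 23) is not
  recovered exactly — the published combination of 75% occlusion
  (= 100 frames each) with that mean is internally inconsistent, and
  the occlusion rule is given precedence.
* **Enzyme curves** are log-normal in time,
  \(c(t) = c_{peak}\exp[-(\ln(t/t_{peak}))^2/2\sigma^2]\), with
  \(t_{peak} = 12\) h and \(\sigma = 0.8\), sampled at the clinical
  schedule 0, 6, 12, 18, 24, 48, 72 h.  Only the schedule and peak
  statistics are published; the shape is a choice.  Because 12 h lies
  on the grid, the sampled maximum equals the drawn peak, keeping the
  peak statistic exact.  Measurement noise is available
  (`noise_sd`, default 0, capped at the peak).
* **Event times** are exponential with constant daily hazard
  \(\lambda = -\ln(1-p_{30})/30\) per event type, censored at 30 days,
  with no competing-risk structure (the counts are single digits) and
  follow-up fixed at 30 days for everyone.  The MACE composite takes
  each patient's first qualifying event.

Determinism: `generate_cohort()` draws under a local RNG state, so the
same `(specs, seed)` is bitwise reproducible and the caller's RNG
stream is untouched.

## Trial statistics

* `ctfc()`: occluded vessel → 100 frames; LAD → raw/1.7; LCX/RCA
  unchanged; full precision retained, rounding only at report time.
* `chi_square_2x2()` is Pearson *without* continuity correction — the
  form that reproduces the published 0.118 (no-reflow), 0.889
  (diabetes) and 0.474 (tirofiban) from the published counts; the
  Yates-corrected statistic does not.
* `fisher_exact_2x2()` implements the two-sided exact test with the
  "probability mass ≤ observed" rule, which reproduces the published
  small-cell p-values 0.683, 0.498 and 1.000 exactly.  The trial
  report's blanket "chi-square" methods statement is contradicted by
  its own small-cell p-values, so `build_tables()` selects the test by
  the classical rule — chi-square when every expected cell is ≥ 5,
  exact otherwise — and logs each choice.  That rule reproduces all
  five 30-day event rows (the two well-filled rows, heart failure
  0.788 and rehospitalization 0.793, match chi-square; the three
  sparse rows match the exact test).  A caveat worth knowing: the
  two-sided exact rule is discrete, so its p-values differ from
  chi-square by up to ~0.1 near p = 1 even for well-filled tables; the
  two agree in the typical case and converge as cells grow.
* `two_sample_t()` is Welch by default (pooled selectable) and accepts
  either raw vectors or `summary_stat(mean, sd, n)` triples, because
  published tables carry only summaries.  Summary-based p-values can
  differ from the originals in the third decimal (the published means
  are rounded): the published age comparison 0.322 recomputes as
  0.320 from the printed summaries.
* `auc_trapezoid()` integrates the sampled CK-MB curve over 0–72 h,
  interpolating at window edges and never extrapolating beyond the
  observed times.
* `km_curve()` wraps the product-limit estimator (survival package)
  per arm with right censoring; `km_survival_at()` evaluates the step
  function anywhere in the window.
* `required_sample_size()` is the two-arm normal-approximation
  formula, per arm \(2((z_{1-\alpha/2}+z_{power})\,\sigma/\delta)^2\),
  rounded up.  The trial states its design (4-frame difference, 80%
  power, two-sided 0.05, at least 192 subjects) but not the assumed
  SD; the default `sd = 9.89` frames is back-solved so the stated
  design returns exactly 192 and is flagged as a reconstruction.  (An
  SD of 9.9 gives 97/arm → 194 under the ceiling rule.)
* No multiple-testing adjustment is applied anywhere, matching the
  trial's analysis plan.

## Gap-flow hemodynamics

The published mechanism study used a bench apparatus with high-speed
imaging and an (unpublished) meshed CFD model.  Here the model class is
deliberately simpler — a **quasi-steady concentric-annulus lubrication
network** — chosen as the most transparent model that captures the
mechanism: during collapse the widening gap must be fed by suction
flow through a still-thin annulus, which transiently drives wall shear
stress far above its physiological level.

Assumptions: rigid vessel wall, concentric and axisymmetric balloon,
incompressible Newtonian fluid, inertia neglected within the gap.  The
last is the load-bearing one and is guarded numerically: the reduced
Reynolds number \(Re^* = (\rho u h/\mu)(h/L)\) is computed every step
and a warning flag is raised above 1.  In the default runs
\(Re^* \approx 0.01\) at the moment of peak WSS (thin-gap phase, where
the approximation matters); it exceeds 1 only late in deflation when
the gap is wide — where the annular solution tends to the ordinary
open-tube Poiseuille limit and the lubrication scaling is no longer
the relevant criterion.

Mechanics: with balloon radius \(R_b(x,t)\) inside a vessel of radius
\(R_v\), mass conservation with the prescribed wall motion gives
\(\partial Q/\partial x = -\partial A_{gap}/\partial t
= 2\pi R_b \dot R_b\), so \(Q(x)\) is piecewise linear on the grid.
Each cell is an annular Poiseuille element with resistance per length
\(8\mu/\pi[R_v^4 - R_b^4 - (R_v^2-R_b^2)^2/\ln(R_v/R_b)]\); the single
free constant (inlet flow) follows from the series pressure-drop
equation between the perfusion boundaries, including a lumped distal
resistance.  Wall shear stress is \(\mu|du/dr|\) at \(r = R_v\) for
the annular profile carrying the local flow; downstream of the
balloon it reduces to the open-tube value \(4\mu|Q|/\pi R_v^3\).  A
subtlety: the annular resistance converges to the open-tube value only
logarithmically as \(R_b \to 0\) (a thin central wire still adds
\(\sim 1/\ln\) drag), so the \(R_b = 0\) case is an exact branch and
the tests check the leading \(1/\ln\) correction rather than a naive
small-\(R_b\) equality.

**Deflation profile.**  The bench reference quantity is the
characteristic radial collapse speed \(v_b\); the published scenarios
halve and double it.  The profile is a quarter-sine from \(R_{b0}\)
down to \(R_{b,min}\): collapse is fastest the instant pressure is
released and decays smoothly to zero, so the peak speed is exactly
\(m\,v_b\) (multiplier \(m\)) and the duration is
\(T = \pi\Delta R/2mv_b\).  An S-shaped (smoothstep) start was
rejected: it would place peak collapse speed when the gap is already
wide, suppressing the thin-gap WSS transient that is the phenomenon of
interest, and a vented balloon does not accelerate gradually.  A
cosine axial taper (shoulders over 5% of the length, floor 0.5) models
the balloon ends.

**Defaults and why** (all exposed in `inst/extdata/sim.cfg`):

| parameter | default | rationale |
|---|---|---|
| vessel radius \(R_v\) | 1.5 mm | published reference diameters ≈ 3–3.4 mm |
| balloon length | 20 mm | published lesion length ≈ 24 mm |
| initial gap | 50 µm | near-occlusive apposition after stent inflation |
| final radius \(R_{b,min}\) | 0.05 mm | non-zero keeps the annular solver non-singular |
| gap floor | 10 µm | numerical guard; clamping is logged, not fatal |
| \(v_b\) | 1.5 mm/s | the bench value is not published; chosen so full deflation takes ≈ 1.5 s; scenario claims are tested as ratios/orderings, never as absolute values tied to this choice |
| fluid | blood-analog: µ = 3.5 mPa·s, ρ = 1060 kg/m³ | physiological WSS comparison (water preset mirrors the dyed-water rig) |
| \(P_{in}/P_{out}\) | 120 / 20 mmHg | the bench perfusion condition |
| distal resistance | 75 mmHg·s/mL | calibrated once, from the closed-form steady state, so the fully-open downstream WSS sits in the physiological 1–2 Pa band (it lands at 1.74 Pa); a reconstruction |
| grid, step | \(n_x = 64\), dt = 1 ms | peak quantities change < 2% under \(n_x \to 128\), dt → 0.5 ms |

Units: mmHg ↔ Pa via 133.322; all internal computation is SI, I/O is
clinical (mm, mmHg, mL/s).

**What the comparison shows.**  Running multipliers 0.5 / 1 / 2 with
`run_simulation()` and `scenario_report()`: peak gap velocity and peak
balloon-area WSS increase strictly with deflation speed, and at the
baseline speed the peak WSS exceeds the post-deflation physiological
downstream WSS by well over 60-fold.  The source study's absolute
values (110–115 Pa under the balloon; 1.75 Pa downstream at ≈ 0.18 s)
came from an unpublished solver, geometry and \(v_b\), so absolute
reproduction is not expected; this model's defaults land in the same
order-of-magnitude bands, and only the ratio and ordering claims are
treated as checkable results.

## Numerical choices and degenerate inputs

* Truncated-normal sampling is by rejection (acceptance ≥ ~0.8 for
  every shipped endpoint); `sd = 0` returns the mean exactly, which is
  what makes the degenerate-spec tests exact.
* `fisher_exact_2x2()` uses a 1 + 10⁻⁷ relative tie tolerance on the
  hypergeometric mass (the convention of the standard implementations)
  and caps the summed p at 1 against floating accumulation.
* Both-arms-zero-variance t-tests return p = 1 by convention (logged)
  when means agree, p = 0 when they differ.
* `solve_gap_flow()` clamps the balloon radius to keep the gap above
  the floor (logged on the state); the wall-motion source is zeroed on
  clamped cells so mass stays conserved.  The per-step conservation
  residual is ~10⁻¹⁶, tested against direct numerical differentiation
  of the gap volume.
* Profile evaluation outside \([0, T]\) clamps to the endpoint radii.

## Problem sizes

The shipped analyses use the trial's own sizes: cohorts of 211
patients; 200 replicate cohorts for the moment-recovery checks; the
solver at \(n_x = 64\) with 1 ms steps (≈ 1500–3000 steps per
scenario).  A full pipeline run (`run_all()`) completes in a few
seconds on one CPU.

## Limitations

* Endpoint independence within a patient is an assumption, not data;
  between-endpoint correlations in the tables are not emulated.
* The hemodynamic model is quasi-1D: no eccentricity, no
  fluid–structure interaction, no transport of embolic debris — it
  quantifies the flow/WSS mechanism, not embolization itself.
* The published hyperlipidemia (0.544) and smoking (0.631) p-values
  are not reproducible from the published counts by either implemented
  test (they recompute as 0.342 and 0.633); they are treated as
  presumable errata and deliberately not tuned to.
* Follow-up beyond 30 days, covariate adjustment, interim analyses and
  imputation are out of scope, matching the source analysis plan.
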