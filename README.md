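# stentflow

Does the *speed* at which a stent balloon is deflated during primary
PCI matter?  In ST-elevation myocardial infarction, abrupt deflation
of the stent balloon may produce a suction transient in the thin
annular gap between balloon and vessel wall, and with it a spike in
wall shear stress (WSS) that could promote distal embolization and
no-reflow.  `stentflow` implements, end to end:

* a **seeded synthetic cohort generator** with the arm-level
  statistical structure of a 1:1 randomized rapid- vs slow-deflation
  trial (105/106 patients; corrected TIMI frame counts at four
  timepoints, CK/CK-MB/troponin release, 30-day events) — the
  patient-level data are not public, so every downstream stage runs on
  reproducible synthetic cohorts;
* the **complete trial analysis**: the cTFC rules (occluded vessel =
  100 frames, LAD counts divided by 1.7), Pearson chi-square without
  continuity correction and the two-sided exact hypergeometric test
  for 2×2 endpoint tables, Welch/pooled t-tests from raw data or
  summary triples, the trapezoidal CK-MB release AUC (infarct-size
  surrogate), Kaplan–Meier curves of freedom from the MACE composite,
  and the design-stage sample-size formula
  `n/arm = 2((z_{1-α/2}+z_{pow})·σ/δ)²`;
* a **quasi-1D lubrication model of the balloon–vessel gap**: the
  deflating balloon is an axial chain of concentric-annulus Poiseuille
  elements with a moving inner boundary; mass conservation
  `∂Q/∂x = −∂A_gap/∂t` plus the series pressure-drop equation between
  the perfusion boundaries (120/20 mmHg) yields the transient gap
  flow, gap velocity and wall WSS, compared across deflation-velocity
  scenarios (0.5·vb, vb, 2·vb).

## Worked example

The repository is organised as a workflow: `analysis/01_simulate_cohort.R`
… `analysis/04_report.R` run the stages and write their tables under
`results/`.  The same can be driven from R:

```r
library(stentflow)

# published counts entered directly
chi_square_2x2(c(8, 97, 3, 103))$p_value   # 0.118  (no-reflow, 8/105 vs 3/106)
fisher_exact_2x2(c(3, 102, 2, 104))        # 0.683  (30-day mortality)
required_sample_size(delta = 4)$n_total    # 192

# a seeded synthetic cohort, analysed
coh <- generate_cohort(seed = 20150801)
tabs <- build_tables(coh)
tabs$table4[tabs$table4$endpoint == "cTFC end of PCI (frames)", ]
#> rapid "26.7 ± 9.0"   slow "23.5 ± 6.6"   p_value 0.003   test "welch"

# deflation-velocity scenarios
rep3 <- scenario_report(lapply(c(0.5, 1, 2), function(m)
  run_simulation(default_sim_config(multiplier = m))))
rep3$summary
#>  multiplier T_deflate peak_wss_Pa peak_gap_velocity_m_s tau_physiological_Pa wss_ratio
#>         0.5     2.932       73.65                0.4298                 1.74     42.34
#>         1.0     1.466      129.39                0.4697                 1.74     74.38
#>         2.0     0.733      240.87                0.5767                 1.74    138.46
```

Reading the output: the synthetic slow arm ends PCI about 3 frames
faster than the rapid arm (better flow), mirroring the trial's primary
endpoint.  In the simulation, faster deflation strictly increases both
the peak gap velocity and the peak balloon-area WSS; at the baseline
deflation speed the WSS transient reaches ~129 Pa against a
physiological downstream level of 1.74 Pa — a ~74-fold amplification,
i.e. "over 60 times" the physiological value, while halving the
deflation speed cuts the transient roughly in half.

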