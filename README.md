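# gripsig

Analysis of **tactile signatures of the human hand** in activities of daily
living, from multi-sensel glove pressure recordings.

A sensorized glove with 361 pressure sensels, grouped into 18 anatomical
regions (thumb and finger phalanges, distal palm, thenar/hypothenar
eminences), records contact pressure at 50 Hz while subjects perform everyday
manipulation tasks. `gripsig` is for researchers in hand biomechanics,
prosthetics and robotic grasping who want population-level answers from such
recordings:

* **Grip force**: GF(t) = Σ over sensels of p(t) × A, with sensel area
  A = 16 mm² (4 mm pitch squared), after median filtering (window 3) and
  discarding sensels that saturate at the 517 kPa full scale.
* **Synchronization**: subjects pace tasks differently, so each subject's
  normalized GF curve is aligned to a reference subject with a bounded
  three-segment piecewise-linear time warp φ: (0,0) → (t1,t1ref) →
  (t2,t2ref) → (1,1), t1,t1ref ∈ [0.15, 0.35], t2,t2ref ∈ [0.65, 0.85],
  minimizing ‖D[warped subject] − D[reference]‖₂ over first derivatives. The
  default optimizer is an exhaustive 21⁴ lattice search (deterministic, the
  test oracle); a seeded evolutionary search is available as
  `strategy = "stochastic"`.
* **Contribution to grip force**: CGF_r(t) = F_r(t)/GF(t); the per-task mean
  CGF averages over the instants where GF exceeds its task mean. After
  scaling each subject to the reference mean GF and discarding the 4 most
  outlying subjects, region/task Pearson correlations, peak force/pressure
  tables, and balanced two-way ANOVAs (subject × task, additive model) are
  computed.
* **Signature graphs**: per-task circles proportional to region CGF, with
  opposition lines connecting finger regions to thumb/palm regions when both
  exceed 5%; rendered as deterministic SVG.
* **Synthetic cohorts**: `generate_study()` produces study-shaped data (22
  subjects × 21 tasks, ~14 s tasks, 5–100 N peaks, known region weights,
  pace warps, noise, spikes, saturation) with analytic ground truth, so the
  full pipeline is testable without hardware.

## Worked example

```r
library(gripsig)

layout <- default_layout()
layout
#> <sensor_layout> 18 regions, 361 sensels, pitch 4 mm, 517 kPa max

cfg <- synthetic_config(n_subjects = 6, n_tasks = 3, duration_mean_s = 6,
                        noise_sd_kpa = "2pct", seed = 42)
study <- generate_study(cfg)
length(study$recordings)
#> [1] 18

out <- tempfile()
res <- run_pipeline(study$recordings, out, n_discard = 1, seed = 42)

round(res$cgf$task_region_mean[1, ], 3)   # task 1 mean CGF per region
#>  [1] 0.023 0.219 0.010 0.005 0.080 0.076 0.143 0.004 0.022 0.009 0.015 0.088
#> [13] 0.009 0.062 0.168 0.022 0.027 0.019
```

Region 2 (proximal thumb) carries ~22% of the grip force in this simulated
task and region 15 (distal palm) ~17%; rows sum to 1 by construction.

```r
res$signatures[["1"]]
#> <signature_graph> 18 regions, 10 opposition edges (CGF > 5%)

round(res$task_corr, 2)      # Pearson r between the tasks' region patterns
#>       1     2     3
#> 1  1.00  0.71 -0.21
#> 2  0.71  1.00 -0.26
#> 3 -0.21 -0.26  1.00

res$anova_gf                 # two-way ANOVA on unscaled windowed mean GF
#>     effect         ss df         ms        f            p
#> 1     task 12201.9222  2 6100.96112 71.15888 1.219684e-06
#> 2  subject   554.3892  5  110.87784  1.29323 3.400581e-01
#> 3 residual   857.3717 10   85.73717       NA           NA
```

Tasks 1 and 2 share similar signatures (r = 0.71); the task factor dominates
the grip force (p ≈ 1e-6) while this small simulated cohort shows no subject
effect. The output directory contains `cgf_matrix.csv`, `task_corr.csv`,
`region_corr.csv`, `peak_table.csv`, `mean_curves.csv`, `durations.csv`,
`anova_gf.csv`, per-task `sync_task*.json` and `signature_task*.svg`, and a
`summary.log`.

A command-line wrapper is installed with the package
(`system.file("exec", "gripsig", package = "gripsig")`):

```sh
gripsig simulate --out data/ --subjects 6 --tasks 3 --seed 1
gripsig report --in data/ --out report/
```

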