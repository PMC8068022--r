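---
title: "Grip-force sharing and tactile signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grip-force sharing and tactile signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripsig)
```

## The problem

When a person turns a door handle, writes with a pen, or lifts a briefcase,
the grip force is not shared evenly across the hand. A sensorized glove with
361 pressure-sensing elements ("sensels"), grouped into 18 anatomical regions
(thumb and finger phalanges, distal palm, thenar and hypothenar eminences),
records how that force is distributed over time. `gripsig` turns such
recordings — one per subject per activity — into comparable, population-level
summaries:

* the grip force **GF(t)**, the sum of all sensel forces at an instant;
* each region's **contribution to grip force**, CGF\(_r\)(t) =
  F\(_r\)(t)/GF(t), a share in \[0, 1\] summing to 1 across regions;
* a per-task **tactile signature**: the vector of mean region CGFs, rendered
  as proportional circles with opposition lines between finger regions and
  thumb/palm regions when both exceed 5%.

Because different subjects execute the same task at different paces, curves
must be synchronized before averaging. `gripsig` implements a bounded
three-segment piecewise-linear time warp rather than classic dynamic time
warping, which can produce singularities (flat stretches where one signal is
artificially held) that distort force profiles.

## Pipeline and model

### Preprocessing

1. **Median filter** (window 3, per sensel) removes single-frame acquisition
   artifacts. Edges use replicate padding, so endpoints are preserved and
   constant signals pass through unchanged. A width-1 spike is fully
   eliminated; on a sloped signal the two neighboring output samples may shift
   by at most one frame-to-frame step, which is the sharpest guarantee a
   width-3 median can give.
2. **Saturation masking**: any sensel that reaches the 517 kPa full scale
   (75 psi) at any frame is zeroed for the whole recording. A cell that
   clipped is untrustworthy for that grasp; per-frame masking is available via
   `per_frame = TRUE`. Both the fraction of affected frames and of affected
   sensel-recordings are reported, since "percent of data discarded" is
   ambiguous between the two.
3. **Force conversion**: each sensel spans 16 mm² (4 mm pitch squared), so
   F\[N\] = p\[kPa\] × 1000 × 16 × 10⁻⁶. GF and the 18 region forces are sums
   over sensels; conservation (GF = Σ region forces = Σ sensel forces) holds
   to machine precision and is asserted in the tests.

### Time normalization and filtering

Task time is rescaled to \[0, 1\] and curves are linearly interpolated at
increments of 0.01 (101 points). For the synchronization cost the GF curve is
first smoothed with a zero-phase third-order low-pass Butterworth filter,
cutoff 10 Hz. One deliberate choice: the filter is applied **in native time at
the 50 Hz sampling rate, before normalization**. A cutoff in Hz is only
meaningful in physical time; applying it after normalization would make the
effective cutoff depend on each execution's duration. For band-limited
signals the two orders agree within 1% RMS (regression-tested). No DSP
package is assumed: the bilinear-transform design and the
forward-backward pass (odd extension, steady-state initial conditions) are
implemented in the package and unit-tested against frozen reference values
from an independent implementation.

### Synchronization

For each task:

1. every subject's filtered GF curve is placed on the 101-point grid;
2. the **reference subject** is the one whose curve is closest (Euclidean
   distance) to the pointwise mean curve; ties break to the lowest subject id;
3. each other subject's warp is found by minimizing the Euclidean distance
   between **first derivatives** of the warped subject curve and the
   reference curve.

The warp φ is continuous, piecewise linear through (0, 0), (t1, t1ref),
(t2, t2ref), (1, 1), with t1, t1ref ∈ \[0.15, 0.35\] and t2, t2ref ∈
\[0.65, 0.85\]. These bounds keep φ strictly increasing and cap the
deformation. Derivatives (central differences on the grid) are compared
rather than values so that peak/valley *timing* drives alignment and constant
offsets are ignored; the derivative is computed after warping, since
computing it before would mis-scale slopes in stretched segments.

The default optimizer is an **exhaustive lattice search** at resolution 0.01
(21⁴ = 194,481 evaluations, ~0.4 s in compiled code), which is deterministic,
seed-free, and serves as the oracle for the `stochastic` strategy — a seeded
differential-evolution search over the continuous box standing in for the
population-based (genetic) optimizer originally used; gradient methods fail
here because the cost has local minima. On every packaged fixture the
stochastic result must match the grid optimum within 1e-6.

The warp estimated on *filtered* curves is applied to the *unfiltered* GF and
to every sensel/region series: filtering exists to stabilize the derivative
cost, not to alter the data. Warping never rescales instantaneous values.

### Contribution analysis

After synchronization, subjects' force channels are scaled by
meanGF(reference)/meanGF(subject), compensating sensor-fit amplitude
differences; CGF is a ratio and is unchanged by this. The 4 subjects whose
scaled GF curve is farthest (Euclidean) from the task's mean curve are
discarded (22 → 18 retained at the study's size). Distances are computed on
scaled curves: unscaled distances would be dominated by exactly the
amplitude differences that scaling is meant to remove, so amplitude outliers
would crowd out genuine shape outliers.

The **mean CGF** for a subject × task averages the instantaneous CGF over the
analysis window {t : GF(t) > mean GF}, i.e. the part of the task where force
is meaningfully applied. Instants with GF ≤ ε (default ε = 0.1 N,
configurable) are excluded to avoid 0/0; a constant-GF recording falls back
to all instants with GF > ε and is flagged. Task–task correlations use each
task's subject-averaged 18-region vector; region–region correlations pool all
subject × task observations, retaining per-subject variation (the source
prose does not fix either convention; these are documented package choices).
Peak force/pressure tables average per-task maxima over the retained
subjects, matching the n = 18 convention of the mean curves.

### ANOVA

With one observation per subject × task cell the two-way model is necessarily
additive — no interaction is estimable — so the sums of squares have closed
forms and are implemented directly (and checked against R's linear-model
decomposition in the tests). The dependent variable is the *unscaled*
windowed mean GF (or CGF): scaling would remove precisely the
between-subject variation the subject factor is testing. Zero-residual
(perfectly additive) tables yield an infinite F flagged with p = 0 rather
than an error.

### Signature graphs

Edges connect finger-class regions (3–14) to thumb- (1–2) or palm-class
(15–18) regions when both mean CGFs exceed the threshold (default 5%).
Thumb–palm and finger–finger pairs are never connected: the opposition
pattern is defined from the fingers' side. Region 17/18 (thenar/hypothenar
eminences) count as palm. Circle radius is linearly proportional to CGF (the
literal reading of "proportional"; area-proportional would compress
differences). Edge sets are monotone in the threshold — lowering it never
removes an edge — and this is property-tested. The SVG renderer is a pure
string template, so identical graphs produce byte-identical files.

## The synthetic world

The generator states a study-shaped world with analytic ground truth:

| parameter | default | rationale |
|---|---|---|
| cohort | 22 subjects × 21 tasks | the study's dimensions |
| sampling | 50 Hz, 0–517 kPa, 361 sensels | sensor spec |
| task duration | lognormal, mean 14 s, sdlog 0.25 | ~14 s mean execution; sdlog chosen so the interquartile pace spread stays within the warp bounds |
| GF profiles | 1–3 raised-cosine bumps, peaks 5–100 N | the observed range from key-pressing to briefcase-lifting; profiles start and end at 0 |
| region weights | seeded, a few dominant regions incl. a thumb/palm opposer | emulates real signatures; weights sum to 1 and are the ground-truth CGF |
| amplitude | lognormal, sdlog 0.2 | sensor-fit differences between subjects |
| pace warp | uniform within the warp bounds | makes synchronization a well-posed inverse problem; applied in continuous time before sampling |
| noise | 0.5 kPa per sensel, or `"2pct"` of each task's peak sensel pressure | mild electronics noise |
| spikes | 0.02 per sensel-second, interior frames | single-frame artifacts the median filter is designed to remove |
| saturation | clip at 517 kPa, events recorded | matches the sensor's hard limit |

What a green recovery test establishes: the pipeline inverts the generative
model — pace warps are recovered, amplitude scaling cancels, and task-mean
CGFs match the generating weights within 0.05 under 2%-of-peak noise. What it
does **not** establish: realism of soft-tissue contact mechanics, sensor
drift/crosstalk, correlated noise, or region co-activation structure of real
grasps; conclusions about real data still require the real recordings.

## Numerical choices and degenerate inputs

* Grid-search ties resolve to the lexicographically smallest
  (t1, t2, t1ref, t2ref); reference-selection and outlier-discard ties
  resolve by subject id. All pipeline stages are deterministic given a seed.
* Warp-parameter validation tolerates 1e-9 beyond the bounds to absorb
  floating accumulation in lattice construction.
* Subjects with identically zero GF are excluded from synchronization (their
  derivative cost is undefined) with a warning; a fully saturated recording
  (GF ≡ 0 after masking) warns at masking time.
* Recordings are serialized with 17 significant digits, making
  write → read the identity on doubles.
* On-disk format is a wide CSV (`time_s,s001..s361`, kPa) plus a JSON
  sidecar; the native export dialect of the original acquisition software is
  not parsed — an adapter can be added without touching the pipeline.

## Known limitations

* Right-hand layout only; the packaged render coordinates are schematic, not
  anthropometric.
* The multivariate (MANOVA) sex test on CGF is not implemented; the one-way
  GF ANOVA is.
* The three-segment warp assumes one dominant pace difference per task
  segment; tasks with more than two misaligned internal events would need
  more knots.
* Peak tables reflect the synthetic or supplied cohort; they are not
  reference values for hand biomechanics.
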