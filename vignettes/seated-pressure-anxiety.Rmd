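---
title: "Detecting driver anxiety from seated pressure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver anxiety from seated pressure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pressanx)
```

## The problem

Anxiety while driving shows up in the body before it shows up anywhere a
camera or electrode can conveniently look: people load their thighs, hips and
lower back more heavily, fidget more, and sway fore–aft in the seat. Two thin
pressure mats — one on the seat cushion, one on the backrest, each a 32 × 32
sensor array sampled at 5 Hz in mmHg — capture this unobtrusively. `pressanx`
implements the full analysis chain from raw pressure frames to two outputs:

1. a **screening table** of statistical features that separate anxious from
   calm sitting in a paired design, with effect sizes, and
2. a **scenario ranking**: which driving scenarios (congestion, roundabout
   entry, emergency braking, …) reproduce the anxiety pressure pattern most
   strongly, after correcting for the pressure changes the driving manoeuvre
   itself causes.

Because no raw recordings of this kind are publicly deposited, the package
ships a synthetic study generator that plants known structure, so every stage
can be validated by parameter recovery rather than by eyeballing.

## The feature set

Each frame pair is segmented into six anatomical regions: left/right buttock
(BTL/BTR) and left/right thigh (THL/THR) on the seat pad, upper/lower back
(UB/LB) on the backrest. The published region layout names the regions but
not the cell boundaries, so the default map splits each pad at its midlines
(thighs = front half of the seat, rows `1:16`; left = columns `1:16`; upper
back = top half of the backrest). The map is a plain data structure
(`region_map()`), fully overridable, serialized to JSON beside every run's
outputs so the convention is always auditable.

Per region and frame, `compute_frame_features()` returns:

* **average contact pressure** over the cells registering pressure > 0 (mmHg),
* **contact area** — the count of those non-zero cells,
* **centre of pressure (COP)** — the pressure-weighted centroid in 1-based
  (row, col) grid units; row is the anterior–posterior axis,
* the **shares** of each region's average pressure and area in the
  six-region totals (`avgSUM`, `aSUM`).

That is 36 variables per frame. Averaging over non-zero cells (rather than
all region cells) is the reading consistent with pairing "average pressure"
with a "sensing area" of non-zero points; `featurize_session()` exposes the
convention in one place should anyone want the alternative. Empty regions
get average 0, area 0 and an *undefined* COP (`NA`), and zero-denominator
shares are `NA` — a region with no contact has no position, and fabricating
a 0 would bias downstream statistics. `NA`s are excluded pairwise later.

Outlier cleaning (`clean_outliers()`) flags per-feature robust z-scores
(median/MAD) above 4 and replaces them by linear interpolation of
neighbouring frames, reporting counts per feature. MAD-zero features are
left alone.

## Event windows

Every analysed epoch is exactly 10 s = 50 frames at 5 Hz:

* **instantaneous** events (a horn press, an emergency brake): the half-open
  interval `[anchor − 5 s, anchor + 5 s)` — 25 frames of emotion emergence
  before the mark, the anchor frame, and 24 frames of development after it;
* **continuous** events (congestion, consecutive turns, parking): the first
  10 s from onset;
* **entry/exit** events (roundabouts): two instantaneous-style windows,
  treated downstream as separate scenarios `*_entry` and `*_exit`.

The half-open convention is forced by wanting "5 s before and after" to be
exactly 50 frames; anchors are snapped to the nearest frame because event
marks are asynchronous to the 5 Hz clock. `pair_windows()` joins calm and
anxious windows per subject and scenario and *excludes* (with a report)
anything unpaired — no imputation, mirroring complete-case analysis.

## Screening

Each window is reduced to Mean, Std and Max of its 36 variables
(`window_stats()`, 108 statistics). For each statistic the paired difference
`D[j, i] = X_anx − X_calm` across subjects is screened:

1. **Normality gate**: Lilliefors test at α = 0.05. The p-value comes from a
   seeded Monte-Carlo null (default 10 000 replicates, cached per sample
   size) rather than lookup tables — exact at any n and reproducible.
   Zero-variance differences are flagged degenerate and sent down the
   non-parametric branch.
2. **Test**: paired t-test (two-sided) if normality is not rejected,
   otherwise the Wilcoxon signed-rank test. The signed-rank implementation
   discards zero differences, uses average ranks for ties, and computes the
   exact conditional null of `W+` by generating-function convolution for up
   to 30 non-zero pairs (identical to enumerating all `2^n` sign
   assignments, which the tests verify), falling back to a tie-corrected
   normal approximation above that.
3. **Effect size**: paired Cohen's d (`mean(D)/sd(D)`) on the t branch;
   matched-pairs rank-biserial `r = (W+ − W−)/(W+ + W−)` on the Wilcoxon
   branch. The two are never mixed silently — every record carries
   `effect_type`.
4. **Gate and rank**: significance is the hard threshold p < 0.005 with no
   further multiple-testing correction (that is the procedure being
   implemented; the threshold is configurable). Significant features are
   ranked by |effect size|, ties broken by smaller p then name.

`region_summary()` attributes each significant feature to its region;
`volcano_table()` exports effect size against −log10 p. `sam_validation()`
applies the same signed-rank machinery to the paired SAM self-reports
(valence/arousal/dominance, 1–9).

## Scenario similarity

For each subject, the **anxiety prototype** is the difference of the 108
window statistics between the anxious and calm static-induction windows
(Δ_static). For each scenario, the **scenario difference** Δ_scene is the
anxious-driving minus calm-driving window statistics — the *dynamic baseline
correction*: because braking shifts weight forward in both conditions, the
subtraction removes the manoeuvre's own signature and keeps only what
anxiety adds. The score is the cosine similarity

    Sim = (Δ_scene · Δ_static) / (‖Δ_scene‖₂ ‖Δ_static‖₂)

computed per subject, then averaged (unweighted) over subjects per scenario
and ranked. Cosine compares direction only, so a heavier subject with the
same *pattern* of change scores identically — the amplitude invariance the
per-subject load-scale in the generator exists to exercise.

Design points that were genuinely open:

* **Per-subject prototype** (not a pooled one) is the default, consistent
  with reporting per-subject similarities; a pooled-prototype mode would be
  a small extension of `similarity_table()`.
* **Feature set**: all 108 statistics by default; restricting to the
  screened significant set is a supported, logged option
  (`pipeline_config(similarity_features = "significant")`).
* **Scaling**: raw differences by default. The 108 components mix units
  (mmHg, cell counts, grid units), so the raw cosine is unit-weighted;
  per-feature standardization by the pooled across-subject sd is available
  (`standardize = TRUE`) but off, because the unscaled form is the faithful
  default and the choice should be visible, not silent.
* **Missingness**: cosines are computed on the pairwise shared support, and
  a pair is dropped (reported) when less than 80% of components are shared.
* A zero difference vector has no direction: its similarity is undefined and
  excluded from means, never coerced to 0.

## The synthetic generator

`simulate_study()` emulates the study design: each subject contributes a
calm and an anxious static induction session and a calm and an anxious drive
over eight scenario labels, plus paired SAM records.

The pressure field of each region is a truncated separable Gaussian blob,
rescaled per frame so the mean over its non-zero cells equals a target level
exactly, with multiplicative log-normal frame noise. The anxiety pattern is
planted as the study conditions describe it:

| parameter | default | meaning |
|---|---|---|
| regional pressure gains | 1.12–1.20 lower body, 1.0 UB | 10–20% elevation of pressure and contact area (blob width scales as √gain) |
| `cop_row_sway_amplitude` | 0.51 grid units | extra anterior–posterior sway: slow sinusoid + AR(1) "regression" process |
| `cop_col_sway_amplitude` | 0.3 grid units | lateral sway, *equal* across conditions (≤ 1 unit) |
| `volatility_gain` | 1.5 | frame-noise multiplier under anxiety |
| `spike_rate` | 0.03 /s | Poisson-timed 2–4-frame postural-adjustment transients |
| level noise sd | 0.12 | multiplicative frame noise (log scale) |
| subject load scale | lognormal, sd 0.15 | between-subject weight proxy |
| calm drift | 2 × 10⁻⁴ /s | slight smooth upward trend, equal across conditions |

Where the study conditions state a value (grid, rate, gains, sway
amplitudes, SAM medians 5/2/8 vs 2/8/2) the default *is* that value. Where
they do not, a value was fixed once on realism grounds: the 12% frame noise
was chosen so that scenario-mean similarities come out on the order reported
for real data (roughly 0.3–0.7) rather than the near-1 values a very clean
generator produces, and one postural spike per ~30 s of anxious sitting
rather than one per window. Spikes perturb pressure level and contact width
but not COP, so the sway amplitude parameter alone controls COP variability.
Calm-state drift is configurable and equal across conditions by default.

In driving sessions, each scenario's window gets a **task component**
(additive regional pressure shifts and a fore–aft COP shift, identical in
both conditions — braking pushes the thighs forward whether or not you are
anxious) plus, in the anxious condition, the anxiety pattern scaled by the
scenario's coupling κ ∈ [0, 1]. The default route plants a descending κ
profile (roundabout entry 0.90 … parking 0.15) matching the qualitative
ordering reported for real scenarios. With κ = 0 and noise off, calm and
anxious drives are bit-identical, so baseline-corrected differences vanish
*exactly* — the defining property of the correction, and one of the
acceptance checks.

### What the generator does and does not emulate

It reproduces: paired structure, regional gains with area in step,
anterior–posterior (not lateral) sway asymmetry, volatility and spikes,
between-subject amplitude differences, scenario task components and graded
anxiety coupling. It does **not** model posture classes, chair geometry,
clothing, time-on-task fatigue, or any musculoskeletal mechanics; its noise
is temporally simple (log-normal i.i.d. plus AR(1) sway). Passing the
recovery tests therefore shows the *pipeline* is correct and well calibrated
— it does not certify performance on real drivers.

One structural caveat worth knowing: the share features are compositional
(all divide by `avgSUM`/`aSUM`), so a genuine pressure gain confined to,
say, the thighs mechanically depresses the *share* features of untouched
regions. A grid-level plant can therefore never produce effects confined to
three regions' features; region-confinement checks are done by planting at
the feature level, and interpretation of regional shares on real data should
keep this coupling in mind.

## Numerical choices and degenerate inputs

* Lilliefors Monte-Carlo null: seeded, cached per (n, reps, seed); the
  cached simulation is RNG-isolated so it cannot perturb a caller's stream.
* Signed-rank p-values: exact convolution up to n = 30; two-sided p is
  `min(1, 2·min(P(W+ ≤ w), P(W+ ≥ w)))`; all-zero differences give p = 1.
* Cohen's d with zero-spread differences, rank-biserial with all-zero
  differences, COPs of empty regions, shares with zero denominators: all
  `NA` with explicit meaning, excluded pairwise downstream.
* Windows: anchor snapping is nearest-frame; extraction errors state frames
  available vs required rather than truncating silently.
* Determinism: every stochastic stage takes a seed; identical seeds give
  bit-identical sessions and byte-identical report files.

## Problem sizes used in the shipped analyses

The `analysis/` drivers and the validation suite use 18 subjects × 8
scenario labels (the complete-case sample size of the motivating study),
60 s static inductions, and 20 independent seeds for the
coupling-recovery check; the screening calibration uses 2000 simulated null
features at n = 25 subjects and 200 replicates for power at d = 2. These
sizes give stable Monte-Carlo estimates (binomial 99% bands for the
false-positive rate; ±0.15 for effect-size recovery at n = 25).

## Limitations

* The default region boundaries are a stated convention, not an anatomical
  fit; real deployments should calibrate the map per seat.
* The screening applies the procedure's hard p < 0.005 gate and nothing
  else; it is a screen, not a confirmatory analysis.
* Raw-cosine similarity weights features by their numeric scale; the
  standardized variant changes the ranking emphasis and is provided for
  sensitivity analysis.
* Synthetic validation bounds what can be claimed: the pipeline recovers
  what was planted, under the generator's assumptions.
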