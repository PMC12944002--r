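# pressanx

Seated-pressure analysis of driver anxiety: who tenses up, where, and in
which driving scenarios.

Anxiety changes how people sit. Relative to a calm baseline, anxious drivers
load the thighs, buttocks and lower back more heavily (on the order of
10–20%), show more frame-to-frame volatility and sudden postural
adjustments, and sway more along the anterior–posterior axis, while the
upper back and lateral balance stay quiet. `pressanx` turns recordings from
two 32 × 32 pressure mats (seat cushion + backrest, 5 Hz, mmHg) into those
statistical fingerprints, and then asks the applied question: *which driving
scenarios reproduce the anxiety fingerprint most strongly?*

The package is aimed at researchers in affective computing, ergonomics and
driver-state monitoring who work with paired (within-subject) calm/anxious
designs on a driving simulator or instrumented seat.

## The method

1. **Regional features.** Each frame pair is segmented into six regions —
   left/right buttock (BTL/BTR), left/right thigh (THL/THR), upper/lower
   back (UB/LB) — and reduced to 36 variables: per-region average contact
   pressure over non-zero cells (mmHg), contact area (non-zero cell count),
   centre of pressure COP in (row, col) grid units, and each region's share
   of the six-region pressure and area totals.
2. **Event windows.** Every analysed epoch is exactly 50 frames (10 s at
   5 Hz): `[anchor − 5 s, anchor + 5 s)` around instantaneous event marks,
   the first 10 s of continuous manoeuvres, and separate entry/exit windows
   for roundabouts. Windows are reduced to 108 statistics
   (Mean/Std/Max of each variable).
3. **Paired screening.** For each statistic, the paired difference
   `D_{j,i} = X^anx_{i,j} − X^calm_{i,j}` across subjects is gated by a
   Lilliefors normality test (α = 0.05, seeded Monte-Carlo null): normal →
   paired t-test with paired Cohen's d; otherwise Wilcoxon signed-rank
   (exact, tie-aware) with matched-pairs rank-biserial
   r = (W⁺ − W⁻)/(W⁺ + W⁻). Features pass at p < 0.005 and are ranked by
   |effect size|.
4. **Scenario similarity.** Per subject, Δ_static = F^anx − F^calm from the
   static anxiety-induction windows is the anxiety prototype (Eq. 1-style);
   Δ_scene,i = F^anx_scene,i − F^calm_scene,i is the dynamically
   baseline-corrected scenario difference — subtracting the calm drive of
   the *same* manoeuvre removes the pressure changes braking or steering
   cause by themselves. Scenarios are scored by
   `Sim_i = Δ_scene,i · Δ_static / (‖Δ_scene,i‖₂ ‖Δ_static‖₂)`,
   averaged over subjects and ranked. Cosine similarity compares direction
   only, so it is invariant to between-subject amplitude differences.

Because raw recordings of this kind are not publicly deposited, the package
includes a first-class synthetic study generator (`simulate_study()`) that
plants the anxiety pattern — regional gains, 0.51-unit anterior–posterior
sway, volatility, spikes — plus per-scenario task components and a graded
anxiety coupling κ, so the whole pipeline is validated by parameter
recovery. See `vignettes/seated-pressure-anxiety.Rmd` for the model, the
defaults and their rationale, and known limitations.

## Worked example

The `analysis/` scripts run the demo study end to end
(`01_simulate.R` → `02_screening.R` → `03_similarity.R`), writing session
directories and report tables under `results/`. In short form:

```r
library(pressanx)

study <- simulate_study(n_subjects = 18, seed = 20260919)
res   <- analyze_study(study)

head(res$screening[, c("feature", "region", "test_used", "p_value", "effect_size")])
res$similarity$scenario_summary
```

Output from this run:

```
73 of 108 statistical features separate anxiety from calm at p < 0.005
Top discriminating features:
       feature region test_used      p_value effect_size rank
     aTHL_Mean    THL  paired_t 3.592516e-21   14.024681    1
     aBTL_Mean    BTL  paired_t 2.738829e-20   12.437530    2
     aBTR_Mean    BTR  paired_t 6.835207e-20   11.782231    3

Scenario ranking by mean cosine similarity to the anxiety prototype:
            scenario mean_similarity sd_similarity  n rank
   congested_traffic       0.8884471    0.04969152 18    1
    roundabout_entry       0.8793476    0.05511405 18    2
   emergency_braking       0.8790341    0.05339113 18    3
         lane_change       0.8752648    0.04227086 18    4
 pedestrian_crossing       0.8606899    0.03466672 18    5
   consecutive_turns       0.8055520    0.06854345 18    6
     roundabout_exit       0.7986036    0.05956682 18    7
             parking       0.6566495    0.12926271 18    8

Spearman correlation between planted coupling and recovered ranking: 0.929
```

Reading it: the screen finds the planted lower-body pressure/area effects
(huge paired d because the effect is consistent across subjects), and the
scenario ranking tracks the planted anxiety couplings (roundabout entry
0.90 … parking 0.15) — high-uncertainty, high-interaction scenarios score
closest to the static anxiety pattern, predictable manoeuvres score lowest,
with parking also the most variable across subjects.

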