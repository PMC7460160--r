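---
title: "Heart-rate-driven difficulty adaptation: model, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-driven difficulty adaptation: model, simulator and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hradapt)
```

## The adaptation model

`hradapt` implements closed-loop dynamic difficulty adjustment for
exergames played by children aged 5–7. A wearable samples heart rate at
1 Hz; the engine maintains a rolling window of the last 20 readings, from
which two statistics drive every decision:

- `w`, the mean of the last 20 readings after min–max scaling onto
  [0, 1] — a smooth, unitless measure of recent exertion used to size
  multiplicative difficulty updates;
- `avgHR`, the mean of the raw (calibrated) readings over the same
  window, compared against a 95 bpm exertion boundary.

The 95 bpm boundary is deliberately below the adult-style 50–70% of
maximal HR band (which for age 6, with maximal HR `220 − age`, would be
roughly 104–150 bpm): young children rarely sustain those levels in mat
play, so the rules act on a lower threshold. An upper boundary of 105 bpm
exists in the threshold set but is not used by the default update rules;
an optional hysteresis mode hardens difficulty only below 95 and eases
only above 105, holding steady in between. Ties at the boundary take the
high-exertion (easing) branch, since the published branches use strict
inequalities on both sides and easing is the safer default for this
population.

Each game scenario has its own controller, a pure function from
`(state, inputs, avgHR, w)` to the next state:

**Scenario 1 (flying character).** While `avgHR < 95` the travelled
distance `d` advances one unit per tick; when the goal distance `deltaD`
is spanned, `d` resets and the goal and horizontal speed `vh` rescale by
the weight: `deltaD ← deltaD + deltaD·w` followed — in that order — by the
speed update with the updated `deltaD`. At or above the boundary both
shrink (`deltaD ← deltaD − deltaD·w`, `vh ← vh − vh·w`). `deltaD` and `vh`
are clamped to configurable positive ranges (defaults [1, 10000] and
[1, 100]) since nothing else bounds a multiplicative update.

**Scenario 2 (bathtub countdown).** The adapted quantity is the *allotted*
round time, initially 10 s and confined to [5, 15] s; the running timer is
separate per-round state. A press with time remaining scores +1 and
tightens the budget by 1 s under low HR (floor 5 s) or relaxes it
otherwise; a timeout scores −1 and always relaxes it (ceiling 15 s). A new
round then starts with the adapted budget.

**Scenario 3 (falling blocks).** Blocks spawn at a generation rate,
initially 0.366 blocks/s, adapted ±0.1 per correctly pressed block and
clamped globally to [0.1, 5 × 0.366 = 1.83]; unpressed blocks cost a point
and leave the rate alone.

**Test scenario.** The architecture check: speed steps ±1 every 20 s
according to whether the *last* reading is below 80 bpm.

The conventional (CIS) arm runs the identical controllers with adaptation
disabled: rounds, timers and scoring behave the same, difficulty stays at
its initial values.

### Design choices where the source rules were ambiguous

Several aspects of the published update rules are internally inconsistent
or silent, and this package fixes each with an explicit, configurable
choice:

- *Scenario-1 speed sign.* The prose describes the speed as incremented on
  goal completion under low HR; the printed pseudocode subtracts. The
  default `mode = "intent"` follows the prose (adaptation must harden the
  game under low exertion for the loop to make sense); `mode = "literal"`
  reproduces the printed sign exactly and is kept as a first-class
  regression surface. The boundary case `d = deltaD`, unhandled in print,
  folds into the goal-completion branch.
- *Scenario-2 direction.* The printed success branch decrements the
  countdown with a floor of 5 while the prose says "increments by 1 (lower
  limit of 5)"; only the pseudocode is self-consistent with the stated
  limits, so it is followed. The countdown is split into the persistent
  allotted time and a per-round timer because the printed timeout branch
  (+1 from zero) is only coherent if the adapted quantity is the budget,
  not the running clock.
- *Scenario-3 units.* An "initial frequency of 0.366 s" conflicts with
  "+0.1 means more frequent". The default reads the variable as a rate in
  blocks/s with a global clamp — the only reading consistent with both
  printed bounds; `interpretation = "period"` flips the signs and applies
  the same bounds to the spawn interval instead.
- *Scaling and windows.* Neither the bpm-to-[0, 1] map nor the `avgHR`
  window is specified. Scaling is linear min–max over a configurable
  [60, 200] bpm with clamping (spans the child resting-to-maximal band and
  guarantees the unit codomain); `avgHR` shares the 20-sample window with
  `w`, keeping one state object and a reactive controller at 1 Hz.
- *Outliers and warm-up.* "Outliers were suppressed" becomes hard
  physiological bounds [40, 220] bpm — simple and auditable. Controllers
  hold off until the window carries at least 5 samples (configurable),
  avoiding spurious first-tick jumps.
- *Score floors.* Whether points can go negative is unstated; they can.

## The synthetic physiology and what it does (not) show

No public dataset accompanies the study design, so the package closes the
loop with a deliberately minimal surrogate. Each synthetic participant has
age 5–7, resting HR drawn uniformly from 70–90 bpm, maximal HR `220 − age`,
and a first-order exertion response: HR relaxes toward
`resting + demand · effort_gain · (hr_max − resting)` with time constant
`tau = 30` s and additive Gaussian noise (`noise_sd = 2` bpm per sample,
scaled by `sqrt(dt)`), clamped to [40, hr_max]. *Demand* normalises each
controller's difficulty variable over its own clamp range, so it lies in
[0, 1] by construction. `effort_gain = 0.35` — the fraction of heart-rate
reserve recruited at maximal game demand — was chosen once so that
steady-state HR in moderate play falls in the 85–105 bpm band typical of
this age group in mat-based exergames. Press success falls linearly from
0.95 at minimal difficulty to 0.45 at maximal, and an optional
`distraction` parameter randomly abandons attempts to emulate field-test
adherence problems (off by default).

Calorie expenditure is a linear-in-HR-reserve surrogate,
`max(0, c0 + c1·(hr − resting)) · dt` with `c0 = 0.01` kcal/s and
`c1 = 0.0012` kcal/s/bpm: the wearable's proprietary algorithm is
unpublished, and these constants simply put a ~200 s scenario segment at
moderate HR in the single-digit-to-low-teens kcal range reported for
comparable sessions. Per-scenario kcal resets at each `activityStarted`,
matching how cumulative per-scenario counts are reported.

Sessions follow the crossover protocol: 10 min play per arm at 1 Hz,
10 min rest between arms (each session therefore starts at resting HR),
equal thirds of play time per scenario (the protocol states no split).
Both arms share a participant's physiology with independent noise
streams, mirroring the within-subject design; everything is deterministic
given the participant seed, which `simulate_cohort()` derives from a
master seed.

What passing closed-loop tests show: the adaptation rules, driven through
this surrogate, regulate late-session `avgHR` toward the 95 bpm target
better than frozen difficulty does, and the full pipeline (signal →
engine → logs → statistics) is internally consistent and bit-for-bit
replayable. What they do not show: anything about real cardiovascular
dynamics, real child behaviour, device artefacts beyond a constant offset,
or the field conditions (device swapping, distraction, coaching) that the
surrogate only caricatures. A real deployment would re-estimate `tau`,
`effort_gain` and the skill curve from pilot data.

One quirk of the closed loop is worth knowing: because adaptation
*regulates toward* 95 bpm rather than maximising exertion, a fixed
difficulty that happens to sit above the target (scenario 2's initial
budget is fairly demanding) can elicit *higher* mean HR in the CIS arm
than in the UAS arm. The adaptive arm's advantage is proximity to the
target band, which is what the closed-loop acceptance property measures.

## The evaluation pipeline

`build_variables()` reduces each participant × scenario × arm to the mean
calibrated HR over the scenario segment and the final cumulative kcal,
under the study's naming convention (`HrateP2UAS`, `Gcalorico3CIS`, …);
participants missing an arm or failing log validation are excluded with a
recorded reason. How the per-participant scenario summary was formed
before testing is not stated in the source; the mean is assumed.

`describe()` reports n, mean, SD, variance, bias-corrected skewness and
excess kurtosis, the kurtosis SE and the interval (range). The
skewness/kurtosis conventions are the sample-adjusted estimators of
mainstream statistics packages — the choice is pinned down by the fact
that the published kurtosis SE at n = 29 (0.85) matches the classical
closed form `2·se_skew·sqrt((n² − 1)/((n − 3)(n + 5)))`. Statistics whose
sample-size requirement is unmet are `NA`, never fabricated.

The paired t-test is implemented once, on summary statistics
(`paired_t_from_summary()`); the raw route forms the differences and
delegates, so the two routes agree exactly by construction (and the raw
route is checked against `stats::t.test` in the test suite, which serves
as the independent oracle rather than the implementation). The summary
route exists because the published inferential tables are fully determined
by their first three columns (mean difference, SD, n) — every printed row
reproduces its t and 95% CI bounds to within ±0.02, the slack absorbing
the source's own rounding of the inputs. Zero-variance differences yield
an infinite t and are flagged, not hidden. No multiple-testing correction
is applied (none was in the source analysis); the rendered report says so
in its footer.

## Numerical and reproducibility choices

- Session logs serialise doubles at `%.17g`, so write → read round-trips
  are lossless and replay comparisons can demand bit-for-bit equality.
- Each log row embeds the tick's inputs (press flag, block outcomes) in
  its state snapshot, which is what makes a log replayable without the
  RNG: `replay_session()` reconstructs the window statistics and the
  controller trace and reports the first divergent tick. Replaying an
  intent-mode log under `mode = "literal"` diverges at the first
  scenario-1 goal-completion tick, and frozen-difficulty logs replay
  identically under either mode.
- The problem sizes used by the test suite were chosen to probe each
  property at the smallest scale that exercises it: exhaustive
  enumeration of all scenario-2 transitions plus 10⁵-step random fuzzing
  for the clamp invariants, 20 seeded participant pairs for the
  closed-loop regulation property, and 20 replicate cohorts of 8
  participants for interval coverage of a known built-in arm effect. The
  arm effect in that experiment is injected as a measurement-level offset
  on one arm with adaptation disabled in both, so the true paired mean
  difference is exactly the injected value; injecting it upstream of the
  controllers would leave the ground truth undefined.

## Known limitations

- The exertion surrogate is first-order and memoryless: no HR drift,
  fatigue, recovery asymmetry or circadian structure.
- The inter-device offset is a single constant; real calibration drifts
  and varies per subject.
- Scenario-1 adaptation is slow under the default goal distance
  (`deltaD = 100` ticks per cycle), so its difficulty moves far less than
  scenarios 2–3 within a 200 s segment — visible in the simulated
  variables as a smaller UAS–CIS contrast for scenario 1.
- The period interpretation of scenario 3 is provided for completeness
  but shares the rate interpretation's clamp constants rather than
  deriving interval-specific ones.
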