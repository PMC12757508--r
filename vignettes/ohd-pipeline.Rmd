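---
title: "Scoring and modelling automated olfactory habituation/dishabituation sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling automated olfactory habituation/dishabituation sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohdtools)
```

## The task and the apparatus this package models

In the olfactory habituation/dishabituation (OHD) task a rodent receives
repeated presentations of each odor in a fixed panel. Investigation of a
repeated odor declines across presentations (habituation) and rebounds when a
novel odor is introduced (dishabituation), making the task a compact probe of
olfactory perception, memory and motivation. `ohdtools` implements the data
side of an automated, olfactometer-driven variant of this task: the subject
sits in a 6-inch acrylic tube; odorized or clean air enters at the *primary*
end through one of five solenoid valves (a normally-open clean-air valve plus
four odorant valves), while positive pressure from the *secondary* end keeps
odorized air localized near the primary end. Total-VOC (tVOC) sensors at both
inlets log odorant levels, and an overhead tracker reports the animal's
centroid in pixels.

The package covers five stages, each usable on its own:

1. **Scheduling** (`paradigm_config()`, `build_ohd_schedule()`,
   `schedule_to_valve_events()`, `validate_valve_events()`,
   `trial_windows()`): a session is a contiguous sequence of trials, one per
   (stimulus, presentation) pair, each trial a 60 s valve-ON period followed
   by a 60 s clean-air flush. The default panel is clean air (CLN), two
   nonsocial odorants (NSA, NSB) and a same-sex urine odor (SOC), three
   presentations each: 12 trials, 24 min. The apparatus routes air through
   exactly one valve at any instant; `validate_valve_events()` checks a log
   against that exclusivity invariant.
2. **Telemetry and tracking I/O** (`read_telemetry()`, `read_tracking()`,
   `per_second_voc()`, `per_trial_voc()`, `screen_bottle()`).
3. **Automatic scoring** (`zone_rule()`, `detect_bouts()`, `score_trials()`,
   `import_manual_bouts()`).
4. **Effect statistics** (`habituation_diffs()`, `dishabituation_diffs()`,
   `bootstrap_ci()`, `paired_permutation_test()`, `holm_adjust()`,
   `ohd_effects()`, `export_long_table()`).
5. **Synthetic sessions** (`voc_params()`, `agent_params()`,
   `generate_session()`, `simulate_cohort_scores()`), so that every stage is
   testable end to end without any recorded data.

## The investigation-scoring rule

Automatic scoring works on the tracked centroid ("center of mass") and a
pixel calibration. With the usual calibration of 0.458 mm/pixel, the zone
boundaries at 2 cm and 6 cm from the primary end correspond to 44 and
132 pixels (`cm_to_px()` uses the ceiling rule — the smallest pixel count
covering the requested distance — which reproduces both thresholds).

A frame counts as *investigating* when:

* the centroid's distance from the primary end lies in the 2–6 cm zone, and
* the animal is moving toward the primary end, or was last moving toward it
  (stationary frames inherit the most recent non-stationary direction; a
  stationary run at the start of a trace has no direction and never counts).

Frames closer than 2 cm never count: a body within 2 cm of the end wall is
taken to be turning away from the stimulus. Maximal runs of investigating
frames become bouts; bout durations are frame counts divided by the average
frame rate. Per-trial investigation is the summed intersection of bouts with
the trial windows, splitting bouts that straddle a boundary.

Direction estimation needs two parameters the scoring rule itself does not
fix: the displacement window and the dead band. The defaults are a centred
window of ~0.25 s of frames (8 frames at 30 fps) and a 2 mm dead band —
roughly the scale of centroid jitter from posture change in a tube this
size — below which a frame is *stationary*. Both are configurable in
`zone_rule()`; the bout detector's invariants (toward-only, inner-zone
exclusion, monotonicity in the outer boundary) hold for any setting.

A deliberate consequence of the "inherit the last direction" formalization:
a bout ends on the first *away* frame or on leaving the zone, not after a
fixed grace period. The rule is therefore entirely local and reproducible
from the trace alone.

### Trial windows

Investigation is tallied over the full trial window, valve onset to the next
trial's onset (ON + OFF, 120 s), matching the 2-minute stimulus presentation
the paradigm emulates; `trial_windows()` windows can also be restricted to
the ON period by passing windows built from `t_on_end_s`. Clean-stimulus
trials produce no valve transitions (the clean valve simply stays open), so
their windows are generated from the schedule rather than the log.

## Effect estimates and uncertainty

The behavioral contrasts use only the first and third (final) presentation
of each stimulus:

* **Habituation** (per stimulus): `duration(presentation 3) −
  duration(presentation 1)` per subject; negative values indicate
  habituation.
* **Dishabituation** (per adjacent stimulus pair): `duration(next stimulus,
  presentation 1) − duration(previous stimulus, presentation 3)`; positive
  values indicate dishabituation.

The point estimate is the mean of the per-subject differences, with a
percentile bootstrap CI (resampling subjects with replacement; 2.5th/97.5th
percentiles of the bootstrap means at the 95% level). The bootstrap-
distribution median is reported alongside the mean, since either can serve
as the plotted point. The percentile method was chosen as the simplest
bootstrap CI; its known cost is mild undercoverage at small cohort sizes
(true coverage ≈93% rather than 95% at n = 24 for Normal data — the suite
verifies nominal calibration at n = 100). BCa or t-bootstrap intervals would
tighten this but add machinery the contrasts do not need.

Significance uses a sign-flip permutation test on the per-subject
differences (exact enumeration of all `2^n` sign assignments when that is no
more work than the requested Monte-Carlo size; otherwise random flips with
the add-one estimator `p = (1 + #extreme)/(1 + n_perm)`), with Holm
step-down adjustment across all reported effects. Mixed-effects modelling of
the full stimulus-by-presentation design is deliberately delegated:
`export_long_table()` writes the model-ready long-format table (presentation
1 and 3 by default) for lme4 or any external tool.

## The synthetic session generator

The generator exists so that the scorer and the statistics can be validated
end to end with known ground truth. It emulates the study conditions, not
any particular recorded session.

**VOC channel.** The primary-inlet concentration follows first-order
kinetics: during valve ON it relaxes toward the stimulus plateau with
`tau_rise_s` (default 10 s), during OFF back toward baseline with
`tau_decay_s` (default 20 s), implemented continuously from the segment's
starting concentration. Odorant plateaus default to 11,500 ppb — the middle
of the 10,000–13,000 ppb band odorants are diluted to — on a 50 ppb
baseline; readings are rounded, floored at 0 and capped at 29,000 ppb
(sensor saturation) inside the raw 0–32,768 ppb range, sampled every 260 ms
with 5 ppb Gaussian read noise. The secondary sensor stays at baseline.

**Behavioral channel.** The centroid's axial position follows a
discrete-time mean-reverting walk,
`x[k+1] = x[k] + θ(μ[k] − x[k])Δt + σ√Δt ξ[k]`, reflected into the 152.4 mm
tube, at 30 fps. Once per second the target `μ` is drawn: the attraction
point (30 mm, inside the zone) with probability
`min(1, attract_scale · salience_s · r^(p−1))` during a trial of stimulus
`s` at presentation `p`, otherwise the rest point (90 mm, outside the zone).
Defaults: salience 0.05 : 1 : 1 : 2.5 for CLN : NSA : NSB : SOC,
habituation ratio `r = 0.6`, `θ = 2 /s`, `σ = 25 mm/√s` (stationary SD
≈12.5 mm, so the agent meanders realistically around its target),
`attract_scale = 0.3`. The scale keeps the attraction probability literally
proportional to salience for all default weights (maximum 0.75): letting the
probability saturate at 1 would flatten the social stimulus' contrast
between its first presentations, distorting the very habituation structure
the generator exists to encode. With these defaults a 24-subject cohort
reproduces the canonical OHD pattern — negative habituation effects with CIs
excluding 0 for every odor stimulus, a clean-air effect an order of
magnitude smaller, and strong positive dishabituation into the social
stimulus.

Ground-truth bouts are obtained by applying the same zone-and-direction rule
to the exact simulated positions before pixel export (3-decimal sub-pixel
coordinates, as commercial trackers emit, plus small lateral jitter).
Re-scoring the exported CSV therefore validates the full read → calibrate →
score path against truth; independence from the implementation is provided
separately by brute-force per-frame oracles in the test suite. Component
seeds derive from one master seed by fixed offsets, so fixtures are
byte-reproducible.

**What the generator does not emulate.** Real sessions contain rearing,
grooming and posture changes that move the centroid without locomotion,
tracker dropouts, lens distortion, airflow-dependent odor plumes, and
sensor warm-up drift. Passing tests on synthetic data therefore demonstrate
that the scoring rule and statistics are implemented correctly and recover
known structure — not that the rule is optimal for any particular video
setup. Absolute investigation durations from the generator are
configuration-driven, not calibrated to any recorded dataset.

## Numerical choices and degenerate inputs

* Per-second VOC buckets are left-closed `[k, k+1)`; empty buckets are
  reported missing, never interpolated.
* Bottle screening (`screen_bottle()`) passes when the median reading lies
  in the inclusive 30–70 ppb band.
* `cm_to_px()` uses the ceiling rule; distances themselves are computed and
  compared in mm, pixels being a convenience view.
* Bout `end_s` is the start time of the frame after the last investigating
  frame, so durations equal frame counts over fps on gap-free traces.
* Valve transitions are instantaneous (no actuation latency); the clean
  valve is treated as open before the first logged event, matching its
  normally-open hardware state.
* Empty inputs: header-only telemetry reads as zero records; an empty event
  log yields zero windows; an empty score table exports a header-only CSV.
  Degenerate bootstrap input (all differences equal) collapses to a
  zero-width CI; all-zero differences give permutation p = 1.
* Problem sizes in the shipped suite were chosen to exercise every property
  at desk scale: 1,000 random traces for the oracle-equivalence check, 20
  full sessions for end-to-end recovery, 1,000 replicate cohorts for
  bootstrap coverage, cohorts of 24 subjects for the pattern-level checks.

## Known limitations

* The scorer uses the centroid only; a snout-distance criterion (as used in
  manual scoring, along with grooming exclusion) is supported only through
  imported manual annotations (`import_manual_bouts()`).
* Percentile bootstrap CIs undercover slightly at small n (above).
* The direction-estimation window and dead band are conventions; no claim
  is made that they match any particular tracker's internal smoothing.
* Statistics here are the bespoke paired contrasts; omnibus mixed-model
  inference is exported, not fitted.
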