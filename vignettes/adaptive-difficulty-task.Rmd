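---
title: "Modelling an adaptive visual search task and its neglect metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an adaptive visual search task and its neglect metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdsearch)
```

## The task and its difficulty controller

The simulated task presents one target at a time inside a wide angular
spawn area (±60° azimuth, ±50° elevation around the midsagittal plane;
10° wider horizontally than a 110° head-mounted-display field of view, so
players must turn their head to cover it). A target must be found and
tagged before its lifetime expires; 2 s after a target resolves (tagged
or expired) the next one appears. Play proceeds in rounds — by default 10
rounds of 30 targets.

Difficulty is organised in 15 levels. Level 1 presents slow, long-lived
targets (2 °/s, 15 s); each level adds fixed increments (−0.786 s
lifetime, +2.36 °/s speed, +1.42 percentage points to both performance
thresholds), ending near 35 °/s and 4 s at level 15. After every round
the percent of found targets is compared with the current level's
thresholds: strictly above the level-up threshold promotes, strictly
below the level-down threshold demotes, anything in between — including
ties — holds the level, and the result is clamped to [1, 15].

Two numerical conventions deserve a note:

* **Delta-based generation.** Level parameters are computed as the
  level-1 value plus (level − 1) increments, not by interpolating toward
  the level-15 endpoints. The two differ only by display rounding at the
  top of the table (e.g. 35.04 °/s vs a printed 35), and the delta form
  reproduces the published level-6 worked example exactly
  (13.8 °/s, 11.07 s, 77.1%, 67.1%).
* **Unrounded comparisons.** Percentages are compared as floating-point
  values; rounding is applied only for display. This avoids boundary
  artifacts for outcomes such as 25/30 = 83.33…%.

```{r}
tab <- default_table()
level_params(tab, 6)
next_level(tab, 6, percent_found(25, 30))
next_level(tab, 6, percent_found(15, 30))
```

Because promotion requires strictly exceeding a threshold, a player whose
hit rate sits inside the band between thresholds stays put: the *balance
point* of the staircase.

## The synthetic agent model

Human play is emulated by an agent with a deliberately small closed-form
response model. For a target at azimuth $a$ (degrees), the time to find
and tag it is

$$ t \;=\; \bigl(L + |a|/v + A\bigr)\;\cdot\;\bigl(1 + g\lambda\,[a<0]\bigr)\;\cdot\;\varepsilon, $$

with base latency $L$ (s; includes the 1 s alerting cue and search
onset), angular scan speed $v$ (°/s), aim/tagging time $A$ (s), lateral
bias $\lambda \in [0,1]$ with gain $g$ applied to left-hemispace targets
only, and multiplicative lognormal noise $\varepsilon$ with median 1 and
log-sd $\sigma$. The target is found iff $t$ does not exceed its
lifetime; misses carry no search time, exactly as in the task's logging.
Choosing median-1 noise means the no-noise closed form is the median
behaviour, which keeps the deterministic unit tests exact.

Modelling choices, and what they deliberately leave out:

* **Azimuth-dominant search.** Elevation is recorded but does not enter
  the search time; horizontal eccentricity dominates the head-turning
  cost in a task whose spawn area is much wider than tall.
* **Speed acts through lifetime only.** Target motion is not given an
  extra detectability cost; the difficulty effect of faster levels is
  carried by their shorter lifetimes. The spawn azimuth is the azimuth
  used in the model.
* **Recentring between trials.** Each trial starts from a neutral
  heading — the alerting cue reorients the player. Gaze carry-over
  between trials is a possible extension, not modelled here.
* **Event-based time.** There is no frame loop; spawn times follow
  resolution times plus the 2 s inter-stimulus interval.

The hemispace penalty $1 + g\lambda$ is the package's operationalisation
of left hemispatial neglect: contralesional (left) search is slowed
multiplicatively, right-hemispace behaviour is untouched. With
$\lambda = 0$ the model is exactly symmetric, which the test suite
verifies both in closed form and statistically (left/right means within
3 SE over >2000 simulated targets).

## Cohort presets

`generate_cohort()` draws per-participant agents from uniform ranges.
The presets emulate the three study populations:

| cohort | n | L (s) | v (°/s) | A (s) | σ | λ | start |
|---|---|---|---|---|---|---|---|
| young | 21 | 0.35–0.5 | 35–45 | 0.3–0.4 | 0.3 | 0 | 8 |
| elderly | 23 | 0.35–0.55 | 25–35 | 0.2–0.3 | 0.6 | 0 | 5 |
| neglect | 11 | 0.6–1.0 | 6–10 | 0.4–0.6 | 0.4 | 0.1–0.9 | 2 |

Young and elderly parameters were calibrated so the median per-target
search time falls near 1.5 s and 1.7 s respectively — the order of the
group means reported for healthy players of such tasks — with the
elderly slower-scanning and more variable. The young starting level is 8,
so at most 7 promotions are possible; a high-skill cohort therefore shows
a ceiling trajectory. The neglect preset uses the patient task variant:
fewer targets per round (8 × 10 rounds ≈ the 80-target sessions typical
of patients), a starting level of 2, and the minimum target speed lowered
to 0.1 °/s. The speed floor is implemented as a level-1 speed override
with the usual per-level increment on top, which is the smallest change
consistent with "the minimal speed was lowered".

Per-participant RNG substreams are derived from the master seed, so any
single session can be reproduced in isolation and whole runs serialize
byte-identically (fixed 6-decimal timestamps, 17-significant-digit
floats).

## The Center of Cancellation

On a cancellation sheet, each target's horizontal position is mapped to a
normalized coordinate: sheet centre → 0, leftmost target column → −1,
rightmost → +1, linear (piecewise about the centre, so asymmetric sheets
still span [−1, 1]). The CoC is the mean normalized coordinate over the
*marked* targets; 0 means no lateral bias, and values ≥ 0.081 (boundary
inclusive) are classified as significant left-sided neglect. The exact
weighting used by published CoC software is not claimed — only the range
and cutoff constrain this implementation — and the raw millimetre mean
deviation is reported alongside. An empty mark set raises an error
rather than returning 0, because 0 means "no bias", not "no data".

The default synthetic sheet (so labelled: it stands in for a published
sheet whose geometry is not public) carries 40 targets on a symmetric
8-column × 5-row grid interleaved among 240 distractors on a 24 × 10
grid of a landscape A4 sheet.

Simulated cancellation links the simulator's bias to sheet behaviour:
a target at normalized coordinate $\tilde x$ is marked with probability
$1 - \lambda(1-\tilde x)/2$ (clamped to [0, 1]), so omissions grow
toward the left edge and with severity; the rightmost target is forced
if every draw fails, guaranteeing a non-empty mark set.

## The severity-recovery experiment

`severity_recovery()` asks the package's central validity question: does
the in-game left-hemispace search time recover the severity measured on
the cancellation sheet? Twenty patients are simulated who differ *only*
in $\lambda \sim U(0.1, 0.9)$ — the standard parameter-recovery design,
holding nuisance abilities fixed (base latency 0.8 s, scan 15 °/s, aim
0.5 s, σ = 0.4) so the construct of interest is the dominant source of
between-patient variance. Each patient plays a short low-difficulty
assessment block (starting level 1, 3 rounds × 50 targets = 150 targets,
a session length patients of the target population realistically
complete) and performs one simulated cancellation test.

The assessment-block design is deliberate. Two mechanisms otherwise cap
the attainable correlation well below what severity alone would predict:

1. **Balance-point censoring.** The adaptive controller drives every
   player toward ~25% misses, so at the plateau the target lifetime
   censors exactly the slowest searches. Found-only left means then
   mostly reflect the (quantized) plateau level rather than $\lambda$ —
   even a noise-free simulation caps near $r \approx 0.8$ under adaptive
   play.
2. **CoC measurement noise.** With 40 Bernoulli marks, the CoC of a
   single sheet has conditional sd ≈ 0.06 against a signal range of
   ≈ 0.02–0.36, bounding any correlation *through* the CoC at ≈ 0.85.

Starting at level 1 keeps even the severe end ($\lambda = 0.9$, penalty
2.8 on a ~5 s deterministic search) below the 15 s lifetime, so
censoring barely binds; the residual scatter of the recovered
correlation is then dominated by the irreducible sheet noise. Across
seeds the left-hemispace correlation concentrates around 0.77 and
exceeds the right-hemispace correlation in every replicate — the
hemispace-specific pattern expected of left neglect — but individual
seeds can fall below 0.7: that is sheet noise, not a property of the
search model.

## Analysis layer

* **Level-difference trajectories** subtract each session's starting
  level, then pool per round across sessions; sessions with fewer rounds
  simply stop contributing (ragged pooling), and the SE is sd/√n over
  the sessions present in that round (0 when only one contributes).
* **Plateau detection** returns the earliest round whose level holds
  unchanged into the next round and from which the remaining levels span
  at most `tolerance` (default 1), over a terminal window of at least 3
  rounds; the plateau level is the rounded window mean. Requiring the
  level to *hold* at entry matches the balance-point notion — the round
  from which the level "did not change anymore" — rather than tagging
  the last climbing round that happens to sit inside the terminal band.
  A consequence: a strict 2-level oscillation with no repeated
  consecutive level reports no plateau. The statistic is invariant to
  adding a constant to all levels.
* **Hand-trace summaries** reduce the controller trace to lateral
  statistics; the shift index is the mean x divided by the 1 m workspace
  half-width, positive for the rightward compression typical of left
  neglect.
* **Questionnaire scoring** returns item means for SUS (1–5) and SSQ
  (1–4) and per-item scores for IPQ (1–5) and PGTQ (1–7), whose items
  probe distinct constructs and are not averaged.
* **Group statistics** use Welch's unequal-variance t test and Pearson
  correlations with two-sided p values. p values are reported, never
  used as automated pass/fail gates, and no multiple-testing correction
  is applied.

## Problem sizes and determinism

The package's own experiments are desk-scale by design: cohorts of
10–25 sessions, sessions of 80–2000 targets, Monte-Carlo loops of
200–10⁴ replicates. All randomness flows from explicit seeds through R's
default generator; `run_simulation()` derives one substream per cohort
and per session, records the master seed, package version, and a config
hash in every output artifact, and produces byte-identical logs on
repeated runs.

## Known limitations

* The agent model is a stand-in, not a cognitive theory: no learning
  across rounds (real players improve with practice, which the level
  trajectories of human groups show as a late slow drift), no gaze
  carry-over, no tagging errors on visible targets (aim error is folded
  into aim time), and no elevation cost.
* With shallow found-rate curves (slow scanners at 30 targets/round) the
  level trajectory behaves as a bounded random walk around the balance
  point and can wander more than 2 levels across 10 rounds; the tight
  plateau property holds for agents whose found-rate drops steeply
  across levels, as with the healthy presets.
* Agreement with published CoC software on real sheets is not claimed;
  only the normalized range and the 0.081 cutoff are matched.
* Passing the simulator's tests shows internal consistency with the
  stated response model, not fidelity to human visual search; real data
  carry practice effects, fatigue, strategy shifts, and heterogeneity
  the generator does not emulate.
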