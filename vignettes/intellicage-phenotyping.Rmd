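---
title: "Automated home-cage phenotyping: event model, task controllers, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated home-cage phenotyping: event model, task controllers, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`intellipheno` re-implements, as a tested and reusable package, the analysis
pipeline of an IntelliCage behavioral-phenotyping experiment comparing
3xTg-AD mice (a triple-transgenic Alzheimer's disease model) with
non-transgenic (NonTg) controls. The IntelliCage is a group-housing
apparatus with four conditioning corners; each corner registers RFID visits,
nosepokes at two nose ports, and licks at a waterspout, and controls water
access through per-animal door logic. Because no raw cohort data are
publicly deposited for this paradigm, the package pairs the analysis with a
stochastic mouse-agent simulator that produces complete, realistic event
logs with retained ground truth, so every metric and statistical routine
can be validated end to end.

The package has five layers:

1. **Event model** — a relational store of animals, visits, nosepokes,
   licks, the phase schedule, and corner assignments, with a plain-text
   tab-separated interchange format, full referential validation, and 24-h
   day slicing.
2. **Protocols** — each phase's controller as a deterministic rule or state
   machine: door policies, the serial-reaction-time (SRT) trial machine,
   the airpuff trigger, reward-corner assignment, and corner geometry.
3. **Simulator** — seeded stochastic agents that interact with those
   controllers over the full 29-day schedule.
4. **Metrics** — every per-animal per-day dependent variable, plus the
   adaptation pass/fail classifier.
5. **Statistics** — mixed repeated-measures ANOVA with Mauchly sphericity
   assessment, Bonferroni-gated post hocs, and pooled two-sample t tests.

# The 29-day battery

The default schedule (`default_schedule()`) runs, in order: free adaptation
(3 days, doors always open), door adaptation (3 days, doors open on any
visit), nosepoke adaptation (3 days, doors open on a nosepoke), place
preference (6 days, water only in one assigned corner), reversal (6 days,
water only in the diagonally opposite corner), SRT (3 days), place
avoidance (1 day, airpuff on nosepoking the assigned corner, all doors
closed), one off-cage delay day, and retention (3 days, water at all
corners). Source descriptions of the paradigm are internally inconsistent
about the SRT duration (three days in the protocol text, six in a figure
legend); only three days is consistent with the 29-day total, so three is
the default here. All phase durations are configurable through the
schedule table.

Time is measured in seconds from a session epoch that coincides with
lights-on (06:00); lights are on for the first 14 h of each session day.
Day windows are half-open intervals `[t0 + (k-1)·86400, t0 + k·86400)`
anchored at each *phase's* start rather than at midnight, because the
program switches phases at arbitrary clock times and the analysis slices
"testing days", not calendar days. A visit — and all of its nosepokes and
licks — is attributed to the day containing its start time; single
attribution keeps per-day counts summing exactly to whole-phase counts even
when a visit straddles a boundary.

# The SRT trial machine

Within an assigned-corner visit, the first nosepoke initiates a trial. A
2-s pre-cue delay precedes a 7-s LED cue. A nosepoke strictly inside the
delay is **premature** (impulsivity); a nosepoke between cue onset and cue
offset is **correct**, with reaction time measured from cue onset; if the
cue expires without a response the trial is **incorrect**. After any
terminal outcome the machine locks until the animal exits the corner;
further pokes while locked are outside-trial events. Boundary convention:
pokes exactly at cue onset or cue offset count as correct (reaction times
0 and 7 s).

One situation is not covered by the source protocol: the animal leaves the
corner while a trial is still pending. The package resolves such trials as
incorrect (a failure to respond to the cue), which preserves the invariant
that every initiated trial has exactly one outcome and
`initiated = correct + premature + incorrect`. The machine is verified
exhaustively against a brute-force classifier over all poke sequences of
length up to three on a 0.5-s grid.

## SRT metric denominators

The protocol's literal formulas put "% correct" and "% incorrect" both over
total visits, yet the two are reported with *identical* test statistics,
which is only possible if they are complements. The package therefore
normalizes the three outcome percentages over **initiated trials**, so they
partition 100% whenever any trial was initiated; `pct_initiated` stays
normalized over total visits (all corners). Both choices are deliberate,
documented, and testable; the per-trial records are exported so any other
normalization can be recomputed.

# Corner assignment

Reward corners for place preference are chosen from each animal's
adaptation visit habits: every animal gets one of its least-visited corners
(to cancel pre-existing corner bias), subject to at most four animals per
corner and a per-corner genotype imbalance of at most one (a full corner
holds two of each genotype). The algorithm processes animals in ascending
id order, preferring the least-visited corner with the lowest index, and
completes with a deterministic depth-first search when the greedy descent
dead-ends; the output is therefore a pure function of its inputs. When
unequal attrition makes a balance bound of one unattainable (e.g. six
survivors of one genotype and one of the other), the bound is relaxed by
the minimum amount that admits any assignment; corner capacity is never
relaxed. The reversal corner is the diagonal opposite (corners indexed
1–4 clockwise, so `c -> ((c+1) mod 4) + 1`, an involution); the SRT,
airpuff and retention reference corner is the reversal corner.

# Adaptation pass/fail

Any animal with zero licks across a full 24-h window is removed to a
standard cage for 7 h (dehydration safeguard) and reintroduced; zero licks
again in the following 24 h excludes it from the experiment. The classifier
walks each animal's lick stream in successive 24-h windows, shifting the
grid by the 7-h gap after a removal; a drinking window resets the removal
state, and a trailing partial window cannot trigger a removal. All
downstream metric tables include only animals that passed adaptation,
mirroring how the cohort analysis conditions on task completion.

# The simulator

Agents emulate the statistical structure the analysis assumes, not mouse
physiology:

* **Visits** arrive as a two-level (light/dark) Poisson process; a smooth
  circadian curve adds nothing for day-level metrics. Visit durations are
  log-normal around a 20-s median (real duration distributions are not
  reported for this paradigm; only ordering and containment matter here).
* **Corner choice**: with probability `w_explore` a visit is exploratory
  (uniform corner), otherwise water-seeking (highest-preference corner).
  Preferences are reinforced after each rewarded drink,
  `w_c <- w_c + alpha (1 - w_c)` with renormalization — a single-operator
  reinforcement rule that produces both the corner habits used for
  assignment and the learning curves in place preference/reversal.
* **Drinking** happens only when the phase controller opens a door; lick
  counts per bout are `1 + Poisson(licks_per_bout_mean - 1)`.
* **SRT**: per initiated trial, premature with `p_impulsive`, otherwise a
  response with `p_attend` at an exponential latency (`rt_scale` mean,
  truncated to the cue window), otherwise a timeout.
* **Avoidance**: each airpuff multiplies the agent's probability of
  returning to the airpuff corner by `(1 - avoid_learn)`.
* **Drink failure**: with probability `p_drink_fail` an agent never learns
  to use the waterspout; it emits visits but no licks and is excluded by
  the removal rule exactly as a real non-drinker would be.

All parameters, with units and defaults, live in one documented calibration
file (`inst/extdata/default_params.yaml`). The default genotype parameter
sets reproduce the qualitative effect directions of the reference cohort:
TG agents have a suppressed first (novel) day of exploration
(`day1_rate_mult` 0.6), a higher drink-motivated visit fraction
(`w_explore` 0.35 vs 0.60), a 0.15 lower cue-response probability
(`p_attend` 0.65 vs 0.80), weaker airpuff learning (`avoid_learn` 0.25 vs
0.50), and a higher drink-failure probability (0.43 vs 0.13, matching the
reference pass rates of 57.14% and 86.96%).

A single seeded generator stream drives the whole cohort, with animals
simulated in a fixed order, so equal configurations and seeds give
byte-identical stores. The simulator deliberately omits: social
interactions between cage mates, thirst/body-weight homeostasis, side
(left/right port) contingencies, and any within-genotype individual
parameter variability — between-animal variance in simulated metrics is
purely sampling noise, which makes power results on simulated data
optimistic relative to real cohorts. Passing tests therefore demonstrate
correctness of the pipeline's bookkeeping and statistics, not behavioral
realism.

# Statistics

The battery matches the classical analysis of such designs:

* `rm_anova()` — split-plot decomposition with one between-subjects factor
  (genotype, tested against subjects-within-groups) and one
  within-subjects factor (day; day and genotype×day tested against the
  subject×day residual). Group sizes may differ; the decomposition uses
  weighted (least-squares) day means and agrees with `stats::aov` `Error()`
  strata to numerical precision. Missing animal-days (`NA` from
  zero-denominator metrics) are removed by listwise deletion — classical
  RM-ANOVA needs complete cases; with the default cohort sizes this costs
  little and is reported as a limitation rather than silently imputed.
* `mauchly_test()` — Mauchly's W on the `d-1` orthonormal within-subject
  contrasts of the pooled within-group covariance, with the standard
  first-order chi-square approximation. Greenhouse–Geisser epsilon is
  computed and reported by `rm_anova()` but not applied by default (the
  reference analysis found no sphericity violations); `gg_correct = TRUE`
  applies it.
* `bonferroni_posthoc()` — per-day pooled t comparisons, run only after a
  significant interaction (the gating rule is enforced with an error), with
  `adjusted_p = min(1, p × d)`.
* `pooled_t_from_summary()` / `pooled_t_from_data()` — Student's
  equal-variance t from printed `mean ± SEM, n` summaries or raw samples;
  the two are exactly consistent, which lets published summary tables be
  re-tested without raw data.

Zero-denominator days yield `NA`, never 0 — a 0 would fabricate a
behavioral score for an animal that produced no denominator events.

# Numerical and format choices

* Timestamps are written with 17 significant digits so that
  `read_store(write_store(s))` reproduces `s` exactly; outputs are sorted
  (animals by id, events by time) and byte-stable across calls.
* Validation checks every structural invariant (unique ids, enum domains,
  interval containment, per-animal visit non-overlap, referential
  integrity, schedule contiguity) and reports the offending table and row.
* Interval conventions: day windows are half-open; an event exactly on a
  boundary belongs to the later day. Visit overlap tolerates exact
  touching (`t_end == next t_start`).
* The relational store is abstract; tab-separated text is the canonical
  interchange (an embedded database would add a binary dependency without
  changing any result).

# Validation problem sizes

The shipped test suite validates, among others: the SRT machine against a
brute-force enumerator over all ~2,600 poke sequences of length ≤ 3 on a
0.5-s grid in [0, 12] s; every phase metric against an independent
straight-line recount of the raw event rows on 100 seeded 16-animal,
29-day cohorts; the ANOVA F statistics against a direct cell-means
sums-of-squares oracle (1e-9) on 100 random designs plus a 2,000-replicate
null calibration of the between-factor type-I error; corner-assignment
constraints on 100 random feasible instances; and genotype-effect recovery
(pass-rate ordering and detection of the 0.15 `p_attend` difference on SRT
percent correct) across 50 seeded 12+12 cohorts. These sizes were chosen
to give stable Monte-Carlo estimates at interactive runtimes.

# Known limitations

* Reaction-time and visit-duration distributions are stand-ins; treat
  simulated latencies as placeholders.
* The removal/exclusion walk assumes lick timestamps are trustworthy; a
  lickometer outage would read as a non-drinker.
* `pct_initiated` can exceed definitions that require one poke per visit
  in corners outside the assigned one; it is normalized over total visits
  by design.
* The statistics layer covers the classical battery only; linear
  mixed-effects models, non-parametric alternatives and equivalence tests
  are out of scope.
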