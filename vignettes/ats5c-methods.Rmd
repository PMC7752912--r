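---
title: "Simulating automated 5CSRTT training: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating automated 5CSRTT training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ats5c)
```

`ats5c` simulates voluntary, home-cage automated training of mice on the
5-choice serial reaction time task and computes the task's standard
performance analytics. This vignette is the package's account of the
models it implements, the parameters that matter, and the choices made
where the protocol description leaves room.

## The trial state machine

A trial is a fixed sequence of phases. It opens with an inter-trial
interval (ITI) during which poking any port is prohibited; a poke here is
a *premature* response, terminates the trial (the cue is never shown) and
is the task's impulsivity readout. After the ITI one of the five ports is
illuminated for the stage's cue duration ("light on"), followed by a
*limited hold* during which a poke still counts. The first poke of the
trial is classified — the cued port gives a *correct* outcome, a water
reward and a reaction time (poke time minus cue onset); any other port is
*incorrect*; no poke by the end of the limited hold is an *omission*.
Every non-correct outcome appends a 5-s timeout with the house light off.
These four outcomes partition all completed trials, which the test suite
enforces on 10^5 randomized trials.

Two behaviours are not specified by the protocol text and are fixed here
as engine rules: only the first poke of a trial is classified (later pokes
are ignored — each trial ends in exactly one reward or one timeout), and a
wrong-port poke during the cue terminates the trial immediately rather
than leaving the window open for a late correction. A session that runs
out of clock mid-trial discards that trial; it appears in no log and no
metric.

Cue ports are pseudorandom in the balanced sense used by operant
controllers: consecutive blocks of five trials each contain every port
exactly once, shuffled. Photostimulation flags use the same construction
with the block size chosen as the smallest integer making the stimulated
fraction exact (pairs for 50 %), so realized fractions are exact on
complete blocks.

## The 12-stage ladder

`stage_table()` encodes the canonical difficulty ladder: cue durations
30, 20, 10, 5, 2.5, 1.25, 1, 0.9, 0.8, 0.7, 0.6, 0.5 s; rewards 6 µl at
stage 1, 5 µl at stage 2, 4 µl thereafter; the ITI fixed at 5 s for
stages 1–2 and randomized uniformly among 3, 4, 5 s from stage 3. Every
stage leaves at least 5 s to respond (the tightest window, stages 4–12,
is cue + limited hold = 5.5 s), which validation enforces as an
invariant.

Advancement criteria are evaluated after every completed trial, so a
mouse can switch stages mid-session. The printed criteria compress column
spans, and the mapping adopted here is: stage 2 requires ≥ 30 correct;
stage 3 ≥ 50 correct; stages 4–5 add strictly > 80 % accuracy; stages
6–12 add strictly < 20 % omissions. Comparisons use the printed strict
inequalities, and a percentage whose denominator is zero counts as not
met. Counters accumulate since the last advancement and carry across
sessions (the alternative — nightly resets — is not stated anywhere; the
carrying scheme is the simplest one consistent with mid-session
switching, and the criteria mapping itself is plain data in the stage
table, so alternative readings are one edit away). There is no demotion:
after a break, training resumes at the stored stage. The limited hold for
stages 6–12 and the ITI for stages 1–2 are not printed; both are fixed at
5 s here and are flagged as assumptions in the stage table's
documentation.

## Scheduling and voluntary entry

In automated (ATS) mode the gate opens every 2 h for a 15-min session —
12 voluntary opportunities per mouse per day. Two cages share one chamber
and alternate with a 1-h phase offset (configurable), which sidesteps the
question of how hardware would arbitrate simultaneous approaches; a
session always ends before the other cage's slot begins. The gate waits
120 s for an entry (configurable; the protocol does not state how long a
real gate waits) before logging a skip. Manual mode is a single daily
30-min session placed at 09:00, inside the 09:00–12:00 window used for
experimenter-run training, with free water either from a daily 2-h window
(standard) or as a top-up to 1.8 ml/day at 16:00 (controlled water
consumption). Free water at session start is 15 µl per port — the midpoint
of the printed 10–20 µl range — delivered every ATS session but only at
stage 1 in manual mode.

Days are bounded at midnight for aggregation and circadian hour equals
wall-clock hour, with lights on at 07:00. All clocks are plain seconds
from experiment start; this keeps CSV round-trips lossless and circadian
binning arithmetic trivial.

## The virtual mouse

The protocol trains real animals and offers no per-trial generative model
of behaviour, so the agent here is openly invented: its functional forms
are the simplest ones reproducing the qualitative phenomena a protocol
designer needs to exercise, and all of them sit behind a small interface
(`respond`, `entry_prob`) so alternative models plug in.

- **Circadian engagement.** Entry is Bernoulli with an hour-indexed
  probability. The default curve holds 0.9 through the night, declines
  linearly from 09:00 to a minimum of 0.52 in the 15:00 hour, and
  recovers to 0.94 by 23:00 — the two printed anchors of the activity
  profile this emulates (least-active hour 15:00–16:00 at 0.52; late-day
  maximum 0.94).
- **Premature pokes.** A constant hazard during the ITI
  (default 0.02 s⁻¹): the first event time is exponential, accepted if it
  falls inside the ITI, giving P(premature) = 1 − exp(−hazard × ITI),
  which the suite checks against Monte-Carlo frequencies.
- **Detection.** P(detect) = floor + (ceiling − floor) × skill ×
  d/(d + h) for cue duration d with half-point h = 0.5 s (floor 0.1,
  ceiling 0.98) — monotone in both duration and skill, so difficulty
  bites exactly when the ladder shortens the cue.
- **Learning.** Skill rises by `learning_rate` (default 0.001) per
  completed trial, capped at 1; 700 trials take a naive-ish agent from
  0.2 to 0.9. Learning is outcome-independent by default (a reward-gated
  variant is exposed), which makes learning curves a function of
  completed trials — the comparison the sliding-window analysis is built
  for.
- **Responses.** Detected cues are answered at the cued port with
  probability 1 − `wrong_port_prob` (default 0.1) after a lognormal
  reaction time (µ = −0.25, σ = 0.35 on the log scale, mean ≈ 0.83 s,
  matching the sub-second reaction times typical of well-trained
  automated-training mice), truncated to the response window so the
  trial-record invariants hold. Undetected cues are omitted with
  probability 0.4 or answered with a late random-port poke.
- **Perturbations.** Named parameter shifts with a session countdown:
  `scopolamine_like` raises the wrong-port probability (accuracy −25
  points on the detection pathway) and the premature hazard (+0.05 s⁻¹)
  — the qualitative signature of muscarinic blockade in this task;
  `stim_learning_delay` halves the learning rate;
  `post_break_lapse` is a mild transient accuracy/premature/omission
  shift for modelling post-break performance dips, which are therefore an
  optional scenario, not hard-coded engine behaviour. Perturbed values
  are clipped to their ranges and the baseline is restored at expiry
  (learned skill carries over).

What the agent does **not** model: satiety and motivation dynamics within
a session, port biases, win-stay/lose-shift sequential dependencies,
sleep structure beyond the hourly entry curve, or any neurobiology.
Passing tests therefore demonstrate that the *engine, scheduler and
analytics* behave correctly on behaviourally plausible input — not that
real mice will match the simulated trial counts or learning speed.

## Analytics

The performance formulas are the task's standard ones: accuracy =
correct/(correct + incorrect) × 100; premature % = premature/all trials ×
100; omission % = omitted/(correct + incorrect + omitted) × 100, i.e.
prematurely terminated trials never enter the omission denominator; the
reaction time is cue onset to correct poke. Zero-denominator metrics are
NA rather than 0, and `compute_metrics()` is tested against an
independent single-pass recount on randomized logs.

Daily summaries are the *unweighted* mean over the day's entered sessions
with at least one trial, following the stated convention for multi-session
days verbatim; a trial-weighted variant is an explicit option. Learning
curves use 50-trial windows with 50 % overlap over the first 700 trials:
window starts step by 25, and the last window is the final one fully
contained, giving 27 windows — the arithmetic answer. (Repeated-measures
degrees of freedom in the source analysis imply 28 windows; the
discrepancy is noted and the arithmetic definition implemented.) Activity
profiles pool opportunities and entries per mouse across days and then
average probabilities across mice, so mice observed for different
durations weigh equally; the pre-averaged per-mouse table is available
via `by_mouse = TRUE`.

## Determinism and numerics

One experiment-level seed drives everything. Each mouse derives a 31-bit
substream seed from a hash of (seed, mouse id) and is simulated end to
end under it, so adding or removing a mouse never perturbs the others'
streams, and identical configurations replay byte-identical logs — the
suite asserts file-level identity. Reaction-time truncation rejects and
redraws (the window is ≥ 5.5 s against a ≈ 0.8 s lognormal, so rejections
are vanishingly rare; a uniform fallback guards the pathological case).
Stage-table and experiment configurations round-trip through YAML with
15-significant-digit floats; the canonical table's values are short
decimals and round-trip exactly.

## Problem sizes in the test suite

The suite sizes its simulations to what the properties need: 10^5
randomized trials for the partition/water invariants, 30,000 draws for
ITI uniformity (±0.01 on thirds), 20,000 trials for the premature-hazard
closed form, five 5,000-trial replicates for the flat fixed-accuracy
learning curve (a single replicate's binomial error, ≈ 0.6 points, is
close to the 1.5-point band being checked, so the point estimate is
averaged), and a 400-day entry-only cohort (sessions too short to
complete a trial) for circadian-curve recovery at 3 binomial standard
errors per hour including the 15:00 minimum. The full suite runs in
about two minutes on one core.

## Known limitations

Gate mechanics are reduced to open/entry/skip/close events — no motion
sensing, tunnel transit times or hardware latencies. Session-start free
water and rewards are the only water accounting in ATS mode; body-weight
dynamics are out of scope. The scheduler's two-cage alternation is a
fixed phase offset rather than an arbitration model. The agent's
parameters are calibrated only to printed anchor values, not fitted to
animal data; conclusions about real training speed should come from the
hardware, not this simulator.
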