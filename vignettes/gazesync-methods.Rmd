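---
title: "Methods: simulated multi-participant eyetracking for economic games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated multi-participant eyetracking for economic games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesync)
```

## What the package models

gazesync re-creates, in software, the full apparatus of a simultaneous
multi-participant eyetracking experiment built around an iterated two-player
public goods game (PGG): a central server to which every client connects in a
star topology, one low-cost eyetracker per participant, unsupervised
simultaneous calibration, selective recording, and gaze-contingent
synchronization. Hardware trackers are replaced by a gaze simulator, and human
participants by ground-truth agents, so every stage of the pipeline —
wire protocol, session logs, fixation detection, dwell and attention measures,
and contribution models — can be exercised and validated end to end without
equipment or human data.

The package has two user-facing layers:

* a **simulation layer** (`generate_session()` plus `agent_spec()` and
  `session_config()`) that runs a complete session in simulated time and
  writes gaze/event/behavior CSV logs with a ground-truth file; and
* an **analysis layer** (`analyze_session()` and the functions it composes)
  that consumes such logs — whether generated here or produced by compatible
  hardware drivers — and yields fixations, dwells, attention ratios, and
  model comparisons.

## The game and its payoffs

Two players each receive an endowment of 20 points per round and privately
choose integer contributions $C_i \in [0, 20]$ to a common pool. We use a
linear payoff

$$\pi_i = 20 - C_i + m\,(C_i + C_j),$$

with marginal per-capita return $m = 0.75$ by default. Any $m \in (0.5, 1)$
preserves the two-player dilemma: contributing one point costs the
contributor $1 - m > 0$ but yields $2m - 1 > 0$ jointly. The payoff identity
$\pi_i + \pi_j = 2 \cdot 20 + (2m - 1)(C_i + C_j)$ is asserted on every
generated round. Sessions default to 3 games of 10 rounds with fixed pairs,
and pair histories reset at game boundaries, so each game's round 1 is
history-free. Both $m$ and the endowment are configuration, not substance:
all payoff-dependent quantities are relative to `game_config()`.

Each round shows two logical screens. The *contribution screen* offers the
21 options as a 7×3 matrix of option AOIs. A 400×200 px AOI cannot tile 21
options on a 1,920 px-wide screen, so option cells are the maximal
non-overlapping rectangles, 274×200 px by default. The *feedback screen* has
four labeled rows — You, Person B, Sum, Average — each with two 400×200 px
numeric AOIs (current round, game total): 8 numeric AOIs plus 6 written-text
AOIs (two column headers, four row labels). Screens are logical states with
AOI geometry; nothing is drawn.

## The contribution models

For a player $i$ with partner $j$, the **matching model** predicts

$$C_{i,t} = w_i\,C_{i,t-1} + (1 - w_i)\,C_{j,t-1},$$

a weighted average of the pair's previous contributions; $w_i \in [0, 1]$ is
interpretable as the relative weight of one's own payoff information. Two
**conditional cooperation** strategies serve as benchmarks: naïve beliefs
($C_{i,t} = C_{j,t-1}$, i.e. $w = 0$) and actual beliefs
($C_{i,t} = C_{j,t}$). Other conditional-cooperation strategy families
require design features (belief elicitation, strategy method) absent from
this two-player repeated design and are deliberately not implemented.

Models are scored by mean squared deviation (MSD) over all predicted rounds.
Predictions exist for $t \ge 2$ within each game; games are pooled per
individual, and the grand MSD is the unweighted mean over individuals. The
actual-beliefs strategy could predict round 1, but is scored on the same
rounds as the others so all models share one denominator. Predictions stay
real-valued: the matching rule is defined on reals, and rounding would add
an operation the model does not state.

Minimizing the MSD of the matching model in $w$ is a one-parameter least
squares problem. With $d_t = C_{i,t-1} - C_{j,t-1}$ and
$e_t = C_{i,t} - C_{j,t-1}$, the minimizer is
$w^\* = \sum e_t d_t / \sum d_t^2$, clipped to $[0, 1]$ (`fit_w()`); a grid
search exists only as a test oracle. When the pair's lagged contributions
never differ ($d_t \equiv 0$) every $w$ fits equally well; such individuals
are flagged unidentifiable and excluded from downstream correlations.
`matching_model()` wraps the estimator in a classed object with the usual
`coef`/`predict`/`residuals`/`summary`/`simulate` methods.

## Attention measures

Relative attention for player $i$ is

$$ra_i = \frac{\sum \mathrm{fix}_i}{\sum \mathrm{fix}_i + \sum \mathrm{fix}_j},$$

the share of feedback-screen fixations on $i$'s own payoff AOIs among
fixations on own-plus-other payoff AOIs. Fixation *counts* are the default
(`weight = "count"`), matching the reading of "numbers of fixations"; a
duration-weighted variant is one switch away. `ra` is computed across the
experiment by default, with a per-round variant used for the
attention-versus-contribution-difference regression. When both counts are
zero `ra` is undefined and flagged rather than coerced.

## Fixation detection

`detect_fixations_idt()` is a classic dispersion-threshold (I-DT) detector:
grow a sample window while $(\max x - \min x) + (\max y - \min y)$ stays at
or below the dispersion threshold; when the window can grow no further and
spans at least the minimum duration, emit it as a fixation (centroid = mean
of member samples) and continue after it, greedily left to right. Invalid
samples (tracking loss, simulated saccade gaps) break candidate windows.
Defaults are the common literature settings of ~1° dispersion (38 px at the
package's viewing geometry) and 100 ms minimum duration. The detector is
validated against an independent brute-force implementation that
re-enumerates, for every window start, the maximal window satisfying the
dispersion criterion from scratch.

Dwells collapse maximal runs of consecutive same-AOI fixations into single
visits; dwell time is the sum of member fixation durations, and per-AOI
dwell totals must equal per-AOI fixation-duration totals (a conservation
property asserted in the tests). AOIs are half-open rectangles
$[x, x+w) \times [y, y+h)$, so a centroid on the top-left edge belongs to
the AOI and one on the bottom-right edge does not, and adjacent cells never
double-claim a point.

## The tracker simulator and its noise model

`stream_gaze()` emits samples at 60 Hz. During a scripted fixation, sample
positions are the target plus isotropic i.i.d. Gaussian noise with
per-axis sd equal to `accuracy_deg * px_per_deg` — 0.5° × 38 px/° = 19 px at
defaults. The degree-to-pixel factor assumes a 24-inch 1,920×1,080 display
viewed from ~60 cm; viewing geometry is not part of the tracker's own spec,
so `px_per_deg` is configurable. Binocular data are collapsed to one
cyclopean point and pupil size is a constant plus small noise, since no
analysis here uses per-eye or pupil signals. Between scripted fixations the
simulator emits invalid samples by default (conservative for fixation
detection); linear saccade interpolation is available.

One numerical consequence deserves emphasis. Treating the full 0.5°
accuracy as *i.i.d. per-sample* noise makes the sample cloud of a single
fixation much wider than a 1° dispersion window: the expected x+y range of
~15 samples with sd 19 px is already ≈125 px. A 38 px threshold would
shred every simulated fixation. `analyze_session()` therefore derives its
default dispersion threshold from the noise model — 8 standard deviations
of the per-sample noise, 152 px at defaults — which covers the expected
range with margin. This cannot bridge distinct AOIs, because scripted
fixations are separated by invalid saccade samples that break windows
regardless of the threshold. Real trackers concentrate most of a 0.5°
accuracy budget in a slowly varying offset rather than sample-to-sample
scatter, so analyses of hardware data should use the literature default
(38 px) with the measured precision of the device in mind; the 8-sd rule is
specific to the i.i.d. simulation model.

## Calibration flow

Calibration is attempt-based: each attempt draws an attained accuracy from
a zero-truncated normal quality model (mean 0.4°, sd 0.15° by default) and
succeeds when it is below the 0.5° threshold. Failure triggers the next
attempt automatically, up to 3 attempts, after which the policy's failure
action applies — exclude the participant (default), continue untracked, or
abort the session. Success "within three attempts" is read as: the third
failed attempt applies the cutoff. Point-level calibration regression is
not modeled; the flow consumes only attempt-level accuracy, which is all
the policy evaluates. An excluded participant's partner is removed with
them by default (a config switch allows keeping them), since a two-player
game cannot continue one-sided and re-pairing mid-session is not attempted.

## Coordination: registration, barriers, recording

The session proceeds with however many clients registered by the deadline
(30 s simulated by default); an odd arrival count drops the last-registered
client with a logged notice rather than aborting, though aborting is
available. The server performs all aggregation — sums and averages are
computed once, server-side, and broadcast — and the behavior log can be
replayed to reproduce every broadcast value.

The gaze-contingent barrier evaluates on fixation events, not raw samples:
it releases at the first moment every client has, for every required AOI,
at least one fixation and at least `min_dwell_ms` of cumulative fixation
time, the completion instant being the end of the fixation that satisfies
the requirement. An optional timeout applies a configurable fallback
(hold or release). In the simulated driver the barrier consumes the
scripted ground-truth fixations as its "online" feed; with hardware, the
same function would consume the online detector's output.

Recording is windowed per screen: `recording_on`/`recording_off` events
bracket every recorded window, and samples outside windows are never
written. In the simulated transport every logical message crosses the wire
codec (newline-delimited JSON) and a routing log records each hop, so tests
can assert structurally that no client ever exchanges data with another
client. Gaze samples are batched into one `gaze` message per screen rather
than one per sample; the samples themselves travel to the log, and the
batching keeps the routing log proportional to screens, not samples.

## The synthetic scenario generator

Agent behavior and gaze are generated with known ground truth so that every
estimator can be checked against what it should recover:

* **Round-1 contributions**: discretized normal, mean 12, sd 3, clipped to
  [0, 20] — median 12, matching typical first-round generosity in a 0–20
  PGG. From round 2, matching agents apply the matching rule plus Gaussian
  noise (sd 2 points by default), rounded and clipped.
* **Feedback-screen gaze**: the number of payoff fixations per screen is
  drawn from a normal with mean 17, sd 9, truncated at 1 — scaled to the
  fixation counts typical of such feedback screens — and the share directed
  at own-payoff AOIs is `clip(true_w + noise, 0, 1)` with coupling noise sd
  0.05. This is the simplest mechanism producing a positive attention–weight
  relation; setting the coupling noise large effectively severs it for null
  tests.
* **Contribution-screen gaze**: a handful of option AOIs are inspected and
  the final fixation always lands on the clicked option, so the
  last-fixation-versus-click correspondence is 1 by construction and any
  analysis shortfall is attributable to the pipeline, not the scenario.
* **Fixation durations**: truncated normal, mean 250 ms, minimum 180 ms —
  long enough that every scripted fixation spans the detector's minimum
  duration at 60 Hz even after losing edge samples to noise.

What the generator deliberately does **not** emulate: fixations on the
written-text AOIs or outside AOIs (so AOI-share reports on synthetic data
show ~100% numeric, unlike real participants, who spend most fixations on
text); saccade dynamics, drift, blinks or head movement; any systematic
dependence of per-round attention on the contribution difference (the
per-round `ra`-on-difference slope is therefore ≈ 0 on default synthetic
sessions, and the regression is exercised on explicitly coupled data in the
tests); and re-pairing between games. Passing tests on synthetic sessions
validate the machinery — codecs, logs, detection, measures, estimators —
not the behavioral realism of any particular human dataset.

## Parameter-recovery design

Recovery of the matching weight needs input variation: when both pair
members follow the matching rule, their contributions converge and the
lagged difference $d_t$ — the regressor that identifies $w$ — shrinks
toward zero. Simulation shows that with mutual matching pairs at noise
sd 2, only ~83% of fitted weights land within ±0.15 of truth. The package's
recovery experiments therefore pair each focal matching agent with an
*erratic probe* partner (`strategy = "erratic"`: i.i.d. uniform
contributions), the standard system-identification practice of exciting the
input; recovery then exceeds 95% within ±0.15 at noise sd 2, and is exact
up to rounding at zero noise. Model-comparison and attention-linkage
experiments keep mutual matching pairs, since they concern populations, not
probe identification.

## Problem sizes and numerical choices

Simulated sessions used in the validation suite and the acceptance script
are sized like the motivating design: up to 40 participants (20 fixed
pairs), 3 games × 10 rounds, 60 Hz gaze — roughly 26,000 scripted fixations
and 600,000 samples at full scale, which the pipeline processes in well
under a minute. Smaller sessions (2–4 participants, 1–2 games) are used
where the property under test does not depend on scale.

Other numerical conventions: timestamps are integer milliseconds from a
per-session epoch distributed at registration (clients never log
wall-clock); sample timestamps are floored to the millisecond grid, so a
1 s fixation at 60 Hz spans 60 samples and ~983 ms; all simulation entry
points take explicit seeds, derive child seeds deterministically, and
restore the caller's RNG state, so identical seeds yield byte-identical
logs; and degenerate inputs (empty histories, zero-variance regressors,
zero attention counts, unidentifiable weights) are flagged as undefined
rather than silently coerced to numbers.

## Known limitations

The transport is an in-process simulation of a star network, not a socket
server: message semantics, framing and topology are real, but concurrency,
partial failure and cross-machine deployment are out of scope. The gaze
noise model is i.i.d. and stationary, which is pessimistic about dispersion
(see above) and optimistic about drift. Calibration is modeled at the
attempt level only. The mixed-effects analysis of dwell times that one
would run on real data is ordinary off-the-shelf statistics and is left to
the analyst; the package stops at the per-(participant, game, round, AOI)
dwell table that such a model consumes.
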