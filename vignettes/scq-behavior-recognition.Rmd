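---
title: "Queueing-based bed-exit behavior recognition: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queueing-based bed-exit behavior recognition: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqmon)
```

## The problem

A bedside fall-prevention monitor must notice, within about a second, that
a patient has left the bed. Systems that can be wheeled into a ward and
removed again restrict the camera to a narrow field of view — the bed region
or part of the body — so that only the target patient is observed and the
scenes stay simple enough for a lightweight detector on an embedded device.
The price of the narrow view is a fragile detection stream: the bounding
box of the head or trunk disappears for runs of frames, reappears abruptly,
and its position fluctuates while the patient merely turns over. Any
per-frame decision rule inherits all of that noise. `scqmon` implements a
deliberately simple two-stage pipeline that absorbs it: a per-frame
movement *status*, then a queueing buffer that only declares a *behavior*
when the recent status history is consistent enough.

This package operates purely on detection traces (frame index, zero or
more labeled boxes per frame). The detector that produces such traces is
out of scope, as is any learned sequence model — the design goal of the
queueing stage is precisely to avoid recurrent networks and tracking
filters on the embedded target.

## Status classification

Frame $i$'s tracked box center $P_i$ is compared with the previous one
through their Euclidean distances to a fixed reference $P_0$: moving away
(+1) when the distance grew by at least $\varepsilon$, moving toward (−1)
when it shrank by at least $\varepsilon$, neutral (0) otherwise, and −2
when the frame has no box. Two compositional rules matter and are fixed by
this package (they are easy to get wrong and change behavior under
dropouts):

* **Carry across gaps.** The "previous" position is the last *observed*
  position, carried across −2 runs. A box reappearing after a dropout is
  compared against where it was last seen; resetting to $P_0$ instead
  would fabricate a large movement at every reappearance, exactly where
  narrow-view footage is most fragile.
* **First observation.** The first detected frame is compared against
  $P_0$ itself, which plays the role of $P_{i-1}$ before anything has been
  seen.

When several boxes are present (head and trunk can both be detected), one
is selected by label priority — head first by default, since the head is
the stable landmark while the patient is in bed — and ties within a label
go to the highest confidence. Statuses depend only on the selected centers,
never on box sizes.

**Choice of $P_0$.** Three modes are supported: the image origin, a fixed
predefined point, and the first detected position. The origin is the
simplest and is the default for the command-line `run`. For simulation
studies this package anchors $P_0$ at the bed
(`scenario_classifier()`), because the status rule measures *radial*
movement relative to $P_0$: with a bed-anchored reference, walking away
from the bed changes the distance at the full per-frame step, whereas an
origin far off the walking direction sees only the projection of the step
and can classify the first frames of an exit as neutral. Both
conventions are valid deployments; the bed anchor makes the geometry of
the synthetic scenarios exact.

**Choice of $\varepsilon$.** No canonical value exists; the default is 5 px
at 640×360 input scale — small against the ~475 px bed-to-exit transit of
the simulated scenes, large against sub-pixel detector jitter (σ = 1 px in
simulation). It is a plain configuration parameter everywhere.

## The SCQ buffer

Statuses are routed into four FIFO queues (off bed / on bed / return /
nobody for +1 / 0 / −1 / −2). Three rules define the dynamics:

1. at most $M = \mathrm{round}(R \times T)$ statuses are buffered in
   total; when a status arrives with the buffer full, the *globally
   oldest* buffered status is dropped from the head of its queue;
2. when the receiving queue reaches its length $L_j$, behavior $j$ is
   recognized, stamped with the completing frame, and all queues are
   flushed;
3. nothing else ever removes a status.

Rule 1 deserves a note: "drop one status from the head of its output
queue" admits several readings (oldest overall? head of the receiving
queue? round-robin?). Global-FIFO eviction is the reading under which the
buffered multiset is *exactly* the sliding window of the last
$\min(M, \text{received since flush})$ statuses — which is what the window
definition $M = R \times T$ describes. The test suite pins this semantics
against an independent list-slicing oracle (slice the last $M$ statuses,
count per queue) on 10⁴ random streams, at every step.

The configuration constraints $\max_j L_j \le M \le \sum_j L_j$ are
enforced at construction: the first guarantees every queue *can* fill
within one window, the second that a full window fits in the queues.

Consequences worth knowing:

* **Minimum latency.** From an empty system, behavior $j$ fires at exactly
  the $L_j$-th supporting status and never earlier — 1.0 s at the
  operating point $R = 15$, $T = 1$ s, $L_j = 15$.
* **Dropout immunity.** A dropout of $k < L_4$ consecutive missing frames
  can never fill the nobody queue, so no false nobody alarm is possible
  from it.
* **Re-emission.** A sustained behavior re-emits its event every $L_j$
  statuses after each flush; there is no refractory period in the model.
  A `debounce` option (off by default) collapses consecutive duplicate
  events at the reporting layer.
* **Pure-window identity.** When $M = L_j$, queue $j$ fills iff the last
  $M$ statuses are uniformly $j$; in that case the equivalent sum-form
  recognition conditions ($\sum \hat S = L_1$ for off bed,
  $\sum(1-\hat S) = L_2$, $\sum(-\hat S) = L_3$, $\sum(-\hat S/2) = L_4$)
  hold exactly, and the tests assert them at every recognition. The
  implementation uses queue occupancy, not the sums: for $M > L_j$ the
  sum forms admit unintended mixed-status solutions, while the queue
  semantics remain well defined.

Recognized events can be expanded to a per-frame behavior-index step trace
(on bed = 0, off bed = 1, return = −1, nobody = 2; frames before the first
event default to 0, the resting state) for plotting and inspection.

## The simulator

`scenario()` scripts a list of (behavior, duration) segments and
`generate()` renders them:

* *on bed*: centers jitter around the bed anchor (Gaussian, σ = 1 px by
  default), label `head`; one short burst of 3× amplified jitter per
  segment emulates turning over, with the excursion capped at 4 px so it
  stays below the default $\varepsilon$ — real turning movements perturb
  the box without constituting an exit;
* *off bed*: linear transit from bed anchor toward exit anchor at
  `speed` (200 px/s default, i.e. a 13.3 px per-frame step ≥ 2ε at
  15 fps), label switching `head` → `trunk` at the midpoint, as a detector
  sees the head while the patient sits up and the trunk while walking;
* *return*: the reverse transit, `trunk` → `head`;
* *nobody*: empty frames.

Detection failures are injected on top: dropout windows blank all
detections inside non-nobody segments; flicker windows remove every other
frame. Box sizes (head 40×40, trunk 80×120 px) and confidences
(Uniform(0.6, 0.99)) are cosmetic — only the selected centers and the
confidence *ordering* matter downstream. Everything is deterministic given
the scenario, whose seed drives a private RNG stream (the caller's RNG
state is untouched).

`ward_scenario()` is the reference script: nine behavior segments —
on bed, off bed, nobody, return, twice, ending on bed — at 15 fps. The
ground-truth file divides the long initial on-bed period (6 s, twice the
later on-bed durations) into two clips, so each sequence contributes
4 on-bed, 2 off-bed, 2 return and 2 nobody clips to evaluation. The
`horizontal` profile uses the full 475 px transit; the `vertical` profile
has a shorter transit (288 px — a narrower view sees less of the walk) and
additional flicker windows. Unless `clean = TRUE`, each on-bed segment
receives one dropout of 5–10 frames placed in its middle third: mid-segment
placement mirrors where such failures are observed in real traces, and it
keeps every clip long enough to contain an uninterrupted 15-status run, so
the failure mode stresses the buffer without making clips structurally
unrecognizable. Dropout durations are a configuration default, not an
estimate from data.

What the simulator does **not** model: pixel rendering, multi-person
scenes, camera geometry and perspective, detector confusion between
labels, and position noise that is correlated over time. Perfect
recognition rates on these synthetic traces therefore demonstrate the
logic of the pipeline — latency, window semantics, dropout immunity —
not field performance on ward video.

## Evaluation

Detection-stage quality is summarized by the usual confusion-count metrics
(accuracy, precision, recall, F1), with undefined cases raised as errors
rather than silently reported as 0. Percent rounding is half-up, matching
how published tables print whole percents.

Behavior recognition uses clip-based accounting: a ground-truth clip is
recognized iff at least one event of its behavior falls inside it; events
of other behaviors inside a clip are tallied as confusions but do not, by
themselves, fail the clip. This binary per-clip credit (no latency bound)
matches the published protocol; a stricter `max_latency_s` variant is
available for stress tests. Counts are pooled across sequences before
rates are computed.

```{r}
evs <- list(); trs <- list()
for (s in 1:10) {
  case <- generate(ward_scenario("horizontal", seed = s, clean = TRUE))
  fit <- detect_behaviors(case$trace,
                          classifier = scenario_classifier(case$scenario))
  evs[[s]] <- fit$events; trs[[s]] <- case$truth
}
batch_evaluate(evs, trs)$by_behavior
```

## Numerical and degenerate-input choices

* $M$ rounds to the nearest integer with a floor of 1; non-integer
  $R \times T$ is accepted.
* $\varepsilon = 0$ makes every nonnegative distance change "moving away"
  (the +1 branch is checked first); $\varepsilon > 0$ is recommended.
* An all-empty trace classifies to all −2 and is valid, except under
  `p0_mode = "first_detection"`, which errors by design.
* Empty traces, empty event sets and zero-clip behaviors are legal
  everywhere downstream; rates over zero clips are `NA`, never 0.
* Trace files serialize floats at full precision (`%.17g`), so write/read
  round-trips are exact.
* Problem sizes used in the shipped checks — 10⁴ oracle streams of length
  40, 10 sequences (450 frames each) per profile — were chosen as the
  smallest sizes at which the window property and the full clip protocol
  are exercised meaningfully.

## Limitations

The package starts from detection traces; nothing here compensates for a
detector whose boxes are systematically biased. The single-target
assumption is structural: a second person in view would need an upstream
identity tracker. Queue lengths trade latency against robustness and the
defaults encode the published operating point (1 s at 15 fps); deployments
with different frame rates should re-derive $L_j$ from the desired
response time rather than reuse 15.
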