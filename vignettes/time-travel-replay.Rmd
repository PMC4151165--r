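---
title: "Counterfactual replay: how the engine tracks causality across time travels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual replay: how the engine tracks causality across time travels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoreplay)
```

## The problem

Interactive narratives with an illusion of backward time travel need more
than a video-game restart. When a participant relives a sequence of events,
the world must unfold *exactly* as it did before — including their own past
actions, re-enacted by a clone — until the participant's new interventions
make parts of the old history impossible. The engine must then decide, action
by action, what still happens, what happens differently, and what never
happens, while keeping the whole round auditable and deterministic.

This package implements that logic layer. It deliberately excludes any
rendering, animation, audio or motion-capture concern: the interface between
this engine and a presentation layer is the abstract action stream.

## The model

A **history** is an initial world state plus an ordered sequence of timed
actions; the state trajectory is derived, never stored, by folding effects
over the initial state (`state_at()`). World state is a total map from
entities to finite symbolic variables — locations in
`{outside, ground, upper, elevator}`, alive/dead, elevator position/motion/
frozen/pending, alarm on/off. Keeping every domain finite and symbolic makes
precondition evaluation exact and the whole engine free of floating-point
state.

Every action is an instance of a declarative schema with *preconditions*
(state predicates that must hold for the action to take place) and
*postconditions* (the assignments it produces). Utterances are legitimate
empty-effect actions: they replay at their recorded times with no causal
consequences, which is exactly how recorded speech should behave. Two
schemas (the alarm toggle and the elevator call buttons) have
state-dependent outcomes, expressed as computed effects; this is what makes
replay preserve *actions rather than outcomes* — a clone re-pressing an
alarm the live participant already switched on switches it off.

Causality distinguishes three entity classes:

1. **The participant** has free will. An injected action always executes
   (only physically available controls can be injected) and is recorded,
   because later travels must re-enact it.
2. **Physical objects** follow deterministic rules and are re-simulated
   from scratch every round. If nobody intervenes they behave exactly as
   before; if someone does, they diverge coherently instead of replaying
   contradictory recorded motions.
3. **Agents** (visitors, the gunman, clones) are replayed: at the recorded
   start time of each recorded action the engine checks its preconditions;
   on success the action executes unchanged (`replayed`); on failure a
   replacement rule may substitute a similar action (`retargeted`); failing
   that, the action is dropped (`omitted`, contributing no effects but kept
   in the log for audit).

A travel back (`travel_back()`) re-attributes the participant's recorded
actions to a fresh clone entity (`P1`, `P2`, ...), queues the non-omitted
agent actions at or after the destination, and discards nothing silently:
the finished round's history *replaces* the old one as the frame of
reference. Multiple travels accumulate co-existing clones.

## The gallery instance

The packaged scenario is a two-level gallery: six visitors arrive; a
compliant operator ferries five of them upstairs while one stays down; a
seventh arrival asks to be taken up and starts shooting on arrival. The two
scenario rules are:

* **Shooting retarget** — a failed shooting tries new targets co-located
  with the gunman: living visitors in ascending id order, then the
  participant; each candidate serves at most one original attempt; clones
  are excluded unless `clone_targetable` is set. A participant-shot event is
  recorded with its own schema and a `hit` flag — the participant stays
  operational, since a session continues after the participant is targeted.
* **Enter-floor correction** — a failed elevator exit succeeds at whatever
  floor the elevator is currently stationary at (frozen counts as
  stationary); between floors, no exit.

A trial terminates once the termination window (7 s) has elapsed since the
last shooting while no further shooting is possible (elevator not moving, no
living visitor on the gunman's level), or once the gunman has been trapped
inside the elevator for the window. *Trapped* here means stationary between
floors with the gunman aboard, whether or not the alarm is still on: in the
trap solution the clone's replayed alarm press switches the alarm off about
seven seconds after the freeze, and an unfrozen elevator stalled mid-shaft
still imprisons its passenger (unfreezing never resumes a cancelled ride).
A `round_timeout` (60 s) ends degenerate rounds — e.g. a fully idle
operator, where nobody ascends and neither condition can ever fire.

## Tunable parameters

All constants live in the scenario config (YAML round-trippable,
`gallery_config()`), in seconds:

| parameter | default | role |
|---|---|---|
| `tick` | 0.1 | virtual-time grid; all times quantized to it |
| `travel_duration` | 5.0 | elevator ride between floors |
| `command_delay` | 0.5 | button press to start of motion |
| `shot_interval` | 0.5 | between successive shootings |
| `arrival_to_shooting` | 0.5 | gunman's floor entry to first shot |
| `exit_stagger`, `board_interval` | 0.5 | choreography spacing |
| `service_wait` | 1.0 | operator's dwell before sending/recalling the elevator |
| `alarm_delay` | 1.0 | operator's reaction from first shot to alarm press |
| `termination_window` | 7.0 | both termination clauses |
| `round_timeout` | 60.0 | hard stop for degenerate rounds |

The nonzero `command_delay` is load-bearing: it is the window in which an
injected alarm press can pre-empt a commanded ride (the reference
second-round intervention). The round-1 script is *derived* from these
constants, so the scripted visitor choreography is consistent with the
elevator physics under the compliant operator by construction.

## Numerical and design choices

* **Tick grid and tie-breaks.** Simultaneous actions resolve in a fixed
  phase order — injected participant actions, then due recorded actions in
  recorded order, then physical transitions. This makes an injection at the
  exact tick of a due command take effect first, and makes every run
  byte-reproducible (identical configs, policies and seeds give identical
  event logs).
* **Round 1 is checked too.** The reasoning engine proper only activates
  after the first travel, but round-1 scripted actions are
  precondition-checked with the same machinery and skipped silently on
  failure (no replacement rules). This makes divergence under a
  non-compliant operator well-defined instead of undefined.
* **Early termination flushes the queue.** Recorded actions never reached
  before a trial ends are recorded as omitted, so every history fully
  accounts for every attempted action and shooting-attempt conservation
  (attempts = executed + omitted) holds in every round.
* **Replacement search order.** Rules are visited in declaration order;
  within the shooting rule, candidates in ascending entity id, then the
  participant. The specific substitution behavior (single ground-floor
  visitor first, then the participant, remainder omitted) is fixed; the
  search order beyond that is a reproducibility choice.
* **Arbitrary destinations.** Travels normally go to time 0, but any
  on-grid destination within the recorded round works: actions before the
  destination are immutable history (carried over, re-attributed to the
  clone) and the world at the destination is reconstructed by refolding.
* **Stochastic policies.** The engine itself is seedless-deterministic; the
  only randomness is the optional `delay_range` draw of the trap policy,
  taken from a seeded generator that saves and restores the global RNG
  state.

## What the scenario exercises — and what it does not

The gallery instance, its policies and the brute-force strategy enumerator
are engine-exercising fixtures. They demonstrate every mechanism the engine
has: replay identity (a no-injection round reproduces its source
action-for-action), retargeting, omission, toggle semantics, clone
accumulation, both termination clauses, and the three outcome classes of the
single-press strategy space (press before the ride: the gunman exits at
ground and shoots the remaining visitor and the participant; press mid-ride:
trapped, nobody shot; press after arrival or never: the original five).
Policies are **not** participant models: no human behavioral statistic is
reproduced or claimed, and passing tests say nothing about what people do in
such scenarios — only about what the world does in response.

## Problem sizes used by the test suite

The suite validates the core machinery on an exhaustive 54-state elevator
enumeration, 100 randomly generated legal action sequences plus 40
permutation fuzz cases in a small static-effect toy domain, 25×6 refold
oracle comparisons, a 66-point exhaustive press-time enumeration (every tick
across the gunman's ride plus never-press), a sampled strategy grid for the
trajectory properties, and a 40-session seeded stochastic batch compared
against the exhaustive-grid expectation. These sizes keep the default run
around twenty seconds while covering every interval boundary of the
strategy space; all grids refine trivially via function arguments.

## Known limitations

* Values are finite symbols; there is no numeric or probabilistic state.
* No continuous spatial trajectories: locations are floor-granular, so
  within-floor geometry (who is standing where) cannot influence
  preconditions.
* The gallery script is written for exactly six visitors; other counts
  require a new script, not just a config change.
* Whether a gunman left upstairs with no living targets would descend and
  continue is not modeled: the packaged script records no such action, so
  replay omits further shooting and the termination rules end the round.
* Refused visitors wait on the ground floor indefinitely; the second
  zero-shooting solution (send the gunman up alone) is reachable but its
  visitor-side behavior is a modeling choice, not an observed fact.
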