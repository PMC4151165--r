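# chronoreplay

A causality-tracking reasoning engine for *virtual time travel* in
interactive narratives. It records an interactive round as a **history** — an
initial world state plus an ordered sequence of timed actions — and, after a
travel back in time, replays that history while the participant intervenes
freely: recorded human-like actions are re-executed exactly where their
preconditions still hold, replaced by similar actions where a rule applies,
and omitted otherwise; physical objects are re-simulated deterministically
from scratch. Each travel adds a *clone* — an agent re-enacting the
participant's previous actions, unaware of the present — and the newest
history becomes the sole frame of reference for the next travel.

The package targets researchers building simulation backends for behavioral
experiments on counterfactual reasoning and moral dilemmas, and anyone who
needs a deterministic, auditable replay engine with STRIPS-style action
semantics.

## The model

Entities fall into three causal classes:

* **participant** — free will: an injected action always executes and is
  recorded (necessary for further travels);
* **physical** objects (elevator, alarm) — deterministic rules, re-simulated
  every round regardless of the previous round;
* **agents** (visitors, the gunman, clones) — recorded actions are replayed:
  whenever virtual time `t` coincides with the recorded start time of action
  `a` with precondition set `pre(a)` and effects `eff(a)`,

  ```
  s_t ⊨ pre(a)            →  execute: s_{t+} = eff(a)(s_t)   [replayed]
  s_t ⊭ pre(a), rule fires →  execute substitute a'           [retargeted]
  otherwise                →  no effect                       [omitted]
  ```

States are total maps `entity → (variable → value)` over finite symbolic
domains; `state_at(h, t)` is the fold of the effects of all non-omitted
actions with start ≤ t over the initial state, so trajectories are exactly
reproducible and histories are validated by refolding.

The packaged reference instance is a two-level art gallery: the participant
operates an elevator and a freeze-alarm from a ground-floor workbench, six
visitors arrive (five end up upstairs, one stays down), and a seventh
arrival rides up and starts shooting — a trolley-style dilemma in which
doing nothing loses five, sending the elevator down endangers one, and the
non-obvious solution (pressing the alarm while the gunman is mid-ride) traps
him with nobody harmed. Two scenario-specific replacement rules implement
the paper-style corrections: shooting retargets to living persons co-located
with the gunman (visitors first, then the participant), and elevator exits
correct to whatever floor the elevator is actually stationed at.

## Worked example

```r
library(chronoreplay)
ses <- worked_example_session()   # round 1 compliant; round 2: alarm pressed
session_rounds(ses)               # right after the clone's up-command
#> # A tibble: 2 × 10
#>   round n_actions n_injected n_replayed n_retargeted n_omitted visitors_shot
#> 1     1        47          6          0            0         0             5
#> 2     2        46          1         31            3         3             1

worked_example_tail(ses)          # round 2 from the gunman's entry onward
#>        t actor action            target status     original_target
#>  1  34   G     enter_gallery     ""     replayed   ""
#>  2  34.5 G     request_up        ""     replayed   ""
#>  3  35   G     enter_elevator    ""     replayed   ""
#>  4  36   P1    push_up           ""     replayed   ""
#>  5  36.1 P     push_alarm        ""     injected   ""
#>  6  42   G     exit_elevator     ""     retargeted ""
#>  7  42.5 G     shoot             "V6"   retargeted "V1"
#>  8  43   G     shoot_participant "P"    retargeted "V2"
#>  9  43.5 P1    push_alarm        ""     replayed   ""
#> 10  43.5 G     shoot             "V3"   omitted    ""
#> 11  44   G     shoot             "V4"   omitted    ""
#> 12  44.5 G     shoot             "V5"   omitted    ""
```

Reading the second round: everything replays exactly as recorded until the
live participant (`P`) injects an alarm press at 36.1 s, one tick after the
clone `P1` re-issues the up-command. The elevator freezes at the ground
floor, so its recorded ride never happens; the gunman's recorded upper-floor
exit is corrected to the ground floor; his first two shootings retarget to
the one ground-floor visitor (`V1 → V6`) and to the participant (`V2 → P`);
the remaining three cannot be replaced and are omitted. Finally `P1`'s
recorded alarm press — preserved as an *action*, not an outcome — now
switches the alarm **off**. One visitor is shot instead of five.

Other entry points:

```r
sc   <- build_gallery()
h1   <- record_round(sc, "comply_then_alarm")          # 5 visitors shot
ses3 <- run_loop(sc, list("comply_then_alarm", "trap_gunman", "do_nothing"),
                 n_rounds = 3)                          # rounds shoot 5, 0, 0
enum <- enumerate_alarm_strategies(sc)                  # 3 outcome classes
write_event_log(ses3, "events.jsonl")                   # JSON Lines audit log
```

A command-line runner is included
(`Rscript inst/cli/chronoreplay.R --mode time_travel --rounds 3
--policy r2=trap_gunman --out out/`, plus `--selftest`).

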