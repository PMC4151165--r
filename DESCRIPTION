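Package: chronoreplay
Title: Causality-Tracking Replay Engine for Interactive Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A discrete-event reasoning engine for "virtual time travel" in
    interactive narratives. Records a round of an interactive scenario as a
    history of timed actions over an abstract world state, then replays it
    after backward time travel: recorded agent actions are re-executed under
    precondition checks and replaced, retargeted, or omitted when the world
    has diverged; physical objects are re-simulated deterministically; the
    live participant can intervene freely, and each intervention is recorded
    for further travels, with past selves re-enacted by clones. Ships the
    two-level gallery moral-dilemma scenario (elevator, alarm, six visitors
    and a gunman) as the reference instance, together with participant
    policies, a brute-force strategy enumerator, JSON Lines event logs, batch
    session summaries, and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
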