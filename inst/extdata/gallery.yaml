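name: gallery
tick: 0.1
n_visitors: 6
timing:
  travel_duration: 5.0
  command_delay: 0.5
  shot_interval: 0.5
  arrival_to_shooting: 0.5
  exit_stagger: 0.5
  board_interval: 0.5
  service_wait: 1.0
  alarm_delay: 1.0
  termination_window: 7.0
  round_timeout: 60.0
engine:
  clone_targetable: no
  tie_break:
  - participant
  - agent
  - physical
  seed: 1
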