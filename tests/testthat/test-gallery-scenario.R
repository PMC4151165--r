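test_that("the initial gallery world matches the declared setup", {
  w <- chronoreplay:::scenario_initial_world(gallery_sc())
  for (v in paste0("V", 1:6)) {
    expect_identical(world_get(w, v, "location"), "outside")
    expect_true(world_get(w, v, "alive"))
  }
  expect_identical(world_get(w, "G", "location"), "outside")
  expect_identical(world_get(w, "elevator", "position"), "ground")
  expect_identical(world_get(w, "elevator", "motion"), "stationary")
  expect_false(world_get(w, "elevator", "frozen"))
  expect_false(world_get(w, "alarm", "on"))
  expect_identical(world_get(w, "P", "location"), "ground")
})

test_that("a compliant playout puts five visitors upstairs and one downstairs at the gunman's entry", {
  sc <- gallery_sc()
  h1 <- canonical_round1()
  gE <- script_time(sc, "G", "enter_gallery")
  w <- state_at(h1, gE)
  locs <- vapply(sc$visitor_ids, function(v) world_get(w, v, "location"), character(1))
  expect_identical(sum(locs == "upper"), 5L)
  expect_identical(sum(locs == "ground"), 1L)
  expect_identical(unname(locs[["V6"]]), "ground")
})

test_that("scenario configuration round-trips through YAML bit-exactly", {
  cfg <- gallery_config()
  f <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  expect_identical(read_scenario_config(f), cfg)
  # and the packaged default config builds the same scenario
  packaged <- system.file("extdata", "gallery.yaml", package = "chronoreplay")
  sc2 <- build_gallery(packaged)
  expect_identical(sc2$config, gallery_sc()$config)
  expect_identical(sc2$script, gallery_sc()$script)
})

test_that("inconsistent configuration is rejected with a validation error", {
  cfg <- gallery_config()
  cfg$n_visitors <- 5L
  expect_error(build_gallery(cfg), "6 visitors")
})

test_that("the shooting retarget rule matches new targets in candidate order", {
  sc <- gallery_sc()
  w <- chronoreplay:::scenario_initial_world(sc)
  w <- world_set(w, "G", "location", "ground")
  w <- world_set(w, "V6", "location", "ground")
  for (v in paste0("V", 1:5)) w <- world_set(w, v, "location", "upper")
  due <- function(tgt) new_action("shoot", "G", 40, targets = tgt,
                                  params = list(floor = "upper"),
                                  round = 2L, status = "replayed")
  rt <- new.env(); rt$used_targets <- character()

  # V1 -> V6 (the single ground-floor visitor), V2 -> the participant,
  # V3..V5 cannot be replaced
  s1 <- shooting_retarget_rule(due("V1"), w, sc, rt)
  expect_identical(s1$targets, "V6")
  w <- apply_effects(s1, sc$schemas$shoot, w)
  s2 <- shooting_retarget_rule(due("V2"), w, sc, rt)
  expect_identical(s2$schema, "shoot_participant")
  expect_identical(s2$targets, "P")
  w <- apply_effects(s2, sc$schemas$shoot_participant, w)
  expect_null(shooting_retarget_rule(due("V3"), w, sc, rt))

  # gunman sealed between floors: no candidates at all
  w2 <- world_set(w, "G", "location", "elevator")
  w2 <- world_set(w2, "elevator", "position", "between")
  expect_null(shooting_retarget_rule(due("V3"), w2, sc, new.env()))
})

test_that("clones become retarget candidates only when clone_targetable is set", {
  sc <- gallery_sc()
  ctx <- travel_back(canonical_round1())
  w <- ctx$initial_world
  w <- world_set(w, "G", "location", "ground")
  w <- world_set(w, "V6", "alive", FALSE)       # ground visitor already dead
  w <- world_set(w, "V6", "location", "ground")
  rt <- new.env(); rt$used_targets <- "P"        # participant already used
  due <- new_action("shoot", "G", 40, targets = "V1",
                    params = list(floor = "upper"), round = 2L, status = "replayed")
  expect_null(shooting_retarget_rule(due, w, sc, rt))

  sc2 <- sc
  sc2$config$engine$clone_targetable <- TRUE
  rt2 <- new.env(); rt2$used_targets <- "P"
  sub <- shooting_retarget_rule(due, w, sc2, rt2)
  expect_identical(sub$targets, "P1")
})

test_that("the enter-floor correction exits people at the elevator's current floor", {
  sc <- gallery_sc()
  w <- chronoreplay:::scenario_initial_world(sc)
  w <- world_set(w, "G", "location", "elevator")
  due <- new_action("exit_elevator", "G", 42, params = list(floor = "upper"),
                    round = 2L, status = "replayed")

  # stationary (here: frozen) at the ground floor: exit corrected to ground
  wf <- press_alarm(w)
  sub <- enter_floor_correction(due, wf, sc)
  expect_identical(sub$params$floor, "ground")
  expect_identical(sub$status, "retargeted")

  # between floors: no exit possible
  wb <- world_set(wf, "elevator", "position", "between")
  expect_null(enter_floor_correction(due, wb, sc))

  # person not aboard at the recorded time: omitted
  wo <- world_set(wf, "G", "location", "ground")
  expect_null(enter_floor_correction(due, wo, sc))
})

test_that("the elevator starts after the command delay, rides, arrives, and freezes in place", {
  sc <- gallery_sc()
  cfg <- sc$config
  w <- chronoreplay:::scenario_initial_world(sc)
  rt <- new.env()

  # press up at t=0: nothing before the command delay elapses
  w <- apply_effects(new_action("push_up", "P", 0), sc$schemas$push_up, w)
  rt$pending_since <- 0
  expect_identical(world_get(w, "elevator", "pending"), "up")
  expect_length(simulate_elevator(w, rt, 0.1, cfg), 0L)
  fire <- simulate_elevator(w, rt, cfg$timing$command_delay, cfg)
  expect_identical(fire, "start_moving_up")
  w <- apply_effects(new_action("start_moving_up", "elevator", 0.5),
                     sc$schemas$start_moving_up, w)
  rt$arrive_at <- cfg$timing$command_delay + cfg$timing$travel_duration
  expect_identical(world_get(w, "elevator", "position"), "between")

  # mid-ride nothing fires; at the scheduled time the elevator arrives
  expect_length(simulate_elevator(w, rt, 2.0, cfg), 0L)
  expect_identical(simulate_elevator(w, rt, rt$arrive_at, cfg), "arrive_upper")

  # freezing mid-ride: stationary between floors, ride cancelled
  wfz <- press_alarm(w)
  expect_identical(world_get(wfz, "elevator", "position"), "between")
  expect_identical(world_get(wfz, "elevator", "motion"), "stationary")
  expect_true(world_get(wfz, "elevator", "frozen"))
  expect_length(simulate_elevator(wfz, rt, rt$arrive_at, cfg), 0L)

  # call buttons are inert while frozen (exhaustive over both directions)
  for (schema in c("push_up", "push_down")) {
    w2 <- apply_effects(new_action(schema, "P", 3), sc$schemas[[schema]], wfz)
    expect_identical(w2, wfz)
  }
  # unfreezing does not resume the cancelled ride without a new command
  wun <- press_alarm(wfz)
  expect_identical(world_get(wun, "elevator", "pending"), "none")
  expect_length(simulate_elevator(wun, new.env(), 10, cfg), 0L)
})

test_that("alarm presses preserve actions, not outcomes: the clone's press flips it off", {
  ses <- worked_ses()
  h2 <- ses$histories[[2L]]
  d <- tibble::as_tibble(h2)
  presses <- d[d$action == "push_alarm" & d$status != "omitted", ]
  expect_identical(nrow(presses), 2L)
  expect_identical(presses$status, c("injected", "replayed"))
  # after the injected press the alarm is on; after the clone's replayed
  # recorded press it is off again
  expect_true(world_get(state_at(h2, presses$t[[1L]]), "alarm", "on"))
  expect_false(world_get(state_at(h2, presses$t[[2L]]), "alarm", "on"))
})

test_that("trials terminate by the post-shooting window or by the trap window", {
  sc <- gallery_sc()
  h1 <- canonical_round1()
  d <- tibble::as_tibble(h1)
  last_shot <- max(d$t[d$action == "shoot" & d$status != "omitted"])
  win <- sc$config$timing$termination_window
  expect_false(check_termination(h1, last_shot + win - 0.1, sc))
  expect_true(check_termination(h1, last_shot + win, sc))
  expect_identical(h1$end_time, vt_quantize(last_shot + win))

  # shooting still possible: a living visitor on the gunman's level blocks it
  h_blocked <- h1
  h_blocked$actions <- Filter(function(a) {
    !(a$schema == "shoot" && identical(a$targets, "V5"))
  }, h1$actions)
  expect_false(check_termination(h_blocked, last_shot + win, sc))

  # the trap clause: gunman boxed between floors for the full window
  ses <- cached("trap_session",
                run_loop(gallery_sc(),
                         list("comply_then_alarm", "trap_gunman", "do_nothing"),
                         n_rounds = 3L))
  h2 <- ses$histories[[2L]]
  d2 <- tibble::as_tibble(h2)
  trap_t <- d2$t[d2$status == "injected" & d2$action == "push_alarm"]
  expect_false(check_termination(h2, trap_t + win - 0.1, sc))
  expect_true(check_termination(h2, trap_t + win, sc))
  expect_identical(h2$end_time, vt_quantize(trap_t + win))
  wend <- state_at(h2, h2$end_time)
  expect_identical(world_get(wend, "G", "location"), "elevator")
  expect_identical(world_get(wend, "elevator", "position"), "between")
})

test_that("count_shot tallies visitor targets and flags the participant separately", {
  expect_identical(count_shot(canonical_round1()),
                   tibble::tibble(visitors_shot = 5L, participant_shot = FALSE))
  ses <- worked_ses()
  expect_identical(count_shot(ses$histories[[2L]]),
                   tibble::tibble(visitors_shot = 1L, participant_shot = TRUE))
  trap <- cached("trap_session",
                 run_loop(gallery_sc(),
                          list("comply_then_alarm", "trap_gunman", "do_nothing"),
                          n_rounds = 3L))
  expect_identical(count_shot(trap$histories[[2L]])$visitors_shot, 0L)
})

test_that("exhaustive single-press enumeration yields exactly the three outcome classes", {
  enum <- alarm_enum()
  classes <- sort(unique(enum$class))
  expect_identical(length(classes), 3L)

  sc <- gallery_sc()
  up_t <- script_time(sc, "G", "enter_elevator") + sc$config$timing$service_wait
  start_t <- up_t + sc$config$timing$command_delay
  arrive_t <- start_t + sc$config$timing$travel_duration
  early <- enum[enum$press_t <= start_t + 1e-9, ]
  mid <- enum[enum$press_t > start_t + 1e-9 & enum$press_t <= arrive_t + 1e-9, ]
  late <- enum[enum$press_t > arrive_t + 1e-9, ]

  # pressing before the ride: the gunman exits at the ground floor and shoots
  # the remaining visitor and the participant
  expect_true(all(early$visitors_shot == 1L & early$participant_shot & !early$gunman_trapped))
  # pressing strictly during the ride: trapped, nobody shot
  expect_true(all(mid$visitors_shot == 0L & !mid$participant_shot & mid$gunman_trapped))
  expect_gt(nrow(mid), 0L)
  # pressing after arrival, or never: the original tragedy replays
  expect_true(all(late$visitors_shot == 5L & !late$participant_shot & !late$gunman_trapped))
  expect_true(is.infinite(max(late$press_t)))

  # scenario invariants over every enumerated strategy
  expect_true(all(enum$visitors_shot[enum$gunman_trapped] == 0L))
  ground_gunman <- enum$visitors_shot[enum$press_t <= start_t + 1e-9]
  expect_true(all(ground_gunman >= 1L))
})
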