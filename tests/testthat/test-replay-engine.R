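test_that("travel_back re-attributes the participant to a fresh clone and queues agent actions", {
  h1 <- canonical_round1()
  ctx <- travel_back(h1)
  expect_identical(ctx$clone_map, c("1" = "P1"))
  expect_identical(ctx$round, 2L)
  # the clone entity exists, is an agent, and starts as the participant did
  expect_identical(ctx$initial_world[["P1"]]$class, "agent")
  expect_identical(ctx$initial_world[["P1"]]$vars, h1$initial_world[["P"]]$vars)

  actors <- vapply(ctx$queue, function(a) a$actor, character(1))
  # the live participant owns nothing in the queue; P1 owns exactly P's actions
  expect_false("P" %in% actors)
  expect_identical(sum(actors == "P1"),
                   sum(vapply(h1$actions, function(a) a$actor == "P", logical(1))))
  # physical-object actions are never queued: they are re-simulated
  expect_false(any(actors == "elevator"))
  # omitted actions are not part of the frame of reference
  expect_false(any(vapply(ctx$queue, function(a) a$status == "omitted", logical(1))))
  # queue is ordered by start time
  ts <- vapply(ctx$queue, function(a) a$t, numeric(1))
  expect_true(all(diff(ts) >= -1e-9))

  expect_error(travel_back(h1, destination = h1$end_time + 5), "outside")
})

test_that("a replay with zero injections reproduces the source action-for-action", {
  sc <- gallery_sc()
  h1 <- canonical_round1()
  h2 <- replay_round(sc, travel_back(h1), "do_nothing")
  a1 <- tibble::as_tibble(h1)
  a2 <- tibble::as_tibble(h2)
  expect_identical(nrow(a1), nrow(a2))
  expect_identical(a1$t, a2$t)
  expect_identical(a1$action, a2$action)
  expect_identical(a1$targets, a2$targets)
  # actors agree modulo the clone re-attribution
  expect_identical(ifelse(a1$actor == "P", "P1", a1$actor), a2$actor)
  # agent/participant actions carry status replayed; physical stay scripted
  expect_true(all(a2$status[a2$actor != "elevator"] == "replayed"))
  expect_true(all(a2$status[a2$actor == "elevator"] == "scripted"))
  expect_identical(count_shot(h2), count_shot(h1))
})

test_that("injected actions always execute, are unique, and precede due actions at the same tick", {
  ses <- worked_ses()
  h2 <- ses$histories[[2L]]
  d <- tibble::as_tibble(h2)
  inj <- d[d$status == "injected", ]
  expect_identical(nrow(inj), 1L)
  expect_identical(inj$action, "push_alarm")
  expect_identical(inj$actor, "P")

  # inject at the exact tick of the clone's due up-press: the injection runs
  # first, freezing the elevator at the ground floor before the command can
  # take effect -- same outcome class as pressing one tick later
  sc <- gallery_sc()
  up_t <- script_time(sc, "G", "enter_elevator") + sc$config$timing$service_wait
  pol <- make_policy("scripted", actions = tibble::tibble(t = up_t, action = "push_alarm"))
  h <- replay_round(sc, travel_back(canonical_round1()), pol)
  dd <- tibble::as_tibble(h)
  at_tick <- dd[vt_eq(dd$t, up_t), ]
  expect_identical(at_tick$status[at_tick$actor == "P"], "injected")
  expect_lt(which(at_tick$actor == "P"), which(at_tick$actor == "P1"))
  cs <- count_shot(h)
  expect_identical(cs$visitors_shot, 1L)
  expect_true(cs$participant_shot)
})

test_that("only the live participant's controls can be injected", {
  sc <- gallery_sc()
  shoot_policy <- make_policy("scripted",
                              actions = tibble::tibble(t = 1, action = "shoot",
                                                       target = "V1"))
  expect_error(record_round(sc, shoot_policy), "free-will")
  expect_error(record_round(sc, "press_everything"), "unknown policy")
})

test_that("attempt_replacement substitutes per the rules or omits", {
  sc <- gallery_sc()
  w <- chronoreplay:::scenario_initial_world(sc)
  w <- world_set(w, "G", "location", "ground")
  w <- world_set(w, "V6", "location", "ground")
  w <- world_set(w, "V1", "location", "upper")
  due <- new_action("shoot", "G", 40, targets = "V1",
                    params = list(floor = "upper"), round = 2L, status = "replayed")

  res <- attempt_replacement(due, w, sc$rules, sc)
  expect_identical(res$status, "retargeted")
  expect_identical(res$action$targets, "V6")
  expect_identical(res$action$original_targets, "V1")
  expect_identical(res$action$params$floor, "ground")

  # no candidates (gunman sealed between floors): omission
  w2 <- world_set(w, "G", "location", "elevator")
  w2 <- world_set(w2, "elevator", "position", "between")
  expect_identical(attempt_replacement(due, w2, sc$rules, sc)$status, "omitted")

  # an action with no matching rule is omitted outright
  enter <- new_action("enter_gallery", "V1", 1, round = 2L, status = "replayed")
  expect_identical(attempt_replacement(enter, w, sc$rules, sc)$status, "omitted")

  # a rule producing an invalid substitution is an engine invariant error
  bad_rule <- new_replacement_rule("bad", "shoot", function(action, world, scenario, runtime) {
    new_action("shoot", action$actor, action$t, targets = "V1",
               params = list(floor = "upper"), round = action$round)
  })
  expect_error(attempt_replacement(due, w, list(bad_rule), sc),
               "preconditions fail")
})

test_that("run_loop chains travels; one round equals record_round in both modes", {
  sc <- gallery_sc()
  for (mode in c("time_travel", "repetition")) {
    s1 <- run_loop(sc, "comply_then_alarm", n_rounds = 1L, mode = mode)
    expect_identical(tibble::as_tibble(s1$histories[[1L]]),
                     tibble::as_tibble(canonical_round1()))
  }
})

test_that("successive travels accumulate clones: 0, 1, 2 across three rounds", {
  ses <- cached("trap_session",
                run_loop(gallery_sc(),
                         list("comply_then_alarm", "trap_gunman", "do_nothing"),
                         n_rounds = 3L))
  expect_identical(vapply(ses$histories, function(h) length(h$clone_map), integer(1)),
                   c(0L, 1L, 2L))
  d3 <- tibble::as_tibble(ses$histories[[3L]])
  expect_true(all(c("P1", "P2") %in% d3$actor))
})

test_that("after a trapped round, an idle third round replays it unchanged with zero shootings", {
  ses <- cached("trap_session",
                run_loop(gallery_sc(),
                         list("comply_then_alarm", "trap_gunman", "do_nothing"),
                         n_rounds = 3L))
  h2 <- ses$histories[[2L]]
  h3 <- ses$histories[[3L]]
  expect_identical(count_shot(h2)$visitors_shot, 0L)
  expect_identical(count_shot(h3)$visitors_shot, 0L)
  # the non-omitted actions of round 2 reappear action-for-action in round 3
  keep2 <- tibble::as_tibble(h2) |> dplyr::filter(status != "omitted")
  got3 <- tibble::as_tibble(h3) |> dplyr::filter(status != "omitted")
  expect_identical(keep2$t, got3$t)
  expect_identical(keep2$action, got3$action)
  expect_identical(ifelse(keep2$actor == "P", "P2", keep2$actor), got3$actor)
  expect_identical(h2$end_time, h3$end_time)
})

test_that("the queue derives solely from the latest history (frame of reference)", {
  ses <- cached("trap_session",
                run_loop(gallery_sc(),
                         list("comply_then_alarm", "trap_gunman", "do_nothing"),
                         n_rounds = 3L))
  ctx <- travel_back(ses$histories[[2L]])
  # round 2's omitted shootings are gone from the frame of reference: no
  # shoot attempt survives into the round-3 queue
  expect_false(any(vapply(ctx$queue, function(a) a$schema == "shoot", logical(1))))
  # but round 2's injected trap press is queued, re-attributed to P2
  presses <- Filter(function(a) a$schema == "push_alarm" && a$actor == "P2", ctx$queue)
  expect_identical(length(presses), 1L)
})

test_that("an injected action is re-attributed to the new clone after the next travel", {
  ses <- worked_ses()
  ctx <- travel_back(ses$histories[[2L]])
  inj_t <- tibble::as_tibble(ses$histories[[2L]]) |>
    dplyr::filter(status == "injected") |> dplyr::pull(t)
  q <- Filter(function(a) vt_eq(a$t, inj_t) && a$schema == "push_alarm", ctx$queue)
  expect_identical(vapply(q, function(a) a$actor, character(1)), "P2")
})

test_that("identical scenario, policies and seeds give byte-identical event logs", {
  sc <- build_gallery()
  pols <- list("comply_then_alarm",
               make_policy("trap_gunman", params = list(delay_range = c(0, 4)), seed = 11L),
               "do_nothing")
  f1 <- tempfile(fileext = ".jsonl")
  f2 <- tempfile(fileext = ".jsonl")
  write_event_log(run_loop(sc, pols, n_rounds = 3L), f1)
  write_event_log(run_loop(sc, pols, n_rounds = 3L), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("travel to an arbitrary mid-round destination preserves the immutable prefix", {
  sc <- gallery_sc()
  h1 <- canonical_round1()
  dest <- script_time(sc, "G", "enter_elevator") + 1.0
  ctx <- travel_back(h1, destination = dest)
  expect_identical(ctx$destination, dest)
  # queued actions all start at or after the destination
  expect_true(all(vapply(ctx$queue, function(a) a$t, numeric(1)) >= dest - 1e-9))
  h2 <- replay_round(sc, ctx, worked_example_policy(sc))
  d1 <- tibble::as_tibble(h1)
  d2 <- tibble::as_tibble(h2)
  pre1 <- d1[d1$t < dest - 1e-9, ]
  pre2 <- d2[d2$t < dest - 1e-9, ]
  expect_identical(pre1$t, pre2$t)
  expect_identical(pre1$action, pre2$action)
  expect_identical(ifelse(pre1$actor == "P", "P1", pre1$actor), pre2$actor)
  # the worked-example intervention still lands after the destination
  expect_identical(count_shot(h2)$visitors_shot, 1L)
  expect_identical(nrow(validate_history(h2)), 0L)
})
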