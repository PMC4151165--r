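# shared fixtures, computed once per test run
.tt_cache <- new.env()
cached <- function(name, expr) {
  if (!exists(name, envir = .tt_cache)) assign(name, expr, envir = .tt_cache)
  get(name, envir = .tt_cache)
}

gallery_sc <- function() cached("sc", build_gallery())
canonical_round1 <- function() {
  cached("h1", record_round(gallery_sc(), "comply_then_alarm"))
}
worked_ses <- function() cached("wes", {
  sc <- gallery_sc()
  run_loop(sc, list(make_policy("comply_then_alarm"), worked_example_policy(sc)),
           n_rounds = 2L)
})
alarm_enum <- function() {
  cached("enum", enumerate_alarm_strategies(gallery_sc(), round1 = canonical_round1()))
}

script_time <- function(sc, actor, schema) {
  hits <- Filter(function(sp) sp$actor == actor && sp$schema == schema, sc$script)
  vapply(hits, function(sp) sp$t, numeric(1))
}

# the alarm is a toggle: an independent closed-form oracle for its state
alarm_oracle <- function(history, t) {
  presses <- Filter(function(a) {
    a$schema == "push_alarm" && a$status != "omitted" && a$t <= t + 1e-9
  }, history$actions)
  (length(presses) %% 2L) == 1L
}

# the invariant coupling the alarm to the elevator brake, checked along the
# whole state trajectory of a history
alarm_freeze_coupled <- function(history) {
  w <- history$initial_world
  ok <- identical(world_get(w, "alarm", "on"), world_get(w, "elevator", "frozen"))
  for (a in history$actions) {
    if (a$status != "omitted") {
      w <- apply_effects(a, history$schemas[[a$schema]], w)
    }
    ok <- ok && identical(world_get(w, "alarm", "on"),
                          world_get(w, "elevator", "frozen"))
    if (!ok) break
  }
  ok
}

# count shoot-family records (every one traces back to a recorded shooting
# attempt), split by outcome
shot_attempt_counts <- function(history) {
  d <- tibble::as_tibble(history)
  d <- d[d$action %in% c("shoot", "shoot_participant"), ]
  list(executed = sum(d$status != "omitted"), omitted = sum(d$status == "omitted"),
       total = nrow(d))
}

# ---- a tiny static-effect toy domain for core-machinery properties ----------

toy_schemas <- function() {
  s <- list(
    new_schema("open_door", "agent",
               preconds = list(predicate("door", "state", "closed"),
                               predicate("actor", "alive", TRUE)),
               effects = list(eff("door", "state", "open"))),
    new_schema("close_door", "agent",
               preconds = list(predicate("door", "state", "open"),
                               predicate("actor", "alive", TRUE)),
               effects = list(eff("door", "state", "closed"))),
    new_schema("move", "agent",
               preconds = list(predicate("actor", "at", param_ref("from"))),
               effects = list(eff("actor", "at", param_ref("to"))),
               params = c("from", "to")),
    new_schema("wave", "agent",
               preconds = list(predicate("actor", "alive", TRUE)),
               utterance = TRUE)
  )
  stats::setNames(s, vapply(s, function(x) x$name, character(1)))
}

toy_world <- function() {
  new_world(list(
    new_entity("door", "physical", list(state = "closed")),
    new_entity("R1", "agent", list(at = "a", alive = TRUE)),
    new_entity("R2", "agent", list(at = "b", alive = TRUE))
  ))
}

# generates a legal random action sequence by only ever picking actions whose
# preconditions hold in the evolving state
random_toy_history <- function(seed, n = 12L) {
  set.seed(seed)
  sch <- toy_schemas()
  w <- toy_world()
  h <- new_history(1L, w, sch)
  t <- 0
  places <- c("a", "b", "c")
  for (i in seq_len(n)) {
    cands <- list()
    for (actor in c("R1", "R2")) {
      at <- world_get(w, actor, "at")
      for (to in setdiff(places, at)) {
        cands[[length(cands) + 1L]] <- list(schema = "move", actor = actor,
                                            params = list(from = at, to = to))
      }
      cands[[length(cands) + 1L]] <- list(schema = "wave", actor = actor,
                                          params = list())
    }
    door <- world_get(w, "door", "state")
    cands[[length(cands) + 1L]] <- list(
      schema = if (door == "closed") "open_door" else "close_door",
      actor = "R1", params = list())
    pick <- cands[[sample.int(length(cands), 1L)]]
    t <- vt_quantize(t + sample(1:3, 1L) * 0.1)
    a <- new_action(pick$schema, pick$actor, t, params = pick$params)
    stopifnot(evaluate_preconditions(a, sch[[a$schema]], w))
    w <- apply_effects(a, sch[[a$schema]], w)
    h <- append_action(h, a)
  }
  h
}

# brute-force refold written against the raw template structure, independent
# of state_at()/apply_effects() (static effects only: the toy domain)
oracle_refold <- function(history, t) {
  w <- history$initial_world
  for (a in history$actions) {
    if (a$t > t + 1e-9) break
    if (a$status == "omitted") next
    s <- history$schemas[[a$schema]]
    for (e in s$effects) {
      id <- switch(e$entity, actor = a$actor, target = a$targets[[1L]], e$entity)
      v <- if (inherits(e$value, "tt_param_ref")) a$params[[e$value$name]] else e$value
      w[[id]]$vars[[e$variable]] <- v
    }
  }
  w
}
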