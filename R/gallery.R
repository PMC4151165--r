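#' Default gallery scenario configuration
#'
#' The two-level art-gallery instance: a participant operating an elevator
#' from a ground-floor workbench, six visitors, a gunman, and an alarm that
#' freezes the elevator in place. Timing constants (seconds) are design
#' defaults, all config-overridable:
#' \describe{
#'   \item{tick}{0.1 -- virtual time grid.}
#'   \item{travel_duration}{5.0 -- elevator ride between floors.}
#'   \item{command_delay}{0.5 -- from button press to start of motion (this
#'     window is what lets an alarm press pre-empt a commanded ride).}
#'   \item{shot_interval}{0.5 -- between successive shootings.}
#'   \item{arrival_to_shooting}{0.5 -- from the gunman's floor entry to his
#'     first shot.}
#'   \item{exit_stagger}{0.5 -- between successive elevator exits.}
#'   \item{board_interval}{0.5 -- between successive boardings.}
#'   \item{service_wait}{1.0 -- how long a compliant operator waits after the
#'     last boarding before sending the elevator.}
#'   \item{alarm_delay}{1.0 -- compliant operator's reaction time from first
#'     shot to alarm press.}
#'   \item{termination_window}{7.0 -- a trial ends 7 s after the last
#'     shooting with no further shooting possible, or once the gunman has
#'     been trapped in the elevator for 7 s.}
#'   \item{round_timeout}{60.0 -- hard stop for degenerate rounds in which
#'     neither termination condition can ever fire.}
#' }
#'
#' @return a named configuration list accepted by [build_gallery()].
#' @export
gallery_config <- function() {
  list(
    name = "gallery",
    tick = 0.1,
    n_visitors = 6L,
    timing = list(
      travel_duration = 5.0, command_delay = 0.5, shot_interval = 0.5,
      arrival_to_shooting = 0.5, exit_stagger = 0.5, board_interval = 0.5,
      service_wait = 1.0, alarm_delay = 1.0,
      termination_window = 7.0, round_timeout = 60.0
    ),
    engine = list(
      clone_targetable = FALSE,
      tie_break = c("participant", "agent", "physical"),
      seed = 1L
    )
  )
}

gallery_floors <- c("ground", "upper")

# the round-1 predetermined script, derived from the timing constants so the
# scripted visitor choreography is exactly consistent with the elevator
# physics under a compliant operator
gallery_script <- function(cfg) {
  tm <- cfg$timing
  tick <- cfg$tick
  sp <- list()
  add <- function(t, actor, schema, targets = character(), params = list()) {
    sp[[length(sp) + 1L]] <<- list(t = vt_quantize(t, tick), actor = actor,
                                   schema = schema, targets = targets,
                                   params = params)
  }
  ride <- tm$command_delay + tm$travel_duration

  # batch 1: V1..V3 enter, request, board; the operator sends them up
  add(1.0, "V1", "enter_gallery"); add(1.5, "V2", "enter_gallery")
  add(2.0, "V3", "enter_gallery")
  add(2.5, "V1", "request_up"); add(2.6, "V2", "request_up")
  add(2.7, "V3", "request_up")
  b1 <- 3.0 + tm$board_interval * (0:2)
  for (i in 1:3) add(b1[i], paste0("V", i), "enter_elevator",
                     params = list(floor = "ground"))
  up1 <- max(b1) + tm$service_wait
  arrive1 <- up1 + ride
  ex1 <- arrive1 + tm$exit_stagger * (1:3)
  for (i in 1:3) add(ex1[i], paste0("V", i), "exit_elevator",
                     params = list(floor = "upper"))
  down1 <- max(ex1) + tm$service_wait
  arrive_g1 <- down1 + ride

  # batch 2: V4, V5 arrive during the first ride and wait
  add(5.0, "V4", "enter_gallery"); add(5.5, "V5", "enter_gallery")
  add(6.0, "V4", "request_up"); add(6.1, "V5", "request_up")
  b2 <- vt_ceil(arrive_g1 + tick, 0.5) + tm$board_interval * (0:1)
  for (i in 1:2) add(b2[i], paste0("V", i + 3L), "enter_elevator",
                     params = list(floor = "ground"))
  up2 <- max(b2) + tm$service_wait
  arrive2 <- up2 + ride
  ex2 <- arrive2 + tm$exit_stagger * (1:2)
  for (i in 1:2) add(ex2[i], paste0("V", i + 3L), "exit_elevator",
                     params = list(floor = "upper"))
  down2 <- max(ex2) + tm$service_wait
  arrive_g2 <- down2 + ride

  # V6 browses the ground floor and asks the participant for the time
  add(7.0, "V6", "enter_gallery")
  add(8.0, "V6", "ask_time", targets = "P")

  # the gunman: enters, asks to be taken up, rides, exits, shoots V1..V5
  gE <- vt_ceil(arrive_g2 + tick, 0.5)
  add(gE, "G", "enter_gallery")
  add(gE + 0.5, "G", "request_up")
  add(gE + 1.0, "G", "enter_elevator", params = list(floor = "ground"))
  upG <- gE + 1.0 + tm$service_wait
  arriveG <- upG + ride
  exG <- arriveG + tm$exit_stagger
  add(exG, "G", "exit_elevator", params = list(floor = "upper"))
  t0 <- exG + tm$arrival_to_shooting
  for (i in 1:5) add(t0 + tm$shot_interval * (i - 1L), "G", "shoot",
                     targets = paste0("V", i), params = list(floor = "upper"))

  sp[order(map_dbl(sp, "t"))]
}

gallery_entities <- function(cfg) {
  vis <- map(seq_len(cfg$n_visitors), function(i) {
    new_entity(paste0("V", i), "agent", list(location = "outside", alive = TRUE))
  })
  c(list(new_entity("P", "participant",
                    list(location = "ground", alive = TRUE, hit = FALSE))),
    vis,
    list(
      new_entity("G", "agent", list(location = "outside", alive = TRUE)),
      new_entity("elevator", "physical",
                 list(position = "ground", motion = "stationary",
                      frozen = FALSE, pending = "none")),
      new_entity("alarm", "physical", list(on = FALSE))
    ))
}

# alarm toggle: pressing preserves the ACTION; the outcome depends on the
# current state. Switching on freezes the elevator in place (cancelling any
# pending command and any motion, position stays where it is -- possibly
# between floors); switching off unfreezes but does not resume motion.
alarm_toggle <- function(world, action) {
  on <- world_get(world, "alarm", "on")
  if (!on) {
    world <- world_set(world, "alarm", "on", TRUE)
    world <- world_set(world, "elevator", "frozen", TRUE)
    world <- world_set(world, "elevator", "motion", "stationary")
    world <- world_set(world, "elevator", "pending", "none")
  } else {
    world <- world_set(world, "alarm", "on", FALSE)
    world <- world_set(world, "elevator", "frozen", FALSE)
  }
  world
}

# elevator call buttons only take effect while the elevator is free and
# stationary; presses while frozen or moving are recorded but inert
call_button <- function(direction) {
  function(world, action) {
    if (!world_get(world, "elevator", "frozen") &&
        identical(world_get(world, "elevator", "motion"), "stationary")) {
      world <- world_set(world, "elevator", "pending", direction)
    }
    world
  }
}

gallery_schemas <- function(cfg) {
  alive <- function(slot) predicate(slot, "alive", TRUE)
  at <- function(slot, where) predicate(slot, "location", where)
  fl <- param_ref("floor")
  s <- list(
    new_schema("enter_gallery", "agent",
               preconds = list(alive("actor"), at("actor", "outside")),
               effects = list(eff("actor", "location", "ground"))),
    new_schema("request_up", "agent", preconds = list(alive("actor")),
               utterance = TRUE),
    new_schema("ask_time", "agent", preconds = list(alive("actor")),
               utterance = TRUE),
    new_schema("enter_elevator", "agent",
               preconds = list(alive("actor"), at("actor", fl),
                               predicate("elevator", "position", fl),
                               predicate("elevator", "motion", "stationary")),
               effects = list(eff("actor", "location", "elevator")),
               params = "floor"),
    new_schema("exit_elevator", "agent",
               preconds = list(alive("actor"), at("actor", "elevator"),
                               predicate("elevator", "position", fl),
                               predicate("elevator", "motion", "stationary")),
               effects = list(eff("actor", "location", fl)),
               params = "floor", replaceable = "enter_floor_correction"),
    new_schema("push_up", "participant", effect_fn = call_button("up"),
               control = TRUE),
    new_schema("push_down", "participant", effect_fn = call_button("down"),
               control = TRUE),
    new_schema("push_alarm", "participant", effect_fn = alarm_toggle,
               control = TRUE),
    new_schema("shoot", "agent",
               preconds = list(alive("actor"), at("actor", fl),
                               alive("target"), at("target", fl)),
               effects = list(eff("target", "alive", FALSE)),
               params = "floor", replaceable = "shooting_retarget"),
    new_schema("shoot_participant", "agent",
               preconds = list(alive("actor"), at("actor", fl),
                               at("target", fl)),
               effects = list(eff("target", "hit", TRUE)),
               params = "floor"),
    new_schema("start_moving_up", "physical",
               preconds = list(predicate("elevator", "position", "ground"),
                               predicate("elevator", "motion", "stationary"),
                               predicate("elevator", "frozen", FALSE),
                               predicate("elevator", "pending", "up")),
               effects = list(eff("elevator", "motion", "moving_up"),
                              eff("elevator", "position", "between"),
                              eff("elevator", "pending", "none"))),
    new_schema("start_moving_down", "physical",
               preconds = list(predicate("elevator", "position", "upper"),
                               predicate("elevator", "motion", "stationary"),
                               predicate("elevator", "frozen", FALSE),
                               predicate("elevator", "pending", "down")),
               effects = list(eff("elevator", "motion", "moving_down"),
                              eff("elevator", "position", "between"),
                              eff("elevator", "pending", "none"))),
    new_schema("arrive_upper", "physical",
               preconds = list(predicate("elevator", "motion", "moving_up")),
               effects = list(eff("elevator", "position", "upper"),
                              eff("elevator", "motion", "stationary"))),
    new_schema("arrive_ground", "physical",
               preconds = list(predicate("elevator", "motion", "moving_down")),
               effects = list(eff("elevator", "position", "ground"),
                              eff("elevator", "motion", "stationary")))
  )
  setNames(s, map_chr(s, "name"))
}

#' The floor an entity is effectively on
#'
#' A person inside the elevator counts as co-located with a floor when the
#' elevator is stationary at that floor (frozen or not); between floors they
#' are on no floor. Used for retargeting and termination.
#'
#' @param world a [new_world()].
#' @param id entity id.
#' @return `"ground"`, `"upper"`, or `NA_character_`.
#' @export
effective_floor <- function(world, id) {
  loc <- world_get(world, id, "location")
  if (loc %in% gallery_floors) return(loc)
  if (identical(loc, "elevator")) {
    pos <- world_get(world, "elevator", "position")
    if (pos %in% gallery_floors &&
        identical(world_get(world, "elevator", "motion"), "stationary")) {
      return(pos)
    }
  }
  NA_character_
}

#' Scenario-specific replacement rules
#'
#' `shooting_retarget_rule()`: when a recorded shooting's preconditions fail
#' (the gunman is no longer where the victim was), the engine tries to match
#' a new target: living visitors co-located with the gunman, in ascending id
#' order, then the live participant; clones are excluded unless the
#' `clone_targetable` engine flag is set. Each candidate is used for at most
#' one original attempt; exhausted candidates mean omission.
#'
#' `enter_floor_correction()`: when a recorded elevator exit fails, the
#' person exits at the floor the elevator is *currently* stationary at,
#' regardless of whether it is the same floor as before; if the elevator is
#' between floors (or the person is not aboard) the exit is omitted.
#'
#' @param action the failed [new_action()].
#' @param world current [new_world()].
#' @param scenario the gallery scenario.
#' @param runtime engine runtime environment (tracks used retarget
#'   candidates per round).
#' @return a substitute [new_action()], or `NULL` for omission.
#' @export
shooting_retarget_rule <- function(action, world, scenario, runtime = new.env()) {
  g <- action$actor
  fl <- effective_floor(world, g)
  if (is.na(fl)) return(NULL)
  used <- runtime$used_targets %||% character()
  pid <- scenario$participant_id
  clones <- setdiff(world_ids(world, "agent"), c(scenario$visitor_ids, scenario$gunman_id))

  vis <- scenario$visitor_ids
  vis <- vis[order(vis)]
  cand <- keep(vis, function(v) {
    !(v %in% used) && world_get(world, v, "alive") &&
      identical(world_get(world, v, "location"), fl)
  })
  if (length(cand)) {
    runtime$used_targets <- c(used, cand[[1L]])
    return(new_action("shoot", g, action$t, targets = cand[[1L]],
                      params = list(floor = fl), round = action$round,
                      status = "retargeted"))
  }
  if (!(pid %in% used) && identical(world_get(world, pid, "location"), fl)) {
    runtime$used_targets <- c(used, pid)
    return(new_action("shoot_participant", g, action$t, targets = pid,
                      params = list(floor = fl), round = action$round,
                      status = "retargeted"))
  }
  if (isTRUE(scenario$config$engine$clone_targetable)) {
    cc <- keep(sort(clones), function(x) {
      !(x %in% used) && identical(world_get(world, x, "location"), fl)
    })
    if (length(cc)) {
      runtime$used_targets <- c(used, cc[[1L]])
      return(new_action("shoot_participant", g, action$t, targets = cc[[1L]],
                        params = list(floor = fl), round = action$round,
                        status = "retargeted"))
    }
  }
  NULL
}

#' @rdname shooting_retarget_rule
#' @export
enter_floor_correction <- function(action, world, scenario, runtime = new.env()) {
  who <- action$actor
  if (!identical(world_get(world, who, "location"), "elevator")) return(NULL)
  if (!identical(world_get(world, "elevator", "motion"), "stationary")) return(NULL)
  pos <- world_get(world, "elevator", "position")
  if (!pos %in% gallery_floors) return(NULL)
  new_action("exit_elevator", who, action$t, params = list(floor = pos),
             round = action$round, status = "retargeted")
}

#' One tick of deterministic elevator simulation
#'
#' The elevator is a physical object: it is re-simulated every round
#' regardless of what it did before. A pending call command on a free,
#' stationary elevator starts motion `command_delay` seconds after the
#' press; `travel_duration` seconds of motion later the elevator arrives.
#' Switching the alarm on freezes it instantaneously wherever it is.
#'
#' @param world current [new_world()].
#' @param runtime engine runtime environment carrying `pending_since` (time
#'   of the effective call press) and `arrive_at` (scheduled arrival).
#' @param t current virtual time.
#' @param config scenario configuration (see [gallery_config()]).
#' @return character vector of physical transition schema names due now
#'   (in firing order: arrivals before starts); the engine executes them.
#' @export
simulate_elevator <- function(world, runtime, t, config) {
  tm <- config$timing
  tick <- config$tick
  fire <- character()
  motion <- world_get(world, "elevator", "motion")
  if (motion %in% c("moving_up", "moving_down") &&
      !is.null(runtime$arrive_at) && t >= runtime$arrive_at - tick / 2) {
    fire <- c(fire, if (motion == "moving_up") "arrive_upper" else "arrive_ground")
    return(fire)
  }
  pending <- world_get(world, "elevator", "pending")
  if (identical(motion, "stationary") &&
      !world_get(world, "elevator", "frozen") &&
      pending %in% c("up", "down") &&
      !is.null(runtime$pending_since) &&
      t >= runtime$pending_since + tm$command_delay - tick / 2) {
    origin <- if (pending == "up") "ground" else "upper"
    if (identical(world_get(world, "elevator", "position"), origin)) {
      fire <- c(fire, if (pending == "up") "start_moving_up" else "start_moving_down")
    }
  }
  fire
}

#' Press the alarm toggle
#'
#' Convenience wrapper around the alarm's toggle semantics: switches the
#' alarm on (freezing the elevator in place) or off (unfreezing it; a
#' cancelled ride does not resume without a new command). During replay the
#' *press* is preserved, not the resulting state: a clone's recorded press
#' on an alarm the live participant already switched on switches it off.
#'
#' @param world a [new_world()] with `alarm` and `elevator` entities.
#' @param actor pressing entity id (participant or clone).
#' @return the updated world.
#' @export
press_alarm <- function(world, actor = "P") {
  alarm_toggle(world, new_action("push_alarm", actor, 0))
}

gallery_after_action <- function(action, rs, t) {
  rt <- rs$runtime
  tm <- rs$scenario$config$timing
  sch <- action$schema
  if (sch %in% c("push_up", "push_down")) {
    pending <- world_get(rs$world, "elevator", "pending")
    if (pending %in% c("up", "down") && !identical(rt$pending_dir, pending)) {
      rt$pending_since <- t
      rt$pending_dir <- pending
    }
  } else if (sch == "push_alarm") {
    if (world_get(rs$world, "alarm", "on")) {
      rt$arrive_at <- NULL
      rt$pending_since <- NULL
      rt$pending_dir <- NULL
    }
  } else if (sch %in% c("start_moving_up", "start_moving_down")) {
    rt$arrive_at <- t + tm$travel_duration
    rt$pending_since <- NULL
    rt$pending_dir <- NULL
  } else if (sch %in% c("arrive_upper", "arrive_ground")) {
    rt$arrive_at <- NULL
  } else if (sch %in% c("shoot", "shoot_participant")) {
    rt$last_shot <- t
  }
  invisible(rt)
}

gallery_physical_step <- function(rs, t) {
  repeat {
    fire <- simulate_elevator(rs$world, rs$runtime, t, rs$scenario$config)
    if (!length(fire)) break
    for (sch in fire) {
      a <- new_action(sch, "elevator", t, round = rs$round, status = "scripted")
      execute_action(rs, a)
    }
  }
  invisible(rs)
}

gallery_tick_update <- function(rs, t) {
  rt <- rs$runtime
  g <- rs$scenario$gunman_id
  trapped <- identical(world_get(rs$world, g, "location"), "elevator") &&
    identical(world_get(rs$world, "elevator", "position"), "between") &&
    identical(world_get(rs$world, "elevator", "motion"), "stationary")
  if (trapped) {
    if (is.null(rt$trapped_since)) rt$trapped_since <- t
  } else {
    rt$trapped_since <- NULL
  }
  invisible(rt)
}

gallery_terminated <- function(rs, t) {
  termination_verdict(rs$world, rs$runtime, t, rs$scenario)
}

termination_verdict <- function(world, runtime, t, scenario) {
  tm <- scenario$config$timing
  tick <- scenario$config$tick
  g <- scenario$gunman_id
  # trapped inside the elevator for the full window
  if (!is.null(runtime$trapped_since) &&
      t >= runtime$trapped_since + tm$termination_window - tick / 2) {
    return(TRUE)
  }
  # window elapsed since the last shooting and no further shooting possible:
  # the elevator is not moving and there is no living visitor on the
  # gunman's level
  if (!is.null(runtime$last_shot) &&
      t >= runtime$last_shot + tm$termination_window - tick / 2 &&
      identical(world_get(world, "elevator", "motion"), "stationary")) {
    fl <- effective_floor(world, g)
    alive_there <- if (is.na(fl)) FALSE else {
      any(map_lgl(scenario$visitor_ids, function(v) {
        world_get(world, v, "alive") &&
          identical(world_get(world, v, "location"), fl)
      }))
    }
    if (!alive_there) return(TRUE)
  }
  FALSE
}

#' Trial termination
#'
#' A trial terminates either once the termination window (default 7 s) has
#' elapsed since the last shooting while the gunman has no possibility of
#' shooting again (the elevator is not moving and no visitor is alive on his
#' level), or once the gunman has been trapped inside the elevator --
#' stationary between floors -- continuously for the window.
#'
#' @param history a finalized or in-progress [new_history()].
#' @param t virtual time at which to evaluate.
#' @param scenario the gallery scenario.
#' @return logical scalar.
#' @export
check_termination <- function(history, t, scenario) {
  w <- history$initial_world
  last_shot <- NULL
  trapped_since <- NULL
  g <- scenario$gunman_id
  trapped_p <- function(w) {
    identical(world_get(w, g, "location"), "elevator") &&
      identical(world_get(w, "elevator", "position"), "between") &&
      identical(world_get(w, "elevator", "motion"), "stationary")
  }
  for (a in history$actions) {
    if (a$t > t + 1e-9) break
    if (a$status == "omitted") next
    w <- apply_effects(a, schema_of(history, a), w)
    if (a$schema %in% c("shoot", "shoot_participant")) last_shot <- a$t
    if (trapped_p(w)) {
      if (is.null(trapped_since)) trapped_since <- a$t
    } else {
      trapped_since <- NULL
    }
  }
  rt <- new.env(parent = emptyenv())
  rt$last_shot <- last_shot
  rt$trapped_since <- trapped_since
  termination_verdict(w, rt, t, scenario)
}

#' Count shooting outcomes of a round
#'
#' Counts executed (non-omitted) shootings with visitor targets, and flags
#' separately whether the (live or past) participant was targeted --
#' participant-shot events are bookkeeping, the participant remains
#' operational.
#'
#' @param history a finalized [new_history()].
#' @return a one-row tibble with `visitors_shot` (integer) and
#'   `participant_shot` (logical).
#' @export
count_shot <- function(history) {
  acts <- history$actions
  executed <- keep(acts, function(a) a$status != "omitted")
  vis <- keep(executed, function(a) {
    a$schema == "shoot" && length(a$targets) && grepl("^V[0-9]+$", a$targets[[1L]])
  })
  pshot <- any(map_lgl(executed, function(a) a$schema == "shoot_participant"))
  tibble(visitors_shot = length(vis), participant_shot = pshot)
}

#' Build the gallery scenario
#'
#' Assembles entities (participant `P`, visitors `V1`..`V6`, gunman `G`,
#' elevator, alarm), action schemas, the round-1 predetermined script, the
#' two replacement rules (shooting retarget, enter-floor correction) and the
#' termination rules from a configuration list.
#'
#' @param config a configuration list, path to a YAML config file, or
#'   omitted for [gallery_config()] defaults.
#' @return a `tt_scenario`.
#' @examples
#' sc <- build_gallery()
#' h1 <- record_round(sc, "comply_then_alarm")
#' count_shot(h1)
#' @export
build_gallery <- function(config = gallery_config()) {
  if (is.character(config)) config <- read_scenario_config(config)
  config <- normalize_gallery_config(config)
  if (config$n_visitors != 6L) {
    abort("the gallery script is written for exactly 6 visitors")
  }
  entities <- gallery_entities(config)
  schemas <- gallery_schemas(config)
  script <- gallery_script(config)

  ids <- map_chr(entities, "id")
  bad <- character()
  for (sp in script) {
    if (!sp$actor %in% ids) bad <- c(bad, sprintf("undeclared actor '%s'", sp$actor))
    if (!sp$schema %in% names(schemas)) {
      bad <- c(bad, sprintf("undeclared schema '%s'", sp$schema))
    }
    for (tg in sp$targets) {
      if (!tg %in% ids) bad <- c(bad, sprintf("undeclared target '%s'", tg))
    }
  }
  if (length(bad)) {
    abort(c("invalid scenario config", unique(bad)))
  }

  rules <- list(
    new_replacement_rule("enter_floor_correction", "exit_elevator",
                         enter_floor_correction),
    new_replacement_rule("shooting_retarget", "shoot", shooting_retarget_rule)
  )
  structure(
    list(name = config$name, config = config, entities = entities,
         schemas = schemas, script = script, rules = rules,
         participant_id = "P",
         visitor_ids = paste0("V", seq_len(config$n_visitors)),
         gunman_id = "G",
         hooks = list(after_action = gallery_after_action,
                      physical_step = gallery_physical_step,
                      tick_update = gallery_tick_update,
                      terminated = gallery_terminated)),
    class = "tt_scenario"
  )
}

scenario_initial_world <- function(scenario) {
  new_world(scenario$entities)
}

#' @export
print.tt_scenario <- function(x, ...) {
  cat(sprintf("<tt_scenario> %s: %d entities, %d schemas, %d scripted actions\n",
              x$name, length(x$entities), length(x$schemas), length(x$script)))
  invisible(x)
}

#' Brute-force enumeration of single alarm-press strategies
#'
#' Replays the recorded first round once for every candidate alarm-press
#' time on a grid spanning the gunman's elevator ride (plus never pressing),
#' and classifies each outcome by `(visitors_shot, participant_shot,
#' gunman_trapped)`. On any grid refining the three intervals -- before the
#' ride starts, strictly during it, after arrival -- exactly three outcome
#' classes appear: pressing early leaves the gunman at the ground floor
#' where he shoots the remaining visitor and the participant; pressing
#' mid-ride traps him with nobody shot; pressing late (or never) changes
#' nothing.
#'
#' @param scenario the gallery scenario.
#' @param grid numeric vector of press times (seconds); default: every tick
#'   from just before the gunman's ride is commanded to just after arrival.
#' @param round1 optionally, a pre-recorded canonical first round.
#' @param include_never also evaluate the never-press strategy (press time
#'   `Inf`).
#' @return a tibble with one row per strategy: `press_t`, `visitors_shot`,
#'   `participant_shot`, `gunman_trapped`, `class`.
#' @export
enumerate_alarm_strategies <- function(scenario, grid = NULL, round1 = NULL,
                                       include_never = TRUE) {
  if (is.null(round1)) round1 <- record_round(scenario, "comply_then_alarm")
  tm <- scenario$config$timing
  tick <- scenario$config$tick
  boardG <- map_dbl(keep(scenario$script, function(sp) {
    sp$actor == scenario$gunman_id && sp$schema == "enter_elevator"
  }), "t")
  upG <- boardG + tm$service_wait
  arriveG <- upG + tm$command_delay + tm$travel_duration
  if (is.null(grid)) {
    grid <- seq(upG - 0.5, arriveG + 0.4, by = tick)
  }
  grid <- vt_quantize(grid, tick)
  if (include_never) grid <- c(grid, Inf)

  rows <- map(grid, function(tp) {
    pol <- if (is.finite(tp)) {
      make_policy("scripted",
                  actions = tibble(t = tp, action = "push_alarm"))
    } else {
      "do_nothing"
    }
    h2 <- run_round(scenario, pol, travel_back(round1))
    cs <- count_shot(h2)
    w <- state_at(h2, h2$end_time)
    trapped <- identical(world_get(w, scenario$gunman_id, "location"), "elevator") &&
      identical(world_get(w, "elevator", "position"), "between")
    tibble(press_t = tp, visitors_shot = cs$visitors_shot,
           participant_shot = cs$participant_shot, gunman_trapped = trapped)
  })
  out <- bind_rows(rows)
  out$class <- sprintf("(%d,%s,%s)", out$visitors_shot,
                       ifelse(out$participant_shot, "P", "-"),
                       ifelse(out$gunman_trapped, "trap", "-"))
  out
}
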