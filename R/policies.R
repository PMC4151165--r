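#' Participant policies
#'
#' Policies are engine-exercising fixtures standing in for a participant,
#' not models of human behavior. Each is deterministic given its name,
#' parameters and seed, and decides at every tick -- from the current world
#' and the round's history so far -- which controls to press:
#' \describe{
#'   \item{do_nothing}{never acts.}
#'   \item{comply_then_alarm}{a compliant operator: sends the elevator up
#'     `service_wait` seconds after the last boarding, brings it back down
#'     once it has stood empty upstairs for `service_wait`, stops servicing
#'     when the shooting starts, and presses the alarm `alarm_delay` seconds
#'     after the first shot.}
#'   \item{down_on_shooting}{complies, but answers the first shot by sending
#'     the elevator down instead of pressing the alarm.}
#'   \item{trap_gunman}{waits until the gunman is riding up, then presses
#'     the alarm `delay` seconds after the motion is first seen, freezing
#'     the elevator between floors. With `delay_range = c(lo, hi)` the delay
#'     is instead drawn (seeded, on a 0.5 s grid) per round.}
#'   \item{scripted}{presses controls from a fixed timetable (`actions`: a
#'     data frame with columns `t`, `action`, optional `target`).}
#' }
#'
#' @param name policy name (above).
#' @param params named list of parameters (`service_wait`, `alarm_delay`,
#'   `delay`, `delay_range`, ... -- unset parameters default to the scenario
#'   timing constants).
#' @param seed integer seed for stochastic variants (defaults to the
#'   scenario's engine seed).
#' @param actions timetable for `name = "scripted"`.
#' @return a `tt_policy`.
#' @examples
#' make_policy("trap_gunman", params = list(delay = 0.3))
#' @export
make_policy <- function(name, params = list(), seed = NULL, actions = NULL) {
  fns <- list(
    do_nothing = policy_do_nothing,
    comply_then_alarm = policy_comply(alarm = TRUE),
    down_on_shooting = policy_comply(alarm = FALSE),
    trap_gunman = policy_trap,
    scripted = policy_scripted
  )
  if (!name %in% names(fns)) {
    abort(sprintf("unknown policy '%s' (known: %s)", name,
                  paste(names(fns), collapse = ", ")))
  }
  if (name == "scripted") {
    if (is.null(actions)) abort("scripted policy needs an `actions` timetable")
    actions <- as_tibble(actions)
    stopifnot(all(c("t", "action") %in% names(actions)))
    actions <- actions[order(actions$t), ]
    params$actions <- actions
  }
  structure(list(name = name, params = params, seed = seed, fn = fns[[name]]),
            class = "tt_policy")
}

#' @export
print.tt_policy <- function(x, ...) {
  cat(sprintf("<tt_policy> %s\n", x$name))
  invisible(x)
}

resolve_policy <- function(policy, scenario) {
  if (is.null(policy)) policy <- "do_nothing"
  if (is.character(policy)) policy <- make_policy(policy)
  if (is.data.frame(policy)) policy <- make_policy("scripted", actions = policy)
  if (!inherits(policy, "tt_policy")) abort("not a policy")
  tm <- scenario$config$timing
  defaults <- list(tick = scenario$config$tick, service_wait = tm$service_wait,
                   alarm_delay = tm$alarm_delay, delay = 0.0,
                   delay_range = NULL,
                   seed = policy$seed %||% scenario$config$engine$seed)
  policy$resolved <- utils::modifyList(defaults, policy$params)
  policy
}

policy_do_nothing <- function(t, world, hist, mem, cfg) NULL

# incremental scan of the round history: boardings, requests, first shot
policy_scan <- function(hist, mem) {
  n <- length(hist$actions)
  i0 <- mem$n_seen %||% 0L
  if (n > i0) {
    for (i in (i0 + 1L):n) {
      a <- hist$actions[[i]]
      if (a$status == "omitted") next
      if (a$schema == "enter_elevator") mem$last_board <- a$t
      if (a$schema == "exit_elevator") mem$last_exit <- a$t
      if (a$schema %in% c("shoot", "shoot_participant") && is.null(mem$first_shot)) {
        mem$first_shot <- a$t
      }
    }
    mem$n_seen <- n
  }
  invisible(mem)
}

elevator_occupied <- function(world) {
  any(map_lgl(names(world), function(id) {
    "location" %in% names(world[[id]]$vars) &&
      identical(world[[id]]$vars$location, "elevator")
  }))
}

policy_comply <- function(alarm) {
  force(alarm)
  function(t, world, hist, mem, cfg) {
    policy_scan(hist, mem)
    out <- list()
    pos <- world_get(world, "elevator", "position")
    stat <- identical(world_get(world, "elevator", "motion"), "stationary")
    free <- !world_get(world, "elevator", "frozen")
    idle <- identical(world_get(world, "elevator", "pending"), "none")
    if (is.null(mem$first_shot) && stat && free && idle) {
      if (pos == "ground" && elevator_occupied(world) &&
          !is.null(mem$last_board) &&
          t >= mem$last_board + cfg$service_wait - cfg$tick / 2) {
        out <- c(out, list(list(schema = "push_up")))
      } else if (pos == "upper" && !elevator_occupied(world) &&
                 !is.null(mem$last_exit) &&
                 t >= mem$last_exit + cfg$service_wait - cfg$tick / 2) {
        # return the elevator home once it has stood empty upstairs a while
        out <- c(out, list(list(schema = "push_down")))
      }
    }
    if (!is.null(mem$first_shot) && !isTRUE(mem$responded) &&
        t >= mem$first_shot + cfg$alarm_delay - cfg$tick / 2) {
      out <- c(out, list(list(schema = if (alarm) "push_alarm" else "push_down")))
      mem$responded <- TRUE
    }
    out
  }
}

policy_trap <- function(t, world, hist, mem, cfg) {
  policy_scan(hist, mem)
  if (isTRUE(mem$done)) return(NULL)
  if (is.null(mem$press_at)) {
    riding <- identical(world_get(world, "G", "location"), "elevator") &&
      identical(world_get(world, "elevator", "motion"), "moving_up")
    if (riding) {
      d <- cfg$delay
      if (!is.null(cfg$delay_range)) {
        d <- draw_seeded(cfg$delay_range, cfg$seed, hist$round)
      }
      mem$press_at <- vt_quantize(t + d, cfg$tick)
    }
  }
  if (!is.null(mem$press_at) && t >= mem$press_at - cfg$tick / 2) {
    mem$done <- TRUE
    return(list(list(schema = "push_alarm")))
  }
  NULL
}

# a seeded draw on a 0.5 s grid that leaves the global RNG stream untouched
draw_seeded <- function(range, seed, key) {
  grid <- seq(range[[1L]], range[[2L]], by = 0.5)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer((seed * 131L + key * 7919L) %% .Machine$integer.max))
  sample(grid, 1L)
}

policy_scripted <- function(t, world, hist, mem, cfg) {
  tt <- cfg$actions
  i <- mem$idx %||% 1L
  out <- list()
  while (i <= nrow(tt) && tt$t[[i]] <= t + cfg$tick / 2) {
    tg <- if ("target" %in% names(tt) && !is.na(tt$target[[i]])) tt$target[[i]] else character()
    out <- c(out, list(list(schema = tt$action[[i]], targets = tg)))
    i <- i + 1L
  }
  mem$idx <- i
  out
}

#' The worked-example intervention
#'
#' The reference second-round intervention: the live participant presses the
#' alarm one tick after the clone's up-command for the gunman's ride, so the
#' elevator freezes at the ground floor before its motion starts. The
#' gunman's recorded floor entry is corrected to the ground floor, his first
#' two shootings retarget to the remaining ground-floor visitor and to the
#' participant, the rest are omitted, and the clone's later recorded alarm
#' press now switches the alarm *off*.
#'
#' @param scenario the gallery scenario.
#' @return a scripted `tt_policy` (for `worked_example_policy`), or a
#'   two-round `tt_session` (for `worked_example_session`).
#' @export
worked_example_policy <- function(scenario) {
  tm <- scenario$config$timing
  boardG <- map_dbl(keep(scenario$script, function(sp) {
    sp$actor == scenario$gunman_id && sp$schema == "enter_elevator"
  }), "t")
  press <- vt_quantize(boardG + tm$service_wait + scenario$config$tick,
                       scenario$config$tick)
  make_policy("scripted", actions = tibble(t = press, action = "push_alarm"))
}

#' @rdname worked_example_policy
#' @export
worked_example_session <- function(scenario = build_gallery()) {
  run_loop(scenario,
           list(make_policy("comply_then_alarm"), worked_example_policy(scenario)),
           n_rounds = 2L, mode = "time_travel")
}
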