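#' Replacement rules
#'
#' When a replayed action's preconditions fail, the engine consults the
#' scenario's replacement rules (in declaration order) for a similar action
#' to substitute; if none applies the action is omitted. A rule must never
#' produce a substitution whose preconditions fail in the given world.
#'
#' @param id rule id.
#' @param applies_to schema name the rule matches.
#' @param fn `function(action, world, scenario, runtime)` returning a
#'   substitute [new_action()] or `NULL` (no substitution possible).
#' @return a `tt_rule`.
#' @export
new_replacement_rule <- function(id, applies_to, fn) {
  structure(list(id = id, applies_to = applies_to, fn = fn), class = "tt_rule")
}

#' Attempt to replace a failed action
#'
#' Consults the rules matching the action's schema in declaration order; the
#' first substitution whose preconditions hold is returned with status
#' `retargeted`, otherwise the action is omitted. A rule returning an invalid
#' substitution violates an engine invariant and is an error.
#'
#' @param action the due [new_action()] whose preconditions failed.
#' @param world current [new_world()].
#' @param rules list of [new_replacement_rule()].
#' @param scenario the scenario (for schemas/config).
#' @param runtime engine runtime environment (candidate bookkeeping).
#' @return list with `action` (the substitution or `NULL`) and `status`
#'   (`"retargeted"` or `"omitted"`).
#' @export
attempt_replacement <- function(action, world, rules, scenario, runtime = new.env()) {
  for (r in rules) {
    if (!identical(r$applies_to, action$schema)) next
    sub <- r$fn(action, world, scenario, runtime)
    if (is.null(sub)) next
    s <- scenario$schemas[[sub$schema]]
    if (is.null(s)) abort(sprintf("rule '%s' produced unknown schema '%s'", r$id, sub$schema))
    if (!evaluate_preconditions(sub, s, world)) {
      abort(sprintf("rule '%s' produced a substitution whose preconditions fail", r$id))
    }
    sub$status <- "retargeted"
    sub$original_targets <- action$targets
    sub$original_params <- action$params
    return(list(action = sub, status = "retargeted"))
  }
  list(action = NULL, status = "omitted")
}

#' Travel back in time
#'
#' Builds a replay context from a finished round: the participant's recorded
#' actions are re-attributed to a fresh clone (an agent entity re-enacting
#' them, unaware of the live participant), and the non-omitted agent-class
#' actions with start time at or after the destination form the due-action
#' queue. Physical-object actions are *not* queued -- they are re-simulated
#' from scratch in the new round. Actions before the destination are
#' immutable history and are carried over verbatim.
#'
#' @param history the finished round's [new_history()] (the frame of
#'   reference; earlier rounds are discarded).
#' @param destination virtual time to travel back to, on the tick grid,
#'   within `[0, end of history]` (default 0: the beginning).
#' @return a `tt_replay_context`.
#' @export
travel_back <- function(history, destination = 0) {
  end <- history$end_time
  if (is.na(end)) {
    end <- if (length(history$actions)) max(map_dbl(history$actions, "t")) else 0
  }
  if (destination < 0 || destination > end + 1e-9) {
    abort(sprintf("destination %.2f outside [0, %.2f]", destination, end))
  }
  w0 <- history$initial_world
  pid <- world_ids(w0, "participant")
  if (length(pid) != 1L) abort("history must have exactly one participant entity")
  clone_id <- paste0(pid, history$round)
  if (clone_id %in% names(w0)) abort(sprintf("clone id '%s' already declared", clone_id))

  # the clone starts as a copy of the participant, but is a replayed agent
  w0[[clone_id]] <- list(class = "agent", vars = w0[[pid]]$vars)

  reattribute <- function(a) {
    if (identical(a$actor, pid)) a$actor <- clone_id
    a
  }
  pre <- keep(history$actions, function(a) a$t < destination - 1e-9)
  post <- keep(history$actions, function(a) a$t >= destination - 1e-9)
  queue <- keep(post, function(a) {
    a$status != "omitted" && world_class(w0, a$actor) != "physical"
  })
  queue <- map(queue, reattribute)
  prefix <- map(pre, reattribute)

  structure(
    list(round = history$round + 1L,
         destination = destination,
         queue = queue,
         prefix = prefix,
         initial_world = w0,
         clone_map = c(history$clone_map,
                       setNames(clone_id, as.character(history$round))),
         participant_id = pid),
    class = "tt_replay_context"
  )
}

#' @export
print.tt_replay_context <- function(x, ...) {
  cat(sprintf("<tt_replay_context> -> round %d, destination %.1f, %d due actions\n",
              x$round, x$destination, length(x$queue)))
  cat("  clones:", paste(sprintf("%s -> %s", names(x$clone_map), x$clone_map),
                         collapse = ", "), "\n")
  invisible(x)
}

# ---- engine core ------------------------------------------------------------

# initialize the mutable per-round state (an environment, advanced by
# replay_tick); ctx == NULL means a first (recorded) round
round_state_init <- function(scenario, policy, ctx = NULL) {
  rs <- new.env(parent = emptyenv())
  rs$scenario <- scenario
  rs$tick <- scenario$config$tick
  rs$round <- if (is.null(ctx)) 1L else ctx$round
  rs$participant_id <- scenario$participant_id
  if (is.null(ctx)) {
    rs$world0 <- scenario_initial_world(scenario)
    rs$due <- script_due(scenario)
    rs$t <- 0
    clone_map <- character()
    prefix <- list()
  } else {
    rs$world0 <- ctx$initial_world
    rs$due <- map(ctx$queue, function(a) { a$round <- ctx$round; a })
    rs$t <- ctx$destination
    clone_map <- ctx$clone_map
    prefix <- ctx$prefix
  }
  rs$history <- new_history(rs$round, rs$world0, scenario$schemas,
                            clone_map = clone_map)
  rs$world <- rs$world0
  rs$runtime <- new.env(parent = emptyenv())
  rs$runtime$used_targets <- character()
  rs$policy <- policy
  rs$mem <- new.env(parent = emptyenv())
  rs$di <- 1L
  rs$done <- FALSE
  # immutable pre-destination actions: fold them back in so world and
  # physical bookkeeping match the destination state
  for (a in prefix) {
    rs$history <- append_action(rs$history, a)
    if (a$status != "omitted") {
      s <- scenario$schemas[[a$schema]]
      rs$world <- apply_effects(a, s, rs$world)
      scenario$hooks$after_action(a, rs, a$t)
    }
  }
  rs
}

script_due <- function(scenario) {
  map(scenario$script, function(sp) {
    new_action(sp$schema, sp$actor, sp$t, targets = sp$targets %||% character(),
               params = sp$params %||% list(), round = 1L, status = "scripted")
  })
}

record_action <- function(rs, action) {
  rs$history <- append_action(rs$history, action)
  invisible(rs)
}

execute_action <- function(rs, action) {
  s <- rs$scenario$schemas[[action$schema]]
  rs$world <- apply_effects(action, s, rs$world)
  record_action(rs, action)
  rs$scenario$hooks$after_action(action, rs, rs$t)
  invisible(rs)
}

#' Inject a participant action
#'
#' A live participant action is always executed: if the participant was able
#' to take it, it cannot have been logically invalid. The action is recorded
#' (status `injected`) in the round's history -- necessary for further time
#' travels. Only the live participant may inject, and only control-type
#' schemas (the physically available buttons).
#'
#' @param rs a live round state (from inside [run_loop()] / a policy, or
#'   [record_round()] machinery).
#' @param schema schema name of the control.
#' @param targets optional targets.
#' @param params optional bound parameters.
#' @return the recorded [new_action()], invisibly.
#' @export
inject <- function(rs, schema, targets = character(), params = list()) {
  s <- rs$scenario$schemas[[schema]]
  if (is.null(s)) abort(sprintf("unknown schema '%s'", schema))
  if (!isTRUE(s$control)) {
    abort(sprintf("free-will violation: '%s' is not a participant control", schema))
  }
  a <- new_action(schema, rs$participant_id, rs$t, targets = targets,
                  params = params, round = rs$round, status = "injected")
  execute_action(rs, a)
  invisible(a)
}

#' Advance the engine by one tick
#'
#' Runs one tick of a round in three phases, in the tie-break order that
#' resolves simultaneity: (1) injected participant actions (from the round's
#' policy), (2) due recorded actions whose virtual start time coincides with
#' the current virtual time -- preconditions are checked; on failure a
#' replacement is attempted, otherwise the action is omitted -- and (3)
#' deterministic physical-object transitions. Termination is then evaluated.
#'
#' @param rs the round state from the engine (see [run_loop()]).
#' @return the round state, invisibly; `rs$done` becomes TRUE when the round
#'   has terminated.
#' @export
replay_tick <- function(rs) {
  scenario <- rs$scenario
  t <- rs$t

  # phase 1: free-will interventions
  if (!is.null(rs$policy)) {
    specs <- rs$policy$fn(t, rs$world, rs$history, rs$mem, rs$policy$resolved)
    for (sp in specs %||% list()) {
      inject(rs, sp$schema, sp$targets %||% character(), sp$params %||% list())
    }
  }

  # phase 2: due recorded actions at this tick, in recorded order
  while (rs$di <= length(rs$due) && rs$due[[rs$di]]$t <= t + rs$tick / 2) {
    a <- rs$due[[rs$di]]
    rs$di <- rs$di + 1L
    s <- scenario$schemas[[a$schema]]
    if (evaluate_preconditions(a, s, rs$world)) {
      a$status <- if (rs$round == 1L) a$status else "replayed"
      execute_action(rs, a)
    } else if (rs$round == 1L) {
      # the reasoning engine proper only runs after the first travel;
      # a scripted action whose preconditions fail is skipped silently
      a$status <- "omitted"
      record_action(rs, a)
    } else {
      res <- attempt_replacement(a, rs$world, scenario$rules, scenario, rs$runtime)
      if (res$status == "retargeted") {
        sub <- res$action
        sub$t <- a$t
        sub$round <- rs$round
        execute_action(rs, sub)
      } else {
        a$status <- "omitted"
        record_action(rs, a)
      }
    }
  }

  # phase 3: physical objects, simulated afresh every round
  scenario$hooks$physical_step(rs, t)
  scenario$hooks$tick_update(rs, t)

  if (scenario$hooks$terminated(rs, t) ||
      t >= scenario$config$timing$round_timeout - rs$tick / 2) {
    # recorded actions never reached before the trial ended are omitted, so
    # every history fully accounts for every attempted action
    while (rs$di <= length(rs$due)) {
      a <- rs$due[[rs$di]]
      rs$di <- rs$di + 1L
      a$status <- "omitted"
      a$round <- rs$round
      record_action(rs, a)
    }
    rs$history$end_time <- t
    rs$done <- TRUE
  } else {
    rs$t <- vt_quantize(t + rs$tick, rs$tick)
  }
  invisible(rs)
}

run_round <- function(scenario, policy, ctx = NULL) {
  policy <- resolve_policy(policy, scenario)
  rs <- round_state_init(scenario, policy, ctx)
  while (!rs$done) replay_tick(rs)
  rs$history
}

#' Replay one round after a time travel
#'
#' Runs the replay loop over a [travel_back()] context: due recorded actions
#' are re-executed under precondition checks (with replacement/omission on
#' failure), physical objects are re-simulated, and the policy's
#' interventions are injected with free-will priority.
#'
#' @param scenario the scenario the history was recorded in.
#' @param ctx a [travel_back()] context.
#' @param policy the live participant's policy for this round (see
#'   [make_policy()]).
#' @return the new round's [new_history()].
#' @export
replay_round <- function(scenario, ctx, policy = "do_nothing") {
  run_round(scenario, policy, ctx)
}

#' Record a first round
#'
#' Plays the predetermined script and records the participant's
#' interventions. Scripted agent actions are precondition-checked (and
#' skipped silently when the participant's behavior makes them impossible);
#' physical objects are simulated; participant actions carry status
#' `injected`.
#'
#' @param scenario a scenario, e.g. [build_gallery()].
#' @param interventions a policy (see [make_policy()]), a policy name, or a
#'   data frame of timed actions (`t`, `action`, optional `target`) for a
#'   scripted participant.
#' @return the round's [new_history()].
#' @export
record_round <- function(scenario, interventions = "do_nothing") {
  run_round(scenario, interventions, ctx = NULL)
}

#' Run a multi-round session
#'
#' In `time_travel` mode each finished round is travelled back from
#' ([travel_back()]) and replayed with the next policy; the finished round
#' becomes the new frame of reference, and each travel adds one co-existing
#' clone. In `repetition` mode the same program is simply run `n_rounds`
#' times independently: no clones, no replay engine.
#'
#' @param scenario a scenario, e.g. [build_gallery()].
#' @param policies one policy (reused every round) or a list of policies,
#'   one per round (see [make_policy()]).
#' @param n_rounds number of rounds (>= 1).
#' @param mode `"time_travel"` or `"repetition"`.
#' @param destination travel destination time for every travel (default 0,
#'   the beginning of the scenario).
#' @return a `tt_session`: list of histories plus metadata. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' sc <- build_gallery()
#' ses <- run_loop(sc, list("comply_then_alarm", "trap_gunman", "do_nothing"),
#'                 n_rounds = 3)
#' glance(ses)
#' }
#' @export
run_loop <- function(scenario, policies = "do_nothing", n_rounds = 1L,
                     mode = c("time_travel", "repetition"), destination = 0) {
  mode <- match.arg(mode)
  stopifnot(n_rounds >= 1L)
  if (!is.list(policies) || inherits(policies, "tt_policy") ||
      is.data.frame(policies)) {
    policies <- rep(list(policies), n_rounds)
  }
  if (length(policies) != n_rounds) {
    abort("`policies` must be a single policy or one per round")
  }
  histories <- vector("list", n_rounds)
  if (mode == "repetition") {
    for (k in seq_len(n_rounds)) {
      h <- run_round(scenario, policies[[k]], ctx = NULL)
      h$round <- k
      h$actions <- map(h$actions, function(a) { a$round <- k; a })
      histories[[k]] <- h
    }
  } else {
    h <- record_round(scenario, policies[[1L]])
    histories[[1L]] <- h
    for (k in seq_len(n_rounds)[-1L]) {
      ctx <- travel_back(h, destination)
      h <- run_round(scenario, policies[[k]], ctx)
      histories[[k]] <- h
    }
  }
  structure(list(histories = histories, scenario = scenario, mode = mode),
            class = "tt_session")
}

#' @export
print.tt_session <- function(x, ...) {
  cat(sprintf("<tt_session> %s, %d rounds (%s scenario)\n", x$mode,
              length(x$histories), x$scenario$name))
  print(glance(x))
  invisible(x)
}
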