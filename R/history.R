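#' Histories
#'
#' A history is the engine's record of one round: the initial world state
#' plus the ordered, timestamped actions (executed and omitted). It is the
#' sole frame of reference for the next time travel: whenever history changes
#' the previous one is discarded. The state trajectory is derivable by
#' folding the effects of the non-omitted actions over the initial state
#' ([state_at()]); omitted actions contribute no effects.
#'
#' @param round round index (>= 1).
#' @param initial_world the [new_world()] at round start.
#' @param schemas named list of the scenario's [new_schema()] definitions
#'   (needed to derive states and validate).
#' @param actions list of [new_action()], non-decreasing in time.
#' @param clone_map named character vector mapping source round ("1", "2",
#'   ...) to the clone entity id re-enacting that round's participant
#'   actions.
#' @return a `tt_history`.
#' @export
new_history <- function(round, initial_world, schemas, actions = list(),
                        clone_map = character()) {
  structure(
    list(round = as.integer(round), initial_world = initial_world,
         actions = actions, schemas = schemas, clone_map = clone_map,
         end_time = NA_real_),
    class = "tt_history"
  )
}

#' Append an action to a history
#'
#' @param history a [new_history()].
#' @param action a [new_action()]; its time must not precede the last
#'   recorded timestamp (appending at the same tick is permitted --
#'   simultaneity is resolved by the engine's phase order).
#' @return the extended history.
#' @export
append_action <- function(history, action) {
  n <- length(history$actions)
  if (n > 0L) {
    last_t <- history$actions[[n]]$t
    if (action$t < last_t - 1e-9) {
      abort(sprintf("action at t=%.2f precedes last recorded t=%.2f",
                    action$t, last_t))
    }
  }
  history$actions[[n + 1L]] <- action
  history
}

#' World state at a virtual time
#'
#' Folds the effects of every non-omitted action with start time `<= t` over
#' the history's initial state. A pure function of the history: two refolds
#' agree exactly.
#'
#' @param history a [new_history()].
#' @param t virtual time (seconds), `>= 0`.
#' @return the `tt_world` at `t`.
#' @export
state_at <- function(history, t) {
  stopifnot(t >= 0)
  w <- history$initial_world
  for (a in history$actions) {
    if (a$t > t + 1e-9) break
    if (a$status == "omitted") next
    w <- apply_effects(a, schema_of(history, a), w)
  }
  w
}

schema_of <- function(history, action) {
  s <- history$schemas[[action$schema]]
  if (is.null(s)) abort(sprintf("undeclared schema '%s'", action$schema))
  s
}

#' Validate a history
#'
#' Replays the history from its initial state and reports every invariant
#' violation as data (never as an error): non-monotone timestamps, and
#' non-omitted actions whose preconditions do not hold in the state derived
#' from the actions before them. An empty result means the history is
#' internally consistent.
#'
#' @param history a [new_history()].
#' @return a tibble with one row per violation (`index`, `t`, `actor`,
#'   `action`, `problem`).
#' @export
validate_history <- function(history) {
  out <- list()
  w <- history$initial_world
  last_t <- -Inf
  for (i in seq_along(history$actions)) {
    a <- history$actions[[i]]
    if (a$t < last_t - 1e-9) {
      out[[length(out) + 1L]] <- tibble(
        index = i, t = a$t, actor = a$actor, action = a$schema,
        problem = sprintf("timestamp %.2f precedes previous %.2f", a$t, last_t))
    }
    last_t <- max(last_t, a$t)
    if (a$status == "omitted") next
    s <- schema_of(history, a)
    fails <- failed_preconditions(a, s, w)
    for (f in fails) {
      out[[length(out) + 1L]] <- tibble(
        index = i, t = a$t, actor = a$actor, action = a$schema,
        problem = paste("precondition failed:", f))
    }
    # apply effects regardless, so one broken action stays localized
    w <- apply_effects(a, s, w)
  }
  if (length(out)) bind_rows(out) else
    tibble(index = integer(), t = double(), actor = character(),
           action = character(), problem = character())
}

#' @export
print.tt_history <- function(x, ...) {
  cat(sprintf("<tt_history> round %d, %d actions, end_time=%s\n",
              x$round, length(x$actions),
              ifelse(is.na(x$end_time), "NA", sprintf("%.1f", x$end_time))))
  print(as_tibble(x), n = 12)
  invisible(x)
}

#' Tabular view of a history
#'
#' One row per attempted action, sorted in execution order: the event-log
#' record shape (`t`, `round`, `actor`, `action`, `targets`, `status`,
#' `original_targets`, parameter bindings as list columns).
#'
#' @param x a `tt_history`.
#' @param ... unused.
#' @export
as_tibble.tt_history <- function(x, ...) {
  if (!length(x$actions)) {
    return(tibble(t = double(), round = integer(), actor = character(),
                  action = character(), targets = list(), status = character(),
                  original_targets = list(), params = list()))
  }
  tibble(
    t = map_dbl(x$actions, "t"),
    round = map_int(x$actions, "round"),
    actor = map_chr(x$actions, "actor"),
    action = map_chr(x$actions, "schema"),
    targets = map(x$actions, "targets"),
    status = map_chr(x$actions, "status"),
    original_targets = map(x$actions, function(a) a$original_targets %||% character()),
    params = map(x$actions, "params")
  )
}
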