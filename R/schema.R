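#' Action schemas, predicates and effects
#'
#' An action schema is a declarative action template. Preconditions are
#' predicates -- `(entity, variable, required value)` triples -- that must all
#' hold for the action to take place; effects are the state assignments the
#' action produces. The entity slot of a predicate or effect may be a literal
#' entity id or one of the binding slots `"actor"` / `"target"`; the value
#' slot may be a literal or a parameter reference created with [param_ref()]
#' (e.g. the floor at which an elevator exit happens). Utterance-type schemas
#' (speech, requests) legitimately have empty effects: they replay at their
#' recorded times with no causal consequences.
#'
#' Schemas whose outcome depends on the current state (the alarm toggle, the
#' elevator call buttons) carry an `effect_fn` computed effect in addition to
#' (or instead of) static effects; this is what makes replay preserve
#' *actions* rather than outcomes.
#'
#' @param entity entity slot: literal id, `"actor"`, or `"target"`.
#' @param variable variable name.
#' @param value required value (predicate) / new value (effect); a literal or
#'   a [param_ref()].
#' @return `predicate()` and `eff()` return template triples; `param_ref()` a
#'   parameter reference; `new_schema()` a `tt_schema`.
#' @examples
#' sh <- new_schema("shoot", "agent",
#'   preconds = list(
#'     predicate("actor", "alive", TRUE),
#'     predicate("actor", "location", param_ref("floor")),
#'     predicate("target", "alive", TRUE),
#'     predicate("target", "location", param_ref("floor"))
#'   ),
#'   effects = list(eff("target", "alive", FALSE)),
#'   params = "floor"
#' )
#' @export
predicate <- function(entity, variable, value) {
  structure(list(entity = entity, variable = variable, value = value),
            class = "tt_predicate")
}

#' @rdname predicate
#' @export
eff <- function(entity, variable, value) {
  structure(list(entity = entity, variable = variable, value = value),
            class = "tt_effect")
}

#' @rdname predicate
#' @param name parameter name for `param_ref()`; schema name for
#'   `new_schema()`.
#' @export
param_ref <- function(name) {
  structure(list(name = name), class = "tt_param_ref")
}

#' @rdname predicate
#' @param actor_class causal class expected to perform the action.
#' @param preconds list of [predicate()] templates.
#' @param effects list of [eff()] templates (may be empty for utterances).
#' @param params character vector of parameter slot names.
#' @param effect_fn optional `function(world, action)` returning the updated
#'   world, for state-dependent outcomes (toggles, call buttons).
#' @param replaceable id of the replacement rule to consult when this
#'   action's preconditions fail during replay, or `NULL`.
#' @param control TRUE if the live participant may inject this action (a
#'   physically available control).
#' @param utterance TRUE for speech-type actions.
#' @export
new_schema <- function(name, actor_class, preconds = list(), effects = list(),
                       params = character(), effect_fn = NULL,
                       replaceable = NULL, control = FALSE, utterance = FALSE) {
  actor_class <- match.arg(actor_class, c("participant", "physical", "agent"))
  structure(
    list(name = name, actor_class = actor_class, preconds = preconds,
         effects = effects, params = params, effect_fn = effect_fn,
         replaceable = replaceable, control = control, utterance = utterance),
    class = "tt_schema"
  )
}

#' Action instances
#'
#' An action instance binds a schema to an actor, targets, bound parameters,
#' a virtual start time and a round, and carries its outcome status:
#' `scripted` (predetermined script or fresh physical simulation), `injected`
#' (live participant intervention), `replayed` (recorded action re-executed
#' unchanged), `retargeted` (replaced by a similar action on new targets), or
#' `omitted` (preconditions failed and no replacement applied; contributes no
#' effects).
#'
#' @param schema schema name.
#' @param actor actor entity id.
#' @param t virtual start time (seconds, on the tick grid).
#' @param targets character vector of target entity ids.
#' @param params named list of bound parameter values.
#' @param round round index (>= 1).
#' @param status outcome status.
#' @param original_targets,original_params pre-replacement binding, recorded
#'   when `status == "retargeted"`.
#' @return a `tt_action`.
#' @export
new_action <- function(schema, actor, t, targets = character(), params = list(),
                       round = 1L, status = "scripted",
                       original_targets = NULL, original_params = NULL) {
  status <- match.arg(status,
                      c("scripted", "injected", "replayed", "retargeted", "omitted"))
  if (status %in% c("replayed", "retargeted", "omitted") && round < 2L) {
    # round-1 scripted failures are also recorded as omissions
    if (status != "omitted") abort("replayed/retargeted actions require round >= 2")
  }
  structure(
    list(schema = schema, actor = actor, targets = targets, params = params,
         t = t, round = as.integer(round), status = status,
         original_targets = original_targets, original_params = original_params),
    class = "tt_action"
  )
}

#' @export
print.tt_action <- function(x, ...) {
  tg <- if (length(x$targets)) paste0(" -> ", paste(x$targets, collapse = ",")) else ""
  cat(sprintf("<tt_action> t=%.1f r%d [%s] %s %s%s\n",
              x$t, x$round, x$status, x$actor, x$schema, tg))
  invisible(x)
}

# resolve an entity slot against an action's binding
bind_entity <- function(slot, action) {
  if (identical(slot, "actor")) return(action$actor)
  if (identical(slot, "target")) {
    if (!length(action$targets)) abort("schema references 'target' but action has none")
    return(action$targets[[1L]])
  }
  slot
}

bind_value <- function(value, action) {
  if (inherits(value, "tt_param_ref")) {
    v <- action$params[[value$name]]
    if (is.null(v)) abort(sprintf("action '%s' missing bound parameter '%s'",
                                  action$schema, value$name))
    return(v)
  }
  value
}

#' Evaluate an action's preconditions
#'
#' TRUE iff every bound precondition predicate holds in the given world
#' (vacuously TRUE for an empty precondition list). A predicate naming an
#' undeclared entity or variable is a schema error.
#'
#' @param action a [new_action()].
#' @param schema the action's [new_schema()].
#' @param world a [new_world()] state.
#' @return logical scalar.
#' @export
evaluate_preconditions <- function(action, schema, world) {
  length(failed_preconditions(action, schema, world)) == 0L
}

# list of human-readable descriptions of the failing predicates
failed_preconditions <- function(action, schema, world) {
  out <- character()
  for (p in schema$preconds) {
    id <- bind_entity(p$entity, action)
    want <- bind_value(p$value, action)
    got <- world_get(world, id, p$variable)
    if (!identical(got, want)) {
      out <- c(out, sprintf("%s.%s == %s (is %s)", id, p$variable,
                            format(want), format(got)))
    }
  }
  out
}

#' Apply an action's effects
#'
#' Returns a new world differing from the input only in the schema's bound
#' effects (value semantics: the input world is unchanged). Static effects
#' are applied first, then the schema's computed `effect_fn`, if any.
#'
#' @inheritParams evaluate_preconditions
#' @return the updated `tt_world`.
#' @export
apply_effects <- function(action, schema, world) {
  for (e in schema$effects) {
    id <- bind_entity(e$entity, action)
    world <- world_set(world, id, e$variable, bind_value(e$value, action))
  }
  if (!is.null(schema$effect_fn)) {
    world <- schema$effect_fn(world, action)
  }
  world
}
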