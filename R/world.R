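#' World state and entities
#'
#' A world state is a total snapshot: every declared entity is mapped to its
#' abstract state variables (finite symbolic values only -- character or
#' logical scalars). Entities belong to exactly one causal class:
#' `"participant"` (free will: actions always execute), `"physical"`
#' (deterministically re-simulated every round), or `"agent"` (recorded
#' actions are replayed under precondition checks; visitors, the gunman and
#' the participant's past clones).
#'
#' @param id entity id (e.g. `"G"`, `"V1"`, `"elevator"`).
#' @param causal_class one of `"participant"`, `"physical"`, `"agent"`.
#' @param vars named list of initial variable values (character or logical
#'   scalars).
#' @return `new_entity()` returns an entity definition; `new_world()` a
#'   `tt_world` object.
#' @examples
#' w <- new_world(list(
#'   new_entity("lamp", "physical", list(on = FALSE)),
#'   new_entity("R2", "agent", list(at = "a"))
#' ))
#' world_get(w, "lamp", "on")
#' @export
new_entity <- function(id, causal_class, vars) {
  causal_class <- match.arg(causal_class, c("participant", "physical", "agent"))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!rlang::is_named(vars)) abort("entity variables must be a named list")
  ok <- map_lgl(vars, function(v) {
    (is.character(v) || is.logical(v)) && length(v) == 1L && !is.na(v)
  })
  if (!all(ok)) {
    abort(sprintf("entity '%s': variables must be character or logical scalars", id))
  }
  structure(list(id = id, causal_class = causal_class, vars = vars),
            class = "tt_entity")
}

#' @rdname new_entity
#' @param entities list of entities from [new_entity()].
#' @export
new_world <- function(entities) {
  ids <- map_chr(entities, "id")
  if (anyDuplicated(ids)) abort("entity ids must be unique")
  w <- setNames(map(entities, function(e) list(class = e$causal_class, vars = e$vars)), ids)
  structure(w, class = "tt_world")
}

#' @rdname new_entity
#' @param world a `tt_world`.
#' @param variable variable name.
#' @export
world_get <- function(world, id, variable) {
  e <- world[[id]]
  if (is.null(e)) abort(sprintf("undeclared entity '%s'", id))
  if (!variable %in% names(e$vars)) {
    abort(sprintf("entity '%s' has no variable '%s'", id, variable))
  }
  e$vars[[variable]]
}

#' @rdname new_entity
#' @param value new value (same finite domain as declared).
#' @export
world_set <- function(world, id, variable, value) {
  world_get(world, id, variable) # existence check
  world[[id]]$vars[[variable]] <- value
  world
}

world_class <- function(world, id) {
  e <- world[[id]]
  if (is.null(e)) abort(sprintf("undeclared entity '%s'", id))
  e$class
}

world_ids <- function(world, class = NULL) {
  ids <- names(world)
  if (is.null(class)) return(ids)
  ids[map_chr(world, "class") %in% class]
}

#' @export
print.tt_world <- function(x, ...) {
  cat("<tt_world> ", length(x), " entities\n", sep = "")
  for (id in names(x)) {
    vars <- paste(names(x[[id]]$vars),
                  map_chr(x[[id]]$vars, function(v) format(v)),
                  sep = "=", collapse = ", ")
    cat(sprintf("  %-10s [%s] %s\n", id, x[[id]]$class, vars))
  }
  invisible(x)
}

#' @export
as_tibble.tt_world <- function(x, ...) {
  purrr::map_dfr(names(x), function(id) {
    tibble(entity = id, class = x[[id]]$class,
           variable = names(x[[id]]$vars),
           value = map_chr(x[[id]]$vars, function(v) as.character(v)))
  })
}
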