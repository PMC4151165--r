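#' Event logs (JSON Lines)
#'
#' A session streams to one JSON Lines file: a `round` header record per
#' round (round index, initial state, clone map, end time) followed by one
#' `action` record per attempted action, in execution order. `read_event_log()`
#' inverts `write_event_log()` exactly.
#'
#' @param x a `tt_session`, a list of histories, or a single `tt_history`.
#' @param path file path.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   a list of `tt_history`.
#' @export
write_event_log <- function(x, path) {
  histories <- as_history_list(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in histories) {
    header <- list(
      type = "round", round = h$round,
      end_time = if (is.na(h$end_time)) NULL else h$end_time,
      clone_map = if (length(h$clone_map)) as.list(h$clone_map) else NULL,
      initial_state = map(unclass(h$initial_world), function(e) {
        list(class = e$class, vars = e$vars)
      })
    )
    writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
    for (a in h$actions) {
      rec <- compact(list(
        type = "action", t = a$t, round = a$round, actor = a$actor,
        action = a$schema,
        targets = if (length(a$targets)) a$targets else NULL,
        status = a$status,
        params = if (length(a$params)) a$params else NULL,
        original_targets = if (length(a$original_targets)) a$original_targets else NULL,
        original_params = if (length(a$original_params)) a$original_params else NULL
      ))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

as_history_list <- function(x) {
  if (inherits(x, "tt_session")) return(x$histories)
  if (inherits(x, "tt_history")) return(list(x))
  stopifnot(is.list(x), all(map_lgl(x, inherits, "tt_history")))
  x
}

#' @rdname write_event_log
#' @param scenario optionally, the scenario whose schemas to attach to the
#'   reconstructed histories (required for [state_at()]/[validate_history()]
#'   on the result).
#' @export
read_event_log <- function(path, scenario = NULL) {
  lines <- readLines(path, warn = FALSE)
  histories <- list()
  h <- NULL
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      abort(sprintf("malformed event log: parse error at line %d: %s",
                                    i, conditionMessage(e)))
                    })
    type <- rec$type %||% ""
    if (type == "round") {
      if (!is.null(h)) histories[[length(histories) + 1L]] <- h
      w <- structure(map(rec$initial_state, function(e) {
        list(class = e$class, vars = map(e$vars, unlist_scalar))
      }), class = "tt_world")
      h <- new_history(rec$round, w,
                       schemas = if (is.null(scenario)) list() else scenario$schemas,
                       clone_map = unlist(rec$clone_map) %||% character())
      h$end_time <- rec$end_time %||% NA_real_
    } else if (type == "action") {
      if (is.null(h)) abort(sprintf("malformed event log: action before any round header at line %d", i))
      a <- new_action(rec$action, rec$actor, rec$t,
                      targets = as.character(unlist(rec$targets)),
                      params = map(rec$params %||% list(), unlist_scalar),
                      round = rec$round, status = rec$status,
                      original_targets = if (is.null(rec$original_targets)) NULL else
                        as.character(unlist(rec$original_targets)),
                      original_params = if (is.null(rec$original_params)) NULL else
                        map(rec$original_params, unlist_scalar))
      h <- append_action(h, a)
    } else {
      abort(sprintf("malformed event log: unknown record type at line %d", i))
    }
  }
  if (!is.null(h)) histories[[length(histories) + 1L]] <- h
  histories
}

unlist_scalar <- function(v) {
  if (is.list(v)) v <- unlist(v)
  v
}

#' Scenario configuration files
#'
#' The scenario configuration (entities counts, tick, timing constants,
#' engine flags) round-trips through structured YAML text bit-exactly.
#'
#' @param config a configuration list ([gallery_config()]) or a
#'   `tt_scenario` (its config is written).
#' @param path file path.
#' @export
write_scenario_config <- function(config, path) {
  if (inherits(config, "tt_scenario")) config <- config$config
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  normalize_gallery_config(yaml::read_yaml(path))
}

normalize_gallery_config <- function(config) {
  cfg <- utils::modifyList(gallery_config(), config)
  cfg$tick <- as.double(cfg$tick)
  cfg$n_visitors <- as.integer(cfg$n_visitors)
  cfg$timing <- map(cfg$timing, as.double)
  cfg$engine$clone_targetable <- isTRUE(cfg$engine$clone_targetable)
  cfg$engine$tie_break <- as.character(cfg$engine$tie_break)
  cfg$engine$seed <- as.integer(cfg$engine$seed)
  cfg
}

#' Human-readable transcript of a session
#'
#' @param session a `tt_session`.
#' @return character vector of transcript lines.
#' @export
session_transcript <- function(session) {
  out <- character()
  for (h in session$histories) {
    out <- c(out, sprintf("== Round %d (%s) ==", h$round, session$mode))
    w <- h$initial_world
    for (a in h$actions) {
      note <- ""
      if (a$status != "omitted") {
        w <- apply_effects(a, schema_of(h, a), w)
        if (a$schema == "push_alarm") {
          note <- sprintf("  -> alarm %s", if (world_get(w, "alarm", "on")) "on" else "off")
        }
      }
      tg <- if (length(a$targets)) paste0(" ", paste(a$targets, collapse = ",")) else ""
      orig <- if (length(a$original_targets)) {
        sprintf(" (was %s)", paste(a$original_targets, collapse = ","))
      } else ""
      out <- c(out, sprintf("%7.1f  %-10s %s%s%s [%s]%s",
                            a$t, a$actor, a$schema, tg, orig, a$status, note))
    }
    if (!is.na(h$end_time)) out <- c(out, sprintf("   round ends at %.1f", h$end_time))
  }
  out
}
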