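#' Tidy a session into its event records
#'
#' @param x a `tt_session`.
#' @param ... unused.
#' @return one row per attempted action across all rounds, in execution
#'   order.
#' @export
tidy.tt_session <- function(x, ...) {
  bind_rows(map(x$histories, as_tibble))
}

#' One-row session overview
#'
#' @param x a `tt_session`.
#' @param ... unused.
#' @export
glance.tt_session <- function(x, ...) {
  last <- x$histories[[length(x$histories)]]
  cs <- count_shot(last)
  tibble(mode = x$mode, rounds = length(x$histories),
         clones = length(last$clone_map),
         final_visitors_shot = cs$visitors_shot,
         final_participant_shot = cs$participant_shot)
}

#' Per-round session table
#'
#' @param session a `tt_session`.
#' @return one row per round: action counts by status, shooting outcome and
#'   end time.
#' @export
session_rounds <- function(session) {
  bind_rows(map(session$histories, function(h) {
    st <- map_chr(h$actions, "status")
    cs <- count_shot(h)
    tibble(round = h$round, n_actions = length(h$actions),
           n_injected = sum(st == "injected"),
           n_replayed = sum(st == "replayed"),
           n_retargeted = sum(st == "retargeted"),
           n_omitted = sum(st == "omitted"),
           visitors_shot = cs$visitors_shot,
           participant_shot = cs$participant_shot,
           clones = length(h$clone_map),
           end_time = h$end_time)
  }))
}

#' Summarize a batch of sessions
#'
#' Per-round means and standard errors (sd / sqrt(n)) of the participant's
#' action counts (injected interventions) and of the number of visitors
#' shot, across sessions. Aggregates are exactly recomputable from the
#' event logs.
#'
#' @param sessions a non-empty list of `tt_session` (or of history lists
#'   read back from event logs).
#' @return a tibble with one row per round.
#' @export
summarize_sessions <- function(sessions) {
  if (!length(sessions)) abort("empty session batch")
  per <- bind_rows(map(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    hs <- if (inherits(s, "tt_session")) s$histories else as_history_list(s)
    bind_rows(map(hs, function(h) {
      st <- map_chr(h$actions, "status")
      cs <- count_shot(h)
      tibble(session = i, round = h$round,
             actions = sum(st == "injected"),
             visitors_shot = cs$visitors_shot)
    }))
  }))
  se <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  per |>
    group_by(round) |>
    summarise(n_sessions = dplyr::n(),
              mean_actions = mean(actions), se_actions = se(actions),
              mean_shot = mean(visitors_shot), se_shot = se(visitors_shot),
              .groups = "drop")
}

#' Plot a session timeline
#'
#' Actions over virtual time, one lane per actor, one facet per round,
#' colored by outcome status.
#'
#' @param object a `tt_session`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tt_session <- function(object, ...) {
  d <- tidy(object)
  d$target <- map_chr(d$targets, function(x) if (length(x)) x[[1L]] else NA_character_)
  ggplot2::ggplot(d, ggplot2::aes(x = t, y = actor, color = status, shape = status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~round, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "virtual time (s)", y = NULL,
                  title = "Session timeline") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tt_session
#' @param enumeration result of [enumerate_alarm_strategies()].
#' @export
plot_alarm_strategies <- function(enumeration) {
  d <- enumeration[is.finite(enumeration$press_t), ]
  ggplot2::ggplot(d, ggplot2::aes(x = press_t, y = visitors_shot, color = class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "alarm press time (s)", y = "visitors shot",
                  title = "Outcome classes over single alarm-press strategies") +
    ggplot2::theme_minimal()
}

# ---- command-line interface -------------------------------------------------

#' Run a session from the command line
#'
#' A thin CLI over [run_loop()]:
#' `--config <file> --mode {time_travel|repetition} --rounds N`
#' `--policy rK=<name[:k=v,...]> --seed S --out <dir> --selftest`.
#' Writes `events.jsonl`, `summary.tsv` and `transcript.txt` to the output
#' directory. `--selftest` replays the packaged worked example and diffs it
#' against the expected script.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, a list with `status` (0 on success), the session and
#'   output paths. A non-zero status (with a message) signals config or
#'   policy errors.
#' @export
run_session <- function(args = commandArgs(trailingOnly = TRUE)) {
  tryCatch(run_session_impl(args), error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(list(status = 1L))
  })
}

run_session_impl <- function(args) {
  opts <- parse_session_args(args)
  if (isTRUE(opts$selftest)) return(run_selftest())
  scenario <- build_gallery(if (is.null(opts$config)) gallery_config() else opts$config)
  if (!is.null(opts$seed)) {
    scenario$config$engine$seed <- as.integer(opts$seed)
  }
  n <- opts$rounds %||% 3L
  policies <- map(seq_len(n), function(k) {
    spec <- opts$policies[[as.character(k)]] %||% opts$policies[["all"]] %||% "do_nothing"
    if (is.character(spec)) parse_policy_spec(spec) else spec
  })
  session <- run_loop(scenario, policies, n_rounds = n, mode = opts$mode %||% "time_travel")
  outdir <- opts$out %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list(events = file.path(outdir, "events.jsonl"),
                summary = file.path(outdir, "summary.tsv"),
                transcript = file.path(outdir, "transcript.txt"))
  write_event_log(session, files$events)
  utils::write.table(session_rounds(session), files$summary, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(session_transcript(session), files$transcript)
  message(sprintf("wrote %d rounds to %s", n, outdir))
  invisible(list(status = 0L, session = session, files = files))
}

parse_session_args <- function(args) {
  opts <- list(policies = list())
  i <- 1L
  need <- function(flag) {
    if (i + 1L > length(args)) abort(sprintf("flag %s needs a value", flag))
    args[[i + 1L]]
  }
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--selftest") { opts$selftest <- TRUE; i <- i + 1L; next }
    v <- need(a)
    if (a == "--config") opts$config <- v
    else if (a == "--mode") {
      opts$mode <- match.arg(v, c("time_travel", "repetition"))
    } else if (a == "--rounds") opts$rounds <- as.integer(v)
    else if (a == "--seed") opts$seed <- as.integer(v)
    else if (a == "--out") opts$out <- v
    else if (a == "--policy") {
      if (grepl("^r[0-9]+=", v)) {
        k <- sub("^r([0-9]+)=.*$", "\\1", v)
        opts$policies[[k]] <- sub("^r[0-9]+=", "", v)
      } else {
        opts$policies[["all"]] <- v
      }
    } else abort(sprintf("unknown flag '%s'", a))
    i <- i + 2L
  }
  opts
}

parse_policy_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  name <- parts[[1L]]
  params <- list()
  if (length(parts) > 1L) {
    for (kv in strsplit(parts[[2L]], ",", fixed = TRUE)[[1L]]) {
      pieces <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(pieces) != 2L) abort(sprintf("bad policy parameter '%s'", kv))
      val <- suppressWarnings(as.numeric(pieces[[2L]]))
      params[[pieces[[1L]]]] <- if (is.na(val)) pieces[[2L]] else val
    }
  }
  make_policy(name, params = params)
}

run_selftest <- function() {
  session <- worked_example_session()
  expected <- utils::read.delim(
    system.file("extdata", "worked_example_round2.tsv", package = "chronoreplay"),
    stringsAsFactors = FALSE)
  got <- worked_example_tail(session)
  same <- isTRUE(all.equal(got, tibble::as_tibble(expected), tolerance = 1e-9))
  if (same) {
    message("selftest passed: worked-example replay matches the expected script")
    invisible(list(status = 0L, session = session))
  } else {
    message("selftest FAILED: worked-example replay diverges from the expected script")
    print(got)
    invisible(list(status = 1L, session = session))
  }
}

#' Worked-example comparison slice
#'
#' The round-2 event records from the gunman's entry onward, flattened for
#' comparison against the expected script.
#'
#' @param session a two-round session from [worked_example_session()].
#' @return a tibble with columns `t`, `actor`, `action`, `target`, `status`,
#'   `original_target`.
#' @export
worked_example_tail <- function(session) {
  h2 <- session$histories[[2L]]
  sc <- session$scenario
  gE <- min(map_dbl(keep(sc$script, function(sp) sp$actor == sc$gunman_id), "t"))
  d <- as_tibble(h2)
  d <- d[d$t >= gE - 1e-9, ]
  tibble(
    t = d$t, actor = d$actor, action = d$action,
    target = map_chr(d$targets, function(x) if (length(x)) x[[1L]] else ""),
    status = d$status,
    original_target = map_chr(d$original_targets,
                              function(x) if (length(x)) x[[1L]] else "")
  )
}
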