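#' Scripted trainee conversations
#'
#' A script is an ordered list of events — `utter(text)` trainee
#' messages and `wait(seconds)` silences — standing in for a human
#' trainee so a whole conversation can be replayed deterministically.
#' Waits advance the session's logical clock and give the agent the
#' chance to self-initiate.
#'
#' @param name Script name (used in batch summaries).
#' @param ... Events built with [utter()] and [wait()].
#' @param intended_outcome Optional free-text note on what the script
#'   is meant to demonstrate.
#' @return A `bdi_script`.
#' @export
bdi_script <- function(name, ..., intended_outcome = NULL) {
  events <- list(...)
  if (length(events) == 0) {
    abort_config("A script needs at least one event.")
  }
  ok <- vapply(events, function(e) inherits(e, "bdi_event"), logical(1))
  if (!all(ok)) abort_config("Script events must be utter() or wait().")
  structure(list(name = name, events = events,
                 intended_outcome = intended_outcome),
            class = "bdi_script")
}

#' @rdname bdi_script
#' @param text Trainee utterance.
#' @export
utter <- function(text) {
  structure(list(kind = "utter", text = text), class = "bdi_event")
}

#' @rdname bdi_script
#' @param seconds Positive silence duration in seconds.
#' @export
wait <- function(seconds) {
  if (!is.numeric(seconds) || seconds <= 0) {
    abort_config("wait() needs a positive duration in seconds.")
  }
  structure(list(kind = "wait", seconds = seconds), class = "bdi_event")
}

#' Read a script from a YAML or JSON file
#'
#' The file holds `name`, optionally `intended_outcome`, and an
#' `events` list of `{utter: text}` / `{wait: seconds}` entries.
#'
#' @param path Script file path.
#' @return A `bdi_script`.
#' @export
read_script <- function(path) {
  raw <- read_structured(path)
  events <- purrr::map(raw$events, function(e) {
    if (!is.null(e$utter)) utter(e$utter)
    else if (!is.null(e$wait)) wait(as.numeric(e$wait))
    else abort_config("Script events must have an 'utter' or 'wait' key.")
  })
  do.call(bdi_script, c(list(name = raw$name %||% basename(path)), events,
                        list(intended_outcome = raw$intended_outcome)))
}

#' Packaged replay fixtures
#'
#' Two scripted trainees ship with the bullying scenario:
#' `"rushing"` reproduces the worked rushing-trainee conversation — the
#' trainee greets, empathises once, then jumps straight to the child's
#' wish and rejects its request without an alternative, so the child
#' loses faith and the agent ends the conversation itself;
#' `"adherent"` follows the Five Phase Model — exploring the problem
#' and feelings before goals, suggesting an alternative, steering
#' toward a confidant — and ends with the trainee's goodbye.
#'
#' @param name `"rushing"` or `"adherent"`.
#' @return A `bdi_script`.
#' @export
example_script <- function(name = c("rushing", "adherent")) {
  name <- match.arg(name)
  file <- c(rushing = "script_rushing.yaml",
            adherent = "script_adherent.yaml")[[name]]
  read_script(system.file("extdata", file, package = "bdichat"))
}

#' @export
print.bdi_script <- function(x, ...) {
  cat(sprintf("<bdi_script> %s (%d events)\n", x$name, length(x$events)))
  for (e in x$events) {
    if (e$kind == "utter") cat(sprintf("  utter: %s\n", e$text))
    else cat(sprintf("  wait:  %gs\n", e$seconds))
  }
  invisible(x)
}

#' Replay a script against a scenario
#'
#' Runs the events in order against a fresh session on a scripted
#' clock: utterances go through [handle_turn()], waits advance the
#' clock and then give [idle_tick()] a chance to fire. If the agent
#' ends the session mid-script, the remaining events are dropped and a
#' truncation warning is recorded in the result (rushing trainees still
#' get a full feedback report). Fully deterministic.
#'
#' @param scenario A `bdi_scenario`.
#' @param script A `bdi_script`.
#' @return A `bdi_run`: the finished session, its feedback report, and
#'   a one-row outcome summary.
#' @export
run_script <- function(scenario, script) {
  session <- new_session(scenario, clock = scripted_clock())
  truncated <- FALSE
  warn <- character(0)
  for (k in seq_along(script$events)) {
    e <- script$events[[k]]
    if (session$terminated) {
      truncated <- TRUE
      warn <- sprintf(
        "script '%s' truncated: session ended before event %d of %d",
        script$name, k, length(script$events))
      break
    }
    if (e$kind == "utter") {
      handle_turn(session, e$text)
    } else {
      session$clock$advance(e$seconds)
      idle_tick(session)
    }
  }
  report <- build_report(session)
  structure(list(script_name = script$name, session = session,
                 report = report, truncated = truncated, warnings = warn),
            class = "bdi_run")
}

#' Average end belief value of a run
#'
#' The conversational-outcome summary: the arithmetic mean of all final
#' belief values, on \[0, 1\].
#'
#' @param run A `bdi_run` (or a `bdi_session`).
#' @return A number in \[0, 1\].
#' @export
average_end_belief <- function(run) {
  session <- if (inherits(run, "bdi_run")) run$session else run
  mean(session$snapshot$beliefs)
}

#' @method glance bdi_run
#' @export
glance.bdi_run <- function(x, ...) {
  st <- is_terminated(x$session)
  m <- average_end_belief(x)
  tibble::tibble(
    script = x$script_name,
    trainee_turns = sum(x$report$transcript$speaker == "trainee"),
    terminated = st$terminated,
    cause = st$cause,
    mean_end_belief = m,
    mean_end_belief_0_10 = 10 * m,
    truncated = x$truncated)
}

#' @method tidy bdi_run
#' @export
tidy.bdi_run <- function(x, ...) x$report$beliefs

#' @export
print.bdi_run <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Replay several scripts and summarise
#'
#' One row per script: name, outcome mean (raw and on a 0-10 scale),
#' termination cause, trainee turns, and the per-belief deltas in wide
#' columns (`delta_<belief id>`), ready for CSV export.
#'
#' @param scenario A `bdi_scenario`.
#' @param scripts A list of `bdi_script` objects.
#' @return A tibble with one row per script.
#' @export
batch_run <- function(scenario, scripts) {
  if (length(scripts) == 0) abort_config("batch_run() needs at least one script.")
  if (inherits(scripts, "bdi_script")) scripts <- list(scripts)
  purrr::map_dfr(scripts, function(s) {
    run <- run_script(scenario, s)
    deltas <- run$report$beliefs |>
      dplyr::select("id", "delta") |>
      tidyr::pivot_wider(names_from = "id", values_from = "delta",
                         names_prefix = "delta_")
    dplyr::bind_cols(glance(run), deltas)
  })
}

#' Plot belief trajectories across a run
#'
#' Reconstructs each belief's value after every trainee turn from the
#' per-turn change log and draws the trajectories, highlighting the
#' beliefs that moved.
#'
#' @param run A `bdi_run`.
#' @return A ggplot object.
#' @export
plot_belief_trajectory <- function(run) {
  traj <- belief_trajectory(run)
  moved <- traj |>
    dplyr::group_by(.data$belief) |>
    dplyr::summarise(moved = dplyr::n_distinct(.data$value) > 1)
  traj <- dplyr::left_join(traj, moved, by = "belief")
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$trainee_turn, y = .data$value,
                                     group = .data$belief,
                                     colour = ifelse(.data$moved, .data$belief, NA))) +
    ggplot2::geom_step(linewidth = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_discrete(na.value = "grey85", name = "belief") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Trainee turn", y = "Belief value",
                  title = run$script_name) +
    ggplot2::theme_minimal()
}

#' Per-turn belief values of a run
#'
#' @param run A `bdi_run`.
#' @return A tibble with columns `trainee_turn` (0 = session start),
#'   `belief`, `value`.
#' @export
belief_trajectory <- function(run) {
  session <- run$session
  values <- session$start_snapshot$beliefs
  rows <- list(tibble::tibble(trainee_turn = 0L, belief = names(values),
                              value = unname(values)))
  k <- 0L
  for (t in session$transcript) {
    if (t$speaker != "trainee") next
    k <- k + 1L
    ch <- t$belief_changes
    if (!is.null(ch) && nrow(ch) > 0) values[ch$belief] <- ch$after
    rows[[length(rows) + 1]] <- tibble::tibble(
      trainee_turn = k, belief = names(values), value = unname(values))
  }
  dplyr::bind_rows(rows)
}
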