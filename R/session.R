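#' Clocks for idle self-initiation
#'
#' The agent self-initiates when the trainee has been silent for the
#' scenario's idle threshold (10 seconds in the packaged scenario). The
#' clock is injected so this is testable: `scripted_clock()` is a
#' logical clock advanced explicitly (the replay harness and the test
#' suite use it; nothing ever sleeps), `realtime_clock()` reads the wall
#' clock (the interactive CLI uses it). Reads are non-decreasing.
#'
#' @param start Starting time in seconds for the scripted clock.
#' @return A `bdi_clock`: an environment with `now()` and, for the
#'   scripted clock, `advance(seconds)`.
#' @export
scripted_clock <- function(start = 0) {
  t <- start
  env <- new.env(parent = emptyenv())
  env$now <- function() t
  env$advance <- function(seconds) {
    if (seconds < 0) rlang::abort("Cannot move a clock backwards.")
    t <<- t + seconds
    invisible(t)
  }
  class(env) <- "bdi_clock"
  env
}

#' @rdname scripted_clock
#' @export
realtime_clock <- function() {
  t0 <- as.numeric(Sys.time())
  env <- new.env(parent = emptyenv())
  env$now <- function() as.numeric(Sys.time()) - t0
  class(env) <- "bdi_clock"
  env
}

#' Open a chat session
#'
#' A session holds the live agent snapshot, a frozen copy of the
#' starting snapshot for the feedback report, the transcript, and the
#' idle-clock state. Sessions have reference semantics: [handle_turn()]
#' and [idle_tick()] advance the session in place and return the
#' agent's response(s), mirroring how a chat backend is driven.
#'
#' @param scenario A `bdi_scenario`.
#' @param clock A `bdi_clock`; defaults to a fresh scripted clock so
#'   programmatic use is deterministic.
#' @return A `bdi_session` environment.
#' @export
new_session <- function(scenario, clock = scripted_clock()) {
  stopifnot(inherits(scenario, "bdi_scenario"), inherits(clock, "bdi_clock"))
  s <- new.env(parent = emptyenv())
  s$scenario <- scenario
  s$snapshot <- new_snapshot(scenario)
  s$start_snapshot <- s$snapshot
  s$transcript <- list()
  s$clock <- clock
  s$last_trainee_time <- clock$now()
  s$idle_fired <- FALSE
  s$terminated <- FALSE
  s$termination_cause <- NA_character_
  s$warnings <- character(0)
  class(s) <- "bdi_session"
  s
}

append_turn <- function(session, speaker, text, intent, time, changes = NULL,
                        event = "message") {
  session$transcript[[length(session$transcript) + 1]] <- list(
    speaker = speaker, text = text, intent = intent,
    clock_time = time, event = event, belief_changes = changes)
  invisible(session)
}

#' Handle one trainee turn
#'
#' Classifies the utterance, applies the matching rules to the beliefs,
#' re-evaluates desires and the intention, and executes the intention's
#' next incomplete action as the agent's reply. A trainee goodbye is
#' answered with the farewell template and closes the session
#' (`trainee_goodbye`); executing an action of a terminal desire closes
#' it from the agent's side (`agent_goodbye`). Unrecognised input gets
#' the non-understanding fallback and changes no beliefs, as does a
#' recognised intent whose intention has no actions left.
#'
#' @param session A live `bdi_session`.
#' @param text The trainee's utterance.
#' @return Character vector of agent response strings (updates the
#'   session in place).
#' @export
handle_turn <- function(session, text) {
  if (session$terminated) {
    rlang::abort("Session has ended; no further turns are accepted.",
                 class = "bdichat_session_closed")
  }
  sc <- session$scenario
  t <- session$clock$now()
  intent <- classify(text, sc$lexicon)

  before <- session$snapshot$beliefs
  snap <- apply_intent(session$snapshot, intent, sc$rules)
  moved <- names(before)[before != snap$beliefs]
  changes <- tibble::tibble(belief = moved,
                            before = unname(before[moved]),
                            after = unname(snap$beliefs[moved]))
  append_turn(session, "trainee", text, intent, t, changes)

  snap$active_desires <- evaluate_desires(snap, sc$desires)
  snap$intention <- select_intention(snap$active_desires, sc$desires)

  responses <- character(0)
  if (intent == "goodbye") {
    responses <- sc$fallback$farewell
    session$terminated <- TRUE
    session$termination_cause <- "trainee_goodbye"
  } else if (intent == "unrecognized") {
    responses <- sc$fallback$no_understanding
  } else {
    a <- next_action(snap, snap$intention, sc$actions)
    if (is.na(a)) {
      responses <- sc$fallback$no_understanding
    } else {
      res <- execute_action(snap, a, sc)
      snap <- res$snapshot
      responses <- res$response
      if (isTRUE(res$terminal)) {
        session$terminated <- TRUE
        session$termination_cause <- "agent_goodbye"
      }
    }
  }
  session$snapshot <- snap
  session$last_trainee_time <- t
  session$idle_fired <- FALSE
  for (r in responses) append_turn(session, "agent", r, NA_character_, t)
  responses
}

#' Let the agent self-initiate after silence
#'
#' Call whenever time may have passed. If the trainee has been silent
#' for at least the scenario's idle threshold, the agent executes and
#' returns the next incomplete action of its current intention; with an
#' exhausted intention it stays quiet. Fires at most once per silence
#' window unless the scenario enables `multi_idle`.
#'
#' @param session A live `bdi_session`.
#' @return The agent's message, or `NULL` when nothing fires.
#' @export
idle_tick <- function(session) {
  if (session$terminated) return(invisible(NULL))
  sc <- session$scenario
  t <- session$clock$now()
  if (t - session$last_trainee_time < sc$idle_threshold) return(invisible(NULL))
  if (session$idle_fired && !sc$multi_idle) return(invisible(NULL))
  snap <- session$snapshot
  a <- next_action(snap, snap$intention, sc$actions)
  if (is.na(a)) return(invisible(NULL))
  res <- execute_action(snap, a, sc)
  session$snapshot <- res$snapshot
  session$idle_fired <- TRUE
  if (isTRUE(res$terminal)) {
    session$terminated <- TRUE
    session$termination_cause <- "agent_goodbye"
  }
  append_turn(session, "agent", res$response, NA_character_, t, event = "idle")
  res$response
}

#' Is the session over, and why?
#'
#' @param session A `bdi_session`.
#' @return A list with `terminated` (logical) and `cause` (one of
#'   `"agent_goodbye"`, `"trainee_goodbye"`, `"manual"`, or `NA` while
#'   the session is live).
#' @export
is_terminated <- function(session) {
  list(terminated = session$terminated, cause = session$termination_cause)
}

#' End a session manually
#'
#' @param session A live `bdi_session`.
#' @return The session, invisibly.
#' @export
end_session <- function(session) {
  if (!session$terminated) {
    session$terminated <- TRUE
    session$termination_cause <- "manual"
  }
  invisible(session)
}

#' The session transcript as a tibble
#'
#' One row per message with speaker, text, recognised intent (trainee
#' rows), logical clock time, and the event kind (`message` or `idle`).
#' Belief changes caused by each trainee turn are kept in the
#' `belief_changes` list column, so every belief movement is
#' attributable to exactly one turn.
#'
#' @param x A `bdi_session`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bdi_session
#' @export
tidy.bdi_session <- function(x, ...) {
  if (length(x$transcript) == 0) {
    return(tibble::tibble(turn = integer(), speaker = character(),
                          text = character(), intent = character(),
                          clock_time = numeric(), event = character(),
                          belief_changes = list()))
  }
  purrr::imap_dfr(x$transcript, ~ tibble::tibble(
    turn = .y, speaker = .x$speaker, text = .x$text,
    intent = .x$intent %||% NA_character_, clock_time = .x$clock_time,
    event = .x$event,
    belief_changes = list(.x$belief_changes)))
}

#' @method glance bdi_session
#' @export
glance.bdi_session <- function(x, ...) {
  tr <- tidy(x)
  tibble::tibble(
    scenario = x$scenario$meta$name,
    trainee_turns = sum(tr$speaker == "trainee"),
    agent_turns = sum(tr$speaker == "agent"),
    terminated = x$terminated,
    cause = x$termination_cause,
    mean_belief = mean(x$snapshot$beliefs))
}

#' @export
print.bdi_session <- function(x, ...) {
  st <- is_terminated(x)
  cat(sprintf("<bdi_session> %s | %d message(s) | %s\n",
              x$scenario$meta$name, length(x$transcript),
              if (st$terminated) paste0("ended (", st$cause, ")") else "live"))
  invisible(x)
}
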