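#' Agent snapshots and the reasoning engine
#'
#' The agent's whole dynamical state is a snapshot: the current belief
#' values, the set of active desires, the single intention (the active
#' desire with the best priority rank), and the set of completed
#' actions. The reasoning cycle for one trainee turn is:
#' recognised intent -> [apply_intent()] (belief updates) ->
#' [evaluate_desires()] -> [select_intention()] -> [next_action()] ->
#' [execute_action()].
#'
#' @param scenario A `bdi_scenario`.
#' @return `new_snapshot()` returns a fresh `bdi_snapshot` at the
#'   scenario's initial belief values, with the default desire active
#'   and intended and no actions completed.
#' @export
new_snapshot <- function(scenario) {
  default <- scenario$desires$id[scenario$desires$default]
  structure(list(
    beliefs = stats::setNames(scenario$beliefs$initial, scenario$beliefs$id),
    active_desires = default,
    intention = default,
    completed_actions = character(0)),
    class = "bdi_snapshot")
}

#' @export
print.bdi_snapshot <- function(x, ...) {
  cat(sprintf("<bdi_snapshot> intention %s; active {%s}; %d action(s) done\n",
              x$intention, paste(x$active_desires, collapse = ", "),
              length(x$completed_actions)))
  print(round(x$beliefs, 3))
  invisible(x)
}

#' Apply a recognised intent's rules to the beliefs
#'
#' Every rule whose trigger matches `intent` and whose guard (if any)
#' holds under the beliefs at its firing time is applied: its effects
#' are added in listed order and each result is clamped to \[0, 1\]. No
#' other belief changes. The fallback label `"unrecognized"` matches no
#' rule and leaves the snapshot untouched, as does any intent without a
#' rule.
#'
#' @param snapshot A `bdi_snapshot`.
#' @param intent An intent label.
#' @param rules The scenario's rules tibble (columns `intent`, `guard`,
#'   `effects`).
#' @return The updated snapshot.
#' @export
apply_intent <- function(snapshot, intent, rules) {
  hits <- which(rules$intent == intent)
  beliefs <- snapshot$beliefs
  for (i in hits) {
    guard <- rules$guard[[i]]
    if (!is.null(guard) && !eval_condition(guard, beliefs)) next
    eff <- rules$effects[[i]]
    for (j in seq_len(nrow(eff))) {
      b <- eff$belief[j]
      beliefs[[b]] <- clamp_unit(beliefs[[b]] + eff$delta[j])
    }
  }
  snapshot$beliefs <- beliefs
  snapshot
}

#' Which desires are active under the current beliefs?
#'
#' A desire is active when its threshold condition over the beliefs
#' evaluates true. If no condition holds, the scenario's default desire
#' is active (the agent always wants something). Deterministic; the
#' result is ordered by priority rank.
#'
#' @param snapshot A `bdi_snapshot`.
#' @param desires The scenario's desires tibble.
#' @return Character vector of active desire ids.
#' @export
evaluate_desires <- function(snapshot, desires) {
  on <- vapply(desires$condition, eval_condition, logical(1),
               beliefs = snapshot$beliefs)
  ids <- desires$id[on]
  if (length(ids) == 0) ids <- desires$id[desires$default]
  ids[order(desires$priority[match(ids, desires$id)])]
}

#' Pick the intention from the active desires
#'
#' The intention is the most prominent active desire: the one with the
#' best (lowest) priority rank. Ranks are unique within a scenario, so
#' the choice is total and deterministic.
#'
#' @param active Non-empty character vector of active desire ids.
#' @param desires The scenario's desires tibble.
#' @return A single desire id.
#' @export
select_intention <- function(active, desires) {
  if (length(active) == 0) {
    rlang::abort("No active desires; supply the scenario default.",
                 class = "bdichat_empty_intention")
  }
  active[which.min(desires$priority[match(active, desires$id)])]
}

#' The next incomplete action of an intention
#'
#' Actions attached to a desire form an ordered sequence; the agent
#' works through them front to back, skipping completed ones.
#'
#' @param snapshot A `bdi_snapshot`.
#' @param intention A desire id.
#' @param actions The scenario's actions tibble.
#' @return The action id with the lowest sequence index not yet
#'   completed, or `NA_character_` when the intention is exhausted.
#' @export
next_action <- function(snapshot, intention, actions) {
  cand <- actions[actions$desire_id == intention, ]
  cand <- cand[order(cand$seq), ]
  todo <- cand$id[!cand$id %in% snapshot$completed_actions]
  if (length(todo) == 0) NA_character_ else todo[1]
}

#' Execute an action
#'
#' Marks the action completed and returns its canonical (first) surface
#' template. Executing an already-completed action is an error unless
#' the scenario allows repeats. The result flags whether the action
#' belongs to a terminal (end-conversation) desire, so the caller can
#' close the session.
#'
#' @param snapshot A `bdi_snapshot`.
#' @param action_id An action id.
#' @param scenario The `bdi_scenario` (for action templates, desire
#'   flags and the repeat setting).
#' @return A list with elements `snapshot` (updated), `response` (the
#'   surface string) and `terminal` (logical).
#' @export
execute_action <- function(snapshot, action_id, scenario) {
  i <- match(action_id, scenario$actions$id)
  if (is.na(i)) {
    abort_config(sprintf("Unknown action id '%s'.", action_id))
  }
  if (action_id %in% snapshot$completed_actions && !scenario$allow_repeat) {
    rlang::abort(sprintf("Action '%s' already completed and repeats are disabled.",
                         action_id),
                 class = "bdichat_action_repeat")
  }
  snapshot$completed_actions <- union(snapshot$completed_actions, action_id)
  desire <- scenario$actions$desire_id[i]
  list(snapshot = snapshot,
       response = scenario$actions$templates[[i]][1],
       terminal = scenario$desires$terminal[match(desire, scenario$desires$id)])
}
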