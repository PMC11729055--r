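#' Build the post-session feedback report
#'
#' The trainee's feedback is the conversation transcript plus, for every
#' belief, its starting value, ending value and delta (end minus
#' start), annotated with the Five Phase Model phase the belief informs
#' and a desirability sign: positive when the belief moved in the
#' direction the helpline would want (for most beliefs an increase; for
#' "the trainee wants to end the conversation" a decrease). Reports are
#' produced for live and terminated sessions alike.
#'
#' @param session A `bdi_session`.
#' @return A `bdi_feedback` object; its `beliefs` element is a tibble
#'   with one row per belief.
#' @export
build_report <- function(session) {
  sc <- session$scenario
  start <- session$start_snapshot$beliefs
  end <- session$snapshot$beliefs
  beliefs <- sc$beliefs |>
    dplyr::transmute(
      id = .data$id,
      description = .data$description,
      phase = .data$phase,
      group = .data$group,
      start_value = unname(start[.data$id]),
      end_value = unname(end[.data$id]),
      delta = .data$end_value - .data$start_value,
      desirability_sign = .data$delta * .data$desirable)
  st <- is_terminated(session)
  structure(list(
    scenario_name = sc$meta$name,
    beliefs = beliefs,
    transcript = tidy(session) |> dplyr::select(-"belief_changes"),
    terminated = st$terminated,
    termination_cause = st$cause),
    class = "bdi_feedback")
}

#' Serialise a feedback report
#'
#' `"text"` renders a fixed-width table with beliefs grouped under
#' their subgroup headings (About self / About the child helpline
#' trainee / About conversation / About confidant) followed by the
#' transcript; the output is byte-identical across renders. `"json"`
#' produces a lossless JSON document that [read_report()] parses back
#' to an equal report.
#'
#' @param report A `bdi_feedback`.
#' @param format `"text"` or `"json"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) rlang::abort(
                       "`format` must be 'text' or 'json'.",
                       class = "bdichat_usage_error"))
  if (format == "json") {
    return(jsonlite::toJSON(list(
      scenario_name = report$scenario_name,
      terminated = report$terminated,
      termination_cause = report$termination_cause,
      beliefs = report$beliefs,
      transcript = report$transcript),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
      pretty = TRUE))
  }
  b <- report$beliefs
  lines <- c(sprintf("Feedback report — %s", report$scenario_name),
             sprintf("Session %s", if (report$terminated)
               paste0("ended (", report$termination_cause, ")") else "in progress"),
             "",
             sprintf("%-4s %-52s %-6s %6s %6s %7s", "ID", "Belief", "Phase",
                     "Start", "End", "Delta"))
  for (g in unique(b$group)) {
    lines <- c(lines, paste0("-- ", g, " --"))
    rows <- b[b$group == g, ]
    lines <- c(lines, sprintf("%-4s %-52s %-6s %6.2f %6.2f %+7.2f",
                              rows$id, substr(rows$description, 1, 52),
                              rows$phase, rows$start_value, rows$end_value,
                              rows$delta))
  }
  tr <- report$transcript
  if (nrow(tr) > 0) {
    lines <- c(lines, "", "Transcript:",
               sprintf("[%6.1fs] %-7s %s", tr$clock_time, tr$speaker, tr$text))
  }
  paste(lines, collapse = "\n")
}

#' Parse a JSON feedback report
#'
#' @param json A JSON string (or path to a JSON file) produced by
#'   [render_report()] with `format = "json"` or [write_report()].
#' @return A `bdi_feedback` equal to the one serialised.
#' @export
read_report <- function(json) {
  x <- jsonlite::fromJSON(json)
  transcript <- if (length(x$transcript) == 0) {
    tibble::tibble(turn = integer(), speaker = character(),
                   text = character(), intent = character(),
                   clock_time = numeric(), event = character())
  } else {
    tibble::as_tibble(x$transcript)
  }
  structure(list(
    scenario_name = x$scenario_name,
    beliefs = tibble::as_tibble(x$beliefs),
    transcript = transcript,
    terminated = x$terminated,
    termination_cause = x$termination_cause %||% NA_character_),
    class = "bdi_feedback")
}

#' Write a feedback report to a JSON file
#'
#' @param report A `bdi_feedback`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(render_report(report, "json"), path)
  invisible(path)
}

#' @export
print.bdi_feedback <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}

#' @method tidy bdi_feedback
#' @export
tidy.bdi_feedback <- function(x, ...) x$beliefs

#' @method glance bdi_feedback
#' @export
glance.bdi_feedback <- function(x, ...) {
  tibble::tibble(scenario = x$scenario_name,
                 n_beliefs = nrow(x$beliefs),
                 mean_end_belief = mean(x$beliefs$end_value),
                 terminated = x$terminated,
                 cause = x$termination_cause)
}

#' Plot the belief deltas of a feedback report
#'
#' Bar chart of per-belief change over the session, faceted by belief
#' subgroup and coloured by whether the movement was desirable from the
#' helpline's perspective.
#'
#' @param object A `bdi_feedback`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bdi_feedback
#' @export
autoplot.bdi_feedback <- function(object, ...) {
  b <- object$beliefs |>
    dplyr::mutate(movement = dplyr::case_when(
      .data$desirability_sign > 0 ~ "desirable",
      .data$desirability_sign < 0 ~ "undesirable",
      TRUE ~ "unchanged"))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$id, y = .data$delta,
                                  fill = .data$movement)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(desirable = "#2c7fb8",
                                          unchanged = "grey70",
                                          undesirable = "#d95f0e")) +
    ggplot2::labs(x = NULL, y = "Belief change (end - start)",
                  title = object$scenario_name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
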