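#' The closed intent taxonomy
#'
#' Every trainee utterance is mapped to exactly one of these labels (the
#' single-label limitation is deliberate: the agent never fuses multiple
#' intents from one message). `unrecognized` is the fallback label; no
#' lexicon pattern may map to it.
#'
#' @return Character vector of intent labels.
#' @export
intent_taxonomy <- function() {
  c("greeting", "show_empathy", "ask_problem_details", "ask_feelings",
    "ask_wish", "ask_positive_wish", "reject_request_without_alternative",
    "suggest_alternative", "ask_confidant", "ask_what_to_say",
    "confirm_safety", "summarise_story", "goodbye", "unrecognized")
}

#' Build a keyword lexicon recogniser
#'
#' The packaged intent recogniser is a deterministic first-match keyword
#' matcher: patterns are tried in order and the first one found in the
#' utterance wins. Patterns are matched as whole-word phrases
#' (word-boundary anchored), case-insensitively when `case_insensitive`
#' is set. This is a transparent stand-in for a statistical NLU model;
#' any function honouring the [classify()] signature can replace it.
#'
#' @param patterns A data frame or tibble with columns `pattern` and
#'   `intent`, in match-priority order.
#' @param case_insensitive Fold case before matching? Default `TRUE`.
#' @return A `bdi_lexicon` object.
#' @export
new_lexicon <- function(patterns, case_insensitive = TRUE) {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(c("pattern", "intent") %in% names(patterns)))
  if (any(patterns$intent == "unrecognized")) {
    abort_config("No lexicon pattern may map to 'unrecognized'.")
  }
  structure(list(patterns = patterns,
                 case_insensitive = isTRUE(case_insensitive)),
            class = "bdi_lexicon")
}

#' @export
print.bdi_lexicon <- function(x, ...) {
  cat(sprintf("<bdi_lexicon> %d patterns, %d intents%s\n",
              nrow(x$patterns), dplyr::n_distinct(x$patterns$intent),
              if (x$case_insensitive) ", case-insensitive" else ""))
  invisible(x)
}

#' Read a lexicon from a YAML or JSON file
#'
#' The file is a map with a `case_insensitive` flag and a `patterns`
#' list of `{pattern, intent}` entries in priority order.
#'
#' @param path File path.
#' @return A `bdi_lexicon`.
#' @export
read_lexicon <- function(path) {
  raw <- read_structured(path)
  pats <- purrr::map_dfr(raw$patterns, ~ tibble::tibble(
    pattern = .x$pattern, intent = .x$intent))
  new_lexicon(pats, case_insensitive = raw$case_insensitive %||% TRUE)
}

#' The packaged English lexicon
#'
#' @return The `bdi_lexicon` shipped with the bullying scenario.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_en.yaml", package = "bdichat"))
}

# word-boundary regex for a literal phrase
pattern_regex <- function(pattern) {
  paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pattern), "\\b")
}

#' Classify a trainee utterance
#'
#' Returns the intent of the first lexicon pattern found in `text`, or
#' `"unrecognized"` if none matches. Total and deterministic: every
#' finite string gets a label, and classification is invariant under
#' surrounding whitespace (and case, when the lexicon folds case).
#'
#' @param text A single trainee utterance.
#' @param lexicon A `bdi_lexicon`; defaults to the packaged English one.
#' @return One intent label from [intent_taxonomy()].
#' @examples
#' classify("Hi!", default_lexicon())
#' classify("That sounds really difficult for you", default_lexicon())
#' @export
classify <- function(text, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "bdi_lexicon"))
  if (length(text) != 1 || is.na(text)) return("unrecognized")
  txt <- stringr::str_trim(text)
  if (!nzchar(txt)) return("unrecognized")
  pats <- lexicon$patterns
  if (lexicon$case_insensitive) {
    txt <- stringr::str_to_lower(txt)
    needles <- stringr::str_to_lower(pats$pattern)
  } else {
    needles <- pats$pattern
  }
  hit <- which(stringr::str_detect(txt, pattern_regex(needles)))
  if (length(hit) == 0) "unrecognized" else pats$intent[hit[1]]
}

#' Lint a lexicon against the intent taxonomy
#'
#' Reports (never throws) three kinds of finding: patterns mapping to a
#' label outside the taxonomy, duplicated patterns, and unreachable
#' patterns shadowed by an earlier pattern that is a sub-phrase of them
#' (first-match ordering makes the later entry dead).
#'
#' @param lexicon A `bdi_lexicon`.
#' @param taxonomy Character vector of allowed labels.
#' @return A tibble with columns `kind`, `pattern`, `detail`; zero rows
#'   when the lexicon is clean.
#' @export
validate_lexicon <- function(lexicon, taxonomy = intent_taxonomy()) {
  pats <- lexicon$patterns
  findings <- list()
  bad <- !pats$intent %in% taxonomy
  if (any(bad)) {
    findings <- c(findings, purrr::map2(
      pats$pattern[bad], pats$intent[bad],
      ~ tibble::tibble(kind = "unknown_label", pattern = .x,
                       detail = sprintf("intent '%s' not in taxonomy", .y))))
  }
  key <- if (lexicon$case_insensitive) tolower(pats$pattern) else pats$pattern
  dup <- duplicated(key)
  if (any(dup)) {
    findings <- c(findings, purrr::map(
      pats$pattern[dup],
      ~ tibble::tibble(kind = "duplicate", pattern = .x,
                       detail = "pattern appears more than once")))
  }
  # shadowing: an earlier pattern that matches inside a later pattern's
  # text makes the later pattern unreachable
  n <- nrow(pats)
  for (j in seq_len(n)[-1]) {
    earlier <- seq_len(j - 1)
    shadowers <- earlier[stringr::str_detect(
      key[j], pattern_regex(key[earlier]))]
    if (length(shadowers) > 0) {
      findings <- c(findings, list(tibble::tibble(
        kind = "shadowed", pattern = pats$pattern[j],
        detail = sprintf("unreachable: shadowed by earlier pattern '%s'",
                         pats$pattern[shadowers[1]]))))
    }
  }
  if (length(findings) == 0) {
    tibble::tibble(kind = character(), pattern = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

# read YAML or JSON by extension (JSON is valid YAML, so YAML is the
# fallback parser)
read_structured <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("File not found: %s", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) abort_config(
               sprintf("Could not parse %s: %s", path, conditionMessage(e))))
  }
}
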