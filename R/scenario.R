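#' Scenario configuration
#'
#' A scenario bundles everything that defines one simulated child:
#' belief specifications (id, description, Five Phase Model phase,
#' report group, initial value, desirable direction), desires
#' (activation conditions over beliefs, priority ranks), the ordered
#' actions attached to each desire with their surface templates, the
#' intent-to-belief update rules, the recogniser lexicon, the idle
#' threshold, and fallback templates. All behaviour lives in the file;
#' the engine is generic.
#'
#' @name bdi_scenario
#' @seealso [read_scenario()], [validate_scenario()], [example_scenario()]
NULL

new_scenario <- function(meta, beliefs, desires, actions, rules, lexicon,
                         idle_threshold = 10,
                         fallback = list(no_understanding = "Sorry, I don't understand.",
                                         farewell = "Okay... bye."),
                         allow_repeat = FALSE, multi_idle = FALSE) {
  sc <- structure(
    list(meta = meta,
         beliefs = tibble::as_tibble(beliefs),
         desires = tibble::as_tibble(desires),
         actions = tibble::as_tibble(actions),
         rules = tibble::as_tibble(rules),
         lexicon = lexicon,
         idle_threshold = idle_threshold,
         fallback = fallback,
         allow_repeat = isTRUE(allow_repeat),
         multi_idle = isTRUE(multi_idle)),
    class = "bdi_scenario")
  rep <- validate_scenario(sc)
  errs <- rep$message[rep$level == "error"]
  if (length(errs) > 0) {
    abort_config(paste0("Invalid scenario:\n", paste("-", errs, collapse = "\n")))
  }
  sc
}

#' Read a scenario from a YAML or JSON file
#'
#' Parses, cross-checks every reference (rule effects and condition
#' beliefs, action-to-desire links), and rejects out-of-range initial
#' values. A relative `lexicon` path in the file is resolved against the
#' scenario file's directory; the lexicon may also be given inline.
#'
#' @param path Scenario file path.
#' @return A validated `bdi_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- read_structured(path)
  beliefs <- purrr::map_dfr(raw$beliefs, ~ tibble::tibble(
    id = .x$id,
    description = .x$description %||% "",
    phase = as.character(.x$phase %||% "All"),
    group = .x$group %||% "Other",
    initial = as.numeric(.x$initial),
    desirable = as.integer(.x$desirable %||% 1L)))
  desires <- purrr::map_dfr(raw$desires, function(d) tibble::tibble(
    id = d$id,
    description = d$description %||% "",
    phase = as.character(d$phase %||% "All"),
    priority = as.integer(d$priority),
    default = isTRUE(d$default),
    terminal = isTRUE(d$terminal),
    action_free = isTRUE(d$action_free),
    condition = list(parse_condition(d$condition))))
  actions <- purrr::imap_dfr(raw$actions, function(a, i) tibble::tibble(
    id = a$id,
    desire_id = a$desire,
    name = a$name %||% a$id,
    templates = list(as.character(unlist(a$templates)))))
  actions <- actions |>
    dplyr::group_by(.data$desire_id) |>
    dplyr::mutate(seq = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  rules <- purrr::map_dfr(raw$rules, function(r) tibble::tibble(
    intent = r$intent,
    guard = list(parse_condition(r$guard)),
    effects = list(purrr::map_dfr(r$effects, ~ tibble::tibble(
      belief = .x$belief, delta = as.numeric(.x$delta))))))
  lexicon <- if (is.character(raw$lexicon)) {
    lp <- raw$lexicon
    if (!file.exists(lp)) lp <- file.path(dirname(path), raw$lexicon)
    read_lexicon(lp)
  } else {
    new_lexicon(
      purrr::map_dfr(raw$lexicon$patterns, ~ tibble::tibble(
        pattern = .x$pattern, intent = .x$intent)),
      case_insensitive = raw$lexicon$case_insensitive %||% TRUE)
  }
  new_scenario(
    meta = list(name = raw$name %||% basename(path),
                description = raw$description %||% "",
                language = raw$language %||% "en",
                lexicon_path = if (is.character(raw$lexicon)) raw$lexicon else NULL),
    beliefs = beliefs, desires = desires, actions = actions, rules = rules,
    lexicon = lexicon,
    idle_threshold = as.numeric(raw$idle_threshold_seconds %||% 10),
    fallback = list(
      no_understanding = raw$fallback$no_understanding %||% "Sorry, I don't understand.",
      farewell = raw$fallback$farewell %||% "Okay... bye."),
    allow_repeat = isTRUE(raw$allow_repeat),
    multi_idle = isTRUE(raw$multi_idle))
}

#' Write a scenario back to YAML
#'
#' Serialises a scenario so that `read_scenario(write_scenario(sc, f))`
#' round-trips to an equal configuration. The lexicon is inlined unless
#' the scenario was read with a lexicon path.
#'
#' @param scenario A `bdi_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  sc <- scenario
  # the lexicon is always inlined so the written file is self-contained
  lex <- list(case_insensitive = sc$lexicon$case_insensitive,
              patterns = purrr::pmap(sc$lexicon$patterns,
                                     function(pattern, intent)
                                       list(pattern = pattern, intent = intent)))
  out <- list(
    name = sc$meta$name, description = sc$meta$description,
    language = sc$meta$language,
    idle_threshold_seconds = sc$idle_threshold,
    allow_repeat = sc$allow_repeat, multi_idle = sc$multi_idle,
    fallback = sc$fallback,
    lexicon = lex,
    beliefs = purrr::pmap(sc$beliefs,
      function(id, description, phase, group, initial, desirable)
        list(id = id, description = description, phase = phase,
             group = group, initial = initial, desirable = desirable)),
    desires = purrr::pmap(sc$desires,
      function(id, description, phase, priority, default, terminal,
               action_free, condition) {
        d <- list(id = id, description = description, phase = phase,
                  priority = priority)
        if (default) d$default <- TRUE
        if (terminal) d$terminal <- TRUE
        if (action_free) d$action_free <- TRUE
        if (!is.null(condition)) d$condition <- condition_to_list(condition)
        d
      }),
    actions = purrr::pmap(sc$actions[order(sc$actions$desire_id, sc$actions$seq), ],
      function(id, desire_id, name, templates, seq)
        list(id = id, desire = desire_id, name = name,
             templates = as.list(templates))),
    rules = purrr::pmap(sc$rules, function(intent, guard, effects) {
      r <- list(intent = intent)
      if (!is.null(guard)) r$guard <- condition_to_list(guard)
      r$effects <- purrr::pmap(effects, function(belief, delta)
        list(belief = belief, delta = delta))
      r
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The packaged bullying scenario
#'
#' Seventeen beliefs, five desires and eight actions modelling a bullied
#' child contacting a helpline chat, with update rules calibrated so the
#' packaged rushing-trainee replay reproduces the published net belief
#' changes exactly.
#'
#' @return A validated `bdi_scenario`.
#' @export
example_scenario <- function() {
  read_scenario(system.file("extdata", "bullying.yaml", package = "bdichat"))
}

#' Validate a scenario, returning a report
#'
#' Unlike [read_scenario()], which throws on errors, this returns the
#' full report: a tibble of findings at `error` or `warning` level.
#' Errors cover duplicate or dangling ids, out-of-range initial values,
#' non-unique priority ranks, a missing or non-unique default desire,
#' oversized rule deltas, rule intents outside the taxonomy, and desires
#' with no actions that are not flagged action-free. Warnings flag
#' desires whose activation condition is statically unreachable given
#' the rules and initial values (per-belief reachability on a 0.1 grid).
#'
#' @param scenario A `bdi_scenario` (or an unvalidated structure of the
#'   same shape).
#' @return A tibble with columns `level`, `where`, `message`.
#' @export
validate_scenario <- function(scenario) {
  sc <- scenario
  f <- list()
  err <- function(where, msg) tibble::tibble(level = "error", where = where, message = msg)
  wrn <- function(where, msg) tibble::tibble(level = "warning", where = where, message = msg)

  bids <- sc$beliefs$id
  for (what in list(list("beliefs", bids), list("desires", sc$desires$id),
                    list("actions", sc$actions$id))) {
    d <- what[[2]][duplicated(what[[2]])]
    if (length(d)) f <- c(f, list(err(what[[1]], sprintf("duplicate id(s): %s",
                                                         paste(d, collapse = ", ")))))
  }
  bad <- sc$beliefs$initial < 0 | sc$beliefs$initial > 1 | !is.finite(sc$beliefs$initial)
  if (any(bad)) {
    f <- c(f, list(err("beliefs", sprintf(
      "initial value outside [0, 1] for %s",
      paste(bids[bad], collapse = ", ")))))
  }
  okphase <- c("1", "2", "3", "4", "5", "All")
  if (any(!sc$beliefs$phase %in% okphase)) {
    f <- c(f, list(err("beliefs", "phase must be one of 1-5 or 'All'")))
  }
  if (!any(!bad) && nrow(sc$beliefs) == 0) {
    f <- c(f, list(err("beliefs", "scenario has no beliefs")))
  }

  if (anyDuplicated(sc$desires$priority)) {
    f <- c(f, list(err("desires", "priority ranks must be unique")))
  }
  if (sum(sc$desires$default) != 1) {
    f <- c(f, list(err("desires", "exactly one desire must be the default")))
  }
  for (i in seq_len(nrow(sc$desires))) {
    refs <- condition_beliefs(sc$desires$condition[[i]])
    miss <- setdiff(refs, bids)
    if (length(miss)) {
      f <- c(f, list(err("desires", sprintf(
        "%s condition references unknown belief(s): %s",
        sc$desires$id[i], paste(miss, collapse = ", ")))))
    }
  }
  no_act <- setdiff(sc$desires$id[!sc$desires$action_free], sc$actions$desire_id)
  if (length(no_act)) {
    f <- c(f, list(err("desires", sprintf(
      "desire(s) without actions and not flagged action-free: %s",
      paste(no_act, collapse = ", ")))))
  }

  dangling <- setdiff(sc$actions$desire_id, sc$desires$id)
  if (length(dangling)) {
    f <- c(f, list(err("actions", sprintf(
      "action desire link(s) to unknown desire: %s",
      paste(dangling, collapse = ", ")))))
  }
  ctg <- sc$actions |>
    dplyr::group_by(.data$desire_id) |>
    dplyr::summarise(ok = identical(sort(.data$seq), seq_along(.data$seq) - 1L))
  if (any(!ctg$ok)) {
    f <- c(f, list(err("actions", sprintf(
      "sequence indices not contiguous from 0 for desire(s): %s",
      paste(ctg$desire_id[!ctg$ok], collapse = ", ")))))
  }

  for (i in seq_len(nrow(sc$rules))) {
    eff <- sc$rules$effects[[i]]
    miss <- setdiff(eff$belief, bids)
    if (length(miss)) {
      f <- c(f, list(err("rules", sprintf(
        "rule for '%s' affects unknown belief(s): %s",
        sc$rules$intent[i], paste(miss, collapse = ", ")))))
    }
    if (any(abs(eff$delta) > 1)) {
      f <- c(f, list(err("rules", sprintf(
        "rule for '%s' has |delta| > 1", sc$rules$intent[i]))))
    }
    gmiss <- setdiff(condition_beliefs(sc$rules$guard[[i]]), bids)
    if (length(gmiss)) {
      f <- c(f, list(err("rules", sprintf(
        "rule guard for '%s' references unknown belief(s): %s",
        sc$rules$intent[i], paste(gmiss, collapse = ", ")))))
    }
  }
  badint <- setdiff(sc$rules$intent, setdiff(intent_taxonomy(), "unrecognized"))
  if (length(badint)) {
    f <- c(f, list(err("rules", sprintf(
      "rule trigger intent(s) outside the taxonomy: %s",
      paste(badint, collapse = ", ")))))
  }
  rk <- paste(sc$rules$intent,
              vapply(sc$rules$guard, format_condition, character(1)))
  if (anyDuplicated(rk)) {
    f <- c(f, list(err("rules", "more than one rule for the same (intent, guard) pair")))
  }

  # reachability warnings only make sense on an otherwise-valid scenario
  if (!length(f)) {
    reach <- reachable_grid_values(sc)
    for (i in seq_len(nrow(sc$desires))) {
      cond <- sc$desires$condition[[i]]
      if (is.null(cond)) next
      if (!condition_reachable(cond, reach)) {
        f <- c(f, list(wrn("desires", sprintf(
          "%s activation condition looks unreachable under the packaged rules and initial values",
          sc$desires$id[i]))))
      }
    }
  }

  if (length(f)) dplyr::bind_rows(f) else {
    tibble::tibble(level = character(), where = character(), message = character())
  }
}

# Per-belief reachable values on a 0.1 grid: starting from the rounded
# initial value, iterate every rule effect on the belief (honouring
# guard atoms that mention only this belief; other atoms are assumed
# satisfiable) until the reachable set is closed. A static
# approximation: AND-conditions are checked leaf-wise.
reachable_grid_values <- function(sc, max_iter = 30) {
  grid <- function(x) round(round(x * 10) / 10, 10)
  reach <- lapply(stats::setNames(sc$beliefs$initial, sc$beliefs$id),
                  function(v) grid(v))
  # effects per belief with their own-belief guard leaves
  per_belief <- list()
  for (i in seq_len(nrow(sc$rules))) {
    eff <- sc$rules$effects[[i]]
    leaves <- condition_leaves(sc$rules$guard[[i]])
    for (j in seq_len(nrow(eff))) {
      b <- eff$belief[j]
      own <- Filter(function(l) l$belief == b, leaves)
      per_belief[[b]] <- c(per_belief[[b]],
                           list(list(delta = eff$delta[j], own = own)))
    }
  }
  for (b in names(reach)) {
    moves <- per_belief[[b]]
    if (is.null(moves)) next
    for (it in seq_len(max_iter)) {
      new <- reach[[b]]
      for (m in moves) {
        from <- reach[[b]]
        if (length(m$own)) {
          ok <- rep(TRUE, length(from))
          for (l in m$own) {
            ok <- ok & (if (l$op == ">=") from >= l$value else from <= l$value)
          }
          from <- from[ok]
        }
        new <- union(new, grid(clamp_unit(from + m$delta)))
      }
      if (length(new) == length(reach[[b]])) break
      reach[[b]] <- new
    }
  }
  reach
}

condition_reachable <- function(cond, reach) {
  if (is.null(cond)) return(TRUE)
  if (inherits(cond, "bdi_cond_leaf")) {
    v <- reach[[cond$belief]]
    return(if (cond$op == ">=") any(v >= cond$value - 1e-9)
           else any(v <= cond$value + 1e-9))
  }
  vals <- vapply(cond$children, condition_reachable, logical(1), reach = reach)
  if (inherits(cond, "bdi_cond_all")) all(vals) else any(vals)
}

#' Diff two scenario configurations
#'
#' Lists changed belief initial values and directions, desire conditions
#' and priorities, action templates and links, rule effects, and
#' top-level settings. The diff is empty iff the configurations are
#' behaviourally equal.
#'
#' @param a,b `bdi_scenario` objects.
#' @return A tibble with columns `section`, `id`, `field`, `a`, `b`
#'   (values formatted as character; added/removed entries show `NA` on
#'   the missing side).
#' @export
diff_scenarios <- function(a, b) {
  rows <- list()
  add <- function(section, id, field, va, vb) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      section = section, id = id, field = field,
      a = as.character(va), b = as.character(vb))
  }
  cmp_tbl <- function(section, ta, tb, key, fields, fmt = NULL) {
    ids <- union(ta[[key]], tb[[key]])
    for (id in ids) {
      ra <- ta[ta[[key]] == id, ]
      rb <- tb[tb[[key]] == id, ]
      if (nrow(ra) == 0) { add(section, id, "presence", NA, "added"); next }
      if (nrow(rb) == 0) { add(section, id, "presence", "removed", NA); next }
      for (fl in fields) {
        va <- ra[[fl]][[1]]; vb <- rb[[fl]][[1]]
        if (!is.null(fmt) && fl %in% names(fmt)) {
          va <- fmt[[fl]](va); vb <- fmt[[fl]](vb)
        }
        if (!identical(va, vb)) add(section, id, fl, format(va)[1], format(vb)[1])
      }
    }
  }
  cmp_tbl("beliefs", a$beliefs, b$beliefs, "id",
          c("initial", "desirable", "phase", "group", "description"))
  cmp_tbl("desires", a$desires, b$desires, "id",
          c("priority", "default", "terminal", "condition"),
          fmt = list(condition = format_condition))
  cmp_tbl("actions", a$actions, b$actions, "id",
          c("desire_id", "seq", "templates"),
          fmt = list(templates = function(x) paste(x, collapse = " | ")))
  fmt_rule <- function(effects) paste(sprintf("%s%+g", effects$belief, effects$delta),
                                      collapse = ", ")
  ra <- a$rules; rb <- b$rules
  keys <- function(r) paste(r$intent, vapply(r$guard, format_condition, character(1)))
  ka <- keys(ra); kb <- keys(rb)
  for (k in union(ka, kb)) {
    ia <- match(k, ka); ib <- match(k, kb)
    if (is.na(ia)) { add("rules", rb$intent[ib], "presence", NA, "added"); next }
    if (is.na(ib)) { add("rules", ra$intent[ia], "presence", "removed", NA); next }
    ea <- fmt_rule(ra$effects[[ia]]); eb <- fmt_rule(rb$effects[[ib]])
    if (!identical(ea, eb)) add("rules", ra$intent[ia], "effects", ea, eb)
  }
  if (!identical(a$idle_threshold, b$idle_threshold)) {
    add("settings", "idle_threshold", "value", a$idle_threshold, b$idle_threshold)
  }
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(section = character(), id = character(), field = character(),
                   a = character(), b = character())
  }
}

#' @export
print.bdi_scenario <- function(x, ...) {
  cat(sprintf("<bdi_scenario> %s\n", x$meta$name))
  cat(sprintf("  %d beliefs, %d desires, %d actions, %d rules; idle threshold %gs\n",
              nrow(x$beliefs), nrow(x$desires), nrow(x$actions), nrow(x$rules),
              x$idle_threshold))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy bdi_scenario
#' @export
tidy.bdi_scenario <- function(x, ...) x$beliefs

#' @importFrom generics glance
#' @method glance bdi_scenario
#' @export
glance.bdi_scenario <- function(x, ...) {
  tibble::tibble(name = x$meta$name, n_beliefs = nrow(x$beliefs),
                 n_desires = nrow(x$desires), n_actions = nrow(x$actions),
                 n_rules = nrow(x$rules), idle_threshold = x$idle_threshold)
}
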