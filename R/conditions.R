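#' Belief-threshold conditions
#'
#' Desire activation and rule guards are boolean expression trees over
#' belief comparisons. A condition is either a *leaf* — a single
#' comparison `belief <op> value` with `op` one of `">="` or `"<="` — or
#' a conjunction/disjunction of sub-conditions. In scenario files the
#' same structure is written as nested YAML maps:
#'
#' ```yaml
#' condition:
#'   any:
#'     - all:
#'         - {belief: B05, op: "<=", value: 0.2}
#'         - {belief: B06, op: "<=", value: 0.3}
#'     - {belief: B15, op: ">=", value: 0.9}
#' ```
#'
#' @param belief Belief id the leaf compares.
#' @param op Comparator, `">="` or `"<="`.
#' @param value Threshold on \[0, 1\].
#' @return A condition node (a classed list).
#' @seealso [eval_condition()]
#' @export
cond_leaf <- function(belief, op, value) {
  if (!op %in% c(">=", "<=")) {
    abort_config(sprintf("Unknown comparator '%s' (use '>=' or '<=').", op))
  }
  if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1) {
    abort_config("Condition threshold must be a single number in [0, 1].")
  }
  structure(list(belief = belief, op = op, value = value),
            class = c("bdi_cond_leaf", "bdi_cond"))
}

#' @rdname cond_leaf
#' @param ... Sub-conditions.
#' @export
cond_all <- function(...) {
  structure(list(children = list(...)),
            class = c("bdi_cond_all", "bdi_cond"))
}

#' @rdname cond_leaf
#' @export
cond_any <- function(...) {
  structure(list(children = list(...)),
            class = c("bdi_cond_any", "bdi_cond"))
}

# Parse the plain-list (YAML/JSON) form into condition nodes.
parse_condition <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "bdi_cond")) return(x)
  if (!is.list(x)) abort_config("A condition must be a map.")
  if (!is.null(x$all)) {
    return(do.call(cond_all, lapply(x$all, parse_condition)))
  }
  if (!is.null(x$any)) {
    return(do.call(cond_any, lapply(x$any, parse_condition)))
  }
  if (!is.null(x$belief)) {
    return(cond_leaf(x$belief, x$op %||% ">=", as.numeric(x$value)))
  }
  abort_config("A condition map needs one of the keys 'belief', 'all', 'any'.")
}

# Inverse of parse_condition, for serialising scenarios back to YAML.
condition_to_list <- function(cond) {
  if (is.null(cond)) return(NULL)
  if (inherits(cond, "bdi_cond_leaf")) {
    return(list(belief = cond$belief, op = cond$op, value = cond$value))
  }
  key <- if (inherits(cond, "bdi_cond_all")) "all" else "any"
  out <- list(lapply(cond$children, condition_to_list))
  names(out) <- key
  out
}

#' Evaluate a condition against belief values
#'
#' @param cond A condition built with [cond_leaf()], [cond_all()],
#'   [cond_any()], or parsed from a scenario file. `NULL` evaluates to
#'   `FALSE` (a desire with no condition is only active as the default).
#' @param beliefs Named numeric vector of current belief values.
#' @return `TRUE` or `FALSE`.
#' @export
eval_condition <- function(cond, beliefs) {
  if (is.null(cond)) return(FALSE)
  if (inherits(cond, "bdi_cond_leaf")) {
    v <- beliefs[[cond$belief]]
    return(if (cond$op == ">=") v >= cond$value else v <= cond$value)
  }
  vals <- vapply(cond$children, eval_condition, logical(1), beliefs = beliefs)
  if (inherits(cond, "bdi_cond_all")) all(vals) else any(vals)
}

# All belief ids referenced anywhere in a condition tree.
condition_beliefs <- function(cond) {
  if (is.null(cond)) return(character(0))
  if (inherits(cond, "bdi_cond_leaf")) return(cond$belief)
  unique(unlist(lapply(cond$children, condition_beliefs)))
}

# Leaf nodes of a condition tree, flattened.
condition_leaves <- function(cond) {
  if (is.null(cond)) return(list())
  if (inherits(cond, "bdi_cond_leaf")) return(list(cond))
  unlist(lapply(cond$children, condition_leaves), recursive = FALSE)
}

format_condition <- function(cond) {
  if (is.null(cond)) return("(none)")
  if (inherits(cond, "bdi_cond_leaf")) {
    return(sprintf("%s %s %s", cond$belief, cond$op, format(cond$value)))
  }
  sep <- if (inherits(cond, "bdi_cond_all")) " AND " else " OR "
  paste0("(", paste(vapply(cond$children, format_condition, character(1)),
                    collapse = sep), ")")
}

#' @export
print.bdi_cond <- function(x, ...) {
  cat(format_condition(x), "\n")
  invisible(x)
}
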