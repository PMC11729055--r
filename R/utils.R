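#' Clamp a number to the unit interval
#'
#' Belief values live on \[0, 1\] (weak to strong). Every rule effect is
#' clamped through this function, so no sequence of intents can push a
#' belief out of range.
#'
#' @param x A finite numeric vector.
#' @return `x` with every element clamped to \[0, 1\].
#' @examples
#' clamp_unit(c(-0.1, 0.5, 1.2))
#' @export
clamp_unit <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort("`x` must be finite numeric.", class = "bdichat_invalid_value")
  }
  pmin(1, pmax(0, x))
}

# shared abort helpers: configuration problems are load-time errors
abort_config <- function(msg) {
  rlang::abort(msg, class = "bdichat_config_error")
}

`%||%` <- rlang::`%||%`
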