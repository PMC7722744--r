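# Internal error helpers. Every user-facing failure carries a class so callers
# (and the CLI) can distinguish configuration errors, input errors, and
# contract violations without string-matching messages.

stop_config <- function(message, ...) {
  abort(message, class = "callrhythm_config_error", ...)
}

stop_input <- function(message, ...) {
  abort(message, class = "callrhythm_input_error", ...)
}

stop_contract <- function(message, ...) {
  abort(message, class = "callrhythm_contract_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_probability <- function(x, name, open = TRUE) {
  if (!is_scalar_number(x)) {
    stop_contract(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    bounds <- if (open) "(0, 1)" else "[0, 1]"
    stop_contract(sprintf("`%s` must lie in %s, got %s.", name, bounds, format(x)))
  }
  invisible(x)
}

#' Format a p-value in 3-significant-figure scientific notation
#'
#' Renders p-values the way result tables in this field are usually printed,
#' e.g. `8.88E-16` or `1.30E-03`. Computation always keeps full double
#' precision; this formatter is presentation only.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector like `"8.88E-16"`.
#' @examples
#' format_pvalue(c(0.5^50, 0.0013))
#' @export
format_pvalue <- function(p) {
  if (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_contract("`p` must be numeric p-values in [0, 1].")
  }
  out <- toupper(formatC(p, format = "e", digits = 2))
  out[is.na(p)] <- NA_character_
  out
}
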