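#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used only at display: internal
#' arithmetic carries unrounded values. `round()`'s banker's rounding is
#' deliberately avoided so that displayed Naira amounts match ordinary
#' spreadsheet rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.5)   # 3, not 2
#' round_half_up(-2.5)  # -3
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# shared input checks -------------------------------------------------------

check_number <- function(x, arg, min = -Inf, max = Inf, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    rlang::abort(sprintf("`%s` must be a non-missing numeric value.", arg),
                 class = "mchfundr_invalid_input")
  }
  if (any(x < min) || any(x > max)) {
    rlang::abort(
      sprintf("`%s` must lie in [%s, %s].", arg, format(min), format(max)),
      class = "mchfundr_invalid_input"
    )
  }
  invisible(x)
}

check_proportion <- function(x, arg) check_number(x, arg, min = 0, max = 1)

abort_degenerate <- function(msg) {
  rlang::abort(msg, class = "mchfundr_degenerate_input")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "mchfundr_config_error")
}

#' Format Naira amounts for display
#'
#' Thousands separators and a plain leading minus for shortfalls.
#'
#' @param x Numeric vector of Naira amounts.
#' @param digits Decimal places shown after half-up rounding.
#' @return Character vector.
#' @export
format_naira <- function(x, digits = 0) {
  formatC(round_half_up(x, digits),
          format = "f", digits = digits, big.mark = ",")
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
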