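#' Round half away from zero at a fixed number of decimals
#'
#' Published dietary-survey tables round halves upward (4.955 -> 4.96), whereas
#' [base::round()] rounds halves to even. All printed-precision rounding in this
#' package goes through this helper so the table conventions are reproducible.
#'
#' @param x Numeric vector (non-negative in all internal uses).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.315, 0.368, 4.95), 2)
#' round_half_up(0.0455, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # 1e-9 nudge: decimal halves (0.0455) sit just below the true half in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: stop with a classed condition so tests can target error types
abort_saltscen <- function(msg, class) {
  rlang::abort(msg, class = c(class, "saltscen_error"))
}

# internal: check required columns, naming the missing ones
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_saltscen(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      "saltscen_schema_error"
    )
  }
  invisible(df)
}
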