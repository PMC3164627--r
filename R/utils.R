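#' Round half away from zero
#'
#' Decimal rounding with ties going half-up (away from zero), the convention
#' used when reporting consistency coefficients, as opposed to the IEEE
#' round-half-even used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.70265, 4)
#' @export
round_half_up <- function(x, digits = 4) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# collapse a character vector for messages: "a, b, c"
comma <- function(x, max = 10) {
  if (length(x) > max) {
    paste0(paste(head(x, max), collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

# strictly internal: stop unless a scalar finite number
check_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", what, "` must be a single finite number"))
  }
  invisible(x)
}
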