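#' Round half away from zero
#'
#' Rounds to the printed-table convention (0.5 rounds up in magnitude), unlike
#' [base::round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 7.539))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# stop with a classed validation error (exit code 1 territory in the CLI)
abort_validation <- function(msg) {
  abort(msg, class = "quotasim_validation_error")
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0)
}
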