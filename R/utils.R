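`%||%` <- function(x, y) if (is.null(x)) y else x

#' Truncate a number toward zero at a fixed number of decimals
#'
#' Display convention used for relative risks and their confidence limits
#' throughout the package reports: values are truncated toward zero rather
#' than rounded (so 3.386 at one decimal is 3.3, not 3.4).
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector truncated toward zero.
#' @export
#' @examples
#' trunc_dec(c(3.386, 74.275, 15.137), 1)
trunc_dec <- function(x, digits = 1) {
  trunc(x * 10^digits) / 10^digits
}

#' Round half away from zero
#'
#' Display convention for percentages and "1 in N" denominators (base R's
#' \code{round} uses round-half-even, which is not what clinical tables use).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Percentage of a count over a total
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimals kept (round half away from zero).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct(10, 73)  # 13.7
pct <- function(k, n, digits = 1) {
  round_half_away(100 * k / n, digits)
}

#' Format a prevalence as "1 in N"
#'
#' N is total/k rounded half away from zero. Display-only convenience;
#' never used in computations.
#'
#' @param k carrier count.
#' @param total cohort size.
#' @return character scalar, or NA if k is zero.
#' @export
fmt_one_in <- function(k, total) {
  if (k <= 0) return(NA_character_)
  sprintf("1 in %d", as.integer(round_half_away(total / k)))
}

#' Path to a file shipped with the package
#'
#' @param file file name under the package's \code{extdata} directory;
#'   empty to list the directory.
#' @return absolute path.
#' @export
fhc_extdata <- function(file = "") {
  p <- system.file("extdata", file, package = "fhconcord")
  if (identical(p, "")) stop("no packaged file '", file, "'", call. = FALSE)
  p
}

# classed conditions so the CLI can map errors to exit codes
fhc_config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("fhc_config_error", "error")))
}

fhc_data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("fhc_data_error", "error")))
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    fhc_config_error(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}
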