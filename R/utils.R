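#' @importFrom stats rbinom runif sd setNames aggregate
#' @importFrom utils combn head read.delim write.table
NULL

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

collapse0 <- function(x) paste0(x, collapse = "")

revcomp <- function(s) {
  vapply(s, function(x) {
    collapse0(rev(chars(chartr("ACGTNacgtn", "TGCANtgcan", x))))
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Reported percentages use conventional half-up rounding (so 10.575 prints
#' as 10.58), not banker's rounding.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage of a part over a total, rounded half-up
#'
#' The percentage convention used in all composition reports:
#' `100 * part / total`, rounded half-up to `digits` decimals.
#' @param part numerator
#' @param total denominator
#' @param digits decimal places (default 2)
#' @return percentage
#' @export
percent_of <- function(part, total, digits = 2) {
  round_half_up(100 * part / total, digits)
}

# Slice a sequence with 0-based half-open coordinates, optionally wrapping
# the origin of a circular sequence (end may exceed nchar(seq)).
subseq0 <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(start >= 0, end > start)
  if (end <= n) {
    substring(seq, start + 1, end)
  } else {
    stopifnot(end - n <= n)
    paste0(substring(seq, start + 1, n), substring(seq, 1, end - n))
  }
}

is_dna_string <- function(s) {
  grepl("^[ACGTNacgtn]*$", s)
}

stop_if_not_dna <- function(s, what = "sequence") {
  bad <- !vapply(s, is_dna_string, logical(1))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what), call. = FALSE)
  }
  invisible(TRUE)
}
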