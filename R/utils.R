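#' Round half-up to a fixed number of decimals
#'
#' Table-style rounding where .5 always rounds away from zero towards the
#' larger value (e.g. 7.315 -> 7.32), unlike [round()]'s banker's rounding.
#' Used for every reported percentage so printed tables are reproduced
#' digit-for-digit.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a count ratio as a percentage string
#'
#' Renders `100 * numerator / denominator` rounded half-up to two decimals
#' with a trailing percent sign, the convention of the family-census tables.
#'
#' @param numerator,denominator non-negative counts, `numerator <= denominator`.
#' @return character scalar like `"51.02%"`.
#' @export
percentage <- function(numerator, denominator) {
  stopifnot(length(numerator) == 1, length(denominator) == 1)
  if (!is.finite(denominator) || denominator <= 0) {
    stop("percentage(): denominator must be > 0")
  }
  if (!is.finite(numerator) || numerator < 0 || numerator > denominator) {
    stop("percentage(): numerator must be in [0, denominator]")
  }
  sprintf("%.2f%%", round_half_up(100 * numerator / denominator, 2))
}

#' @keywords internal
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @keywords internal
read_report_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Derive a stage-local seed from a master seed; kept below 2^31.
#' @keywords internal
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}
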