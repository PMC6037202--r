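## Small shared helpers. Rounding follows the reporting convention used
## throughout: percentages to one decimal, ties away from zero ("half up"),
## which base round() (banker's rounding) does not guarantee.

#' Round half-up
#'
#' Decimal rounding with ties resolved away from zero, matching the way
#' percentages are conventionally reported in clinical-genetics papers
#' (e.g. 67/440 = 15.227... -> 15.2; 61/440 = 13.8636... -> 13.9).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with reporting-style rounding
#'
#' @param num,den numerator and denominator.
#' @param digits decimal places (default 1).
#' @return `100 * num / den`, rounded half-up.
#' @export
pct <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## collapse a list of reason-code vectors to the semicolon form used in
## audit tables; empty -> ""
join_codes <- function(codes) {
  vapply(codes, function(x) paste(x, collapse = ";"), character(1))
}

split_codes <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
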