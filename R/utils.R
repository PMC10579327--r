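#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every reported percentage so that
#' printed ratios are stable across platforms. Base R's `round()` rounds half
#' to even, which would turn e.g. 0.25 into 0.2 at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the reporting precision
#'   used throughout the package).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(98.75, 1) # 98.8
#' round_half_up(0.25, 1)  # 0.3 (base round() would give 0.2)
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  # tiny epsilon guards against representation error just below .5
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Percentage with reporting rounding
#'
#' @param num,den Numerator and denominator.
#' @param digits Decimal places (default 1).
#' @return `100 * num / den`, rounded half-up.
#' @export
percent_of <- function(num, den, digits = 1) {
  stopifnot(all(den > 0))
  round_half_up(100 * num / den, digits)
}

# Derive a per-table seed from a master seed and a table name, so adding a
# table to the bundle never perturbs the random stream of the others. Kept
# below 2^31 - 1 (R integers are 32-bit).
table_seed <- function(master_seed, table_name) {
  h <- sum(utf8ToInt(table_name) * seq_along(utf8ToInt(table_name)))
  as.integer((as.numeric(master_seed) * 10007 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column if present, else a default (tibbles warn on absent `$` access)
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

assert_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(path)
}
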