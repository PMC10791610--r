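#' @importFrom rlang abort warn .data := %||%
#' @importFrom tibble tibble as_tibble
NULL

# Error constructors: every validation failure carries a class so callers can
# distinguish bad parameters from malformed data files.
stop_invalid <- function(msg, class = "flashear_invalid_parameter") {
  abort(msg, class = c(class, "flashear_error"))
}

stop_data_format <- function(msg) {
  abort(msg, class = c("flashear_data_format", "flashear_error"))
}

stop_missing_reference <- function(msg) {
  abort(msg, class = c("flashear_missing_reference", "flashear_error"))
}

check_number <- function(x, name, min = NULL, strict = FALSE, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite and numeric.", name))
  }
  if (!is.null(min)) {
    bad <- if (strict) any(x <= min) else any(x < min)
    if (bad) {
      op <- if (strict) ">" else ">="
      stop_invalid(sprintf("`%s` must be %s %g.", name, op, min))
    }
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_data_format(sprintf(
      "%s is missing required column(s): %s.", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used when comparing
#' computed quantities against values printed at fixed precision), unlike
#' [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.85, 1) # 1.9
round_half_up <- function(x, digits = 0) {
  scaled <- x * 10^digits
  sign(scaled) * floor(abs(scaled) + 0.5) / 10^digits
}

#' Round a value to the precision of a printed reference
#'
#' Publications report numbers at a fixed number of decimals ("0.035 s",
#' "1.4 %"). `round_printed()` parses the decimal places of the printed string
#' and rounds `x` to the same precision (half away from zero), so computed
#' values can be compared with printed ones at the precision actually printed.
#'
#' @param x Numeric vector to round.
#' @param printed Character scalar, the value as printed (e.g. `"0.035"`).
#' @return `x` rounded to the printed number of decimals.
#' @export
#' @examples
#' round_printed(33 / 930, "0.035") # 0.035
round_printed <- function(x, printed) {
  if (!is.character(printed) || length(printed) != 1) {
    stop_invalid("`printed` must be a single character string such as \"0.035\".")
  }
  digits <- if (grepl("\\.", printed)) nchar(sub("^[^.]*\\.", "", printed)) else 0
  round_half_up(x, digits)
}

# First-order (delta-method) standard deviation of a ratio num/den from the
# means and SDs of independent numerator and denominator.
ratio_sd <- function(num_mean, num_sd, den_mean, den_sd) {
  abs(num_mean / den_mean) *
    sqrt((num_sd / num_mean)^2 + (den_sd / den_mean)^2)
}

# Derive an independent sub-seed for a named generator stream so that adding a
# generator never perturbs another's draws. Stays below 2^31 - 1.
derive_seed <- function(seed, label) {
  offsets <- c(cohort = 101L, vessels = 202L, qpcr = 303L, days = 404L)
  if (!label %in% names(offsets)) {
    stop_invalid(sprintf("unknown generator stream '%s'.", label))
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[label]]) %% 2147483629)
}
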