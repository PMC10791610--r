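# Longitudinal ear-swelling and inflammation-score analysis: sham-referenced
# swelling, ordinal skin scores, group mean +/- SEM curves, peak reaction and
# percent-reduction statistics with two-sample t-tests.

#' Inflammation score table
#'
#' Ordinal grades of the two visually scored skin reactions and their score
#' values. The inflammation score of an ear is the sum of its erythema and
#' desquamation scores, range 0-6.
#'
#' @return Named list with `erythema` and `desquamation` score maps.
#' @export
score_table <- function() {
  list(
    erythema = c("no" = 0, "mild" = 0.5, "definite" = 1.5, "severe" = 3),
    desquamation = c("no" = 0, "dry" = 1, "crust formation" = 2, "moist" = 3)
  )
}

map_level <- function(x, map, column) {
  if (is.numeric(x)) {
    bad <- which(!x %in% unname(map))
    if (length(bad) > 0) {
      stop_data_format(sprintf(
        "numeric %s score %g in row %d is not a valid score value.",
        column, x[bad[1]], bad[1]
      ))
    }
    return(x)
  }
  key <- stringr::str_squish(tolower(as.character(x)))
  bad <- which(!key %in% names(map))
  if (length(bad) > 0) {
    stop_data_format(sprintf(
      "unknown %s level '%s' in row %d (expected one of: %s).",
      column, x[bad[1]], bad[1], paste(names(map), collapse = ", ")
    ))
  }
  unname(map[key])
}

#' Inflammation score of an ear
#'
#' Maps the ordinal erythema and desquamation grades through [score_table()]
#' and sums them. Level labels are matched case-insensitively; numeric values
#' already on the score scale are passed through.
#'
#' @param erythema,desquamation Level labels (or numeric scores), vectorised.
#' @param table Score table, see [score_table()].
#' @return Numeric inflammation scores in `[0, 6]`.
#' @export
#' @examples
#' inflammation_score("Mild", "Dry") # 1.5
inflammation_score <- function(erythema, desquamation, table = score_table()) {
  map_level(erythema, table$erythema, "erythema") +
    map_level(desquamation, table$desquamation, "desquamation")
}

sham_groups <- function(measurements, sham_label) {
  tolower(measurements$dose_rate_label) == tolower(sham_label)
}

# Per-day mean ear thickness of the sham group, with a linear interpolator
# for days between sham measurement days (clamped at the range ends, never
# extrapolating a trend).
sham_reference <- function(measurements, sham_label = "Sham") {
  sham <- measurements[sham_groups(measurements, sham_label), ]
  if (nrow(sham) == 0) {
    stop_missing_reference(sprintf(
      "no sham observations (dose_rate_label == '%s') to reference swelling against.",
      sham_label
    ))
  }
  sham |>
    dplyr::group_by(day = .data$day) |>
    dplyr::summarise(sham_mean_um = mean(.data$ear_thickness_um), .groups = "drop") |>
    dplyr::arrange(.data$day)
}

interp_clamped <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  stats::approx(x, y, xout = xout, method = "linear", rule = 2)$y
}

#' Sham-referenced ear swelling
#'
#' Adds the ear swelling `ES_i(t) = ET_i(t) - mean ET_sham(t)`: each
#' thickness minus the mean thickness of all sham mice at that time point.
#' Where no sham mouse was measured on a given day, the sham mean is linearly
#' interpolated between the neighbouring sham days (clamped at the ends); on
#' days with sham observations the exact per-day mean is used, so averaging
#' the swelling of the sham mice measured that day gives exactly zero.
#'
#' @param measurements Measurement table with columns `mouse_id`,
#'   `dose_rate_label`, `day`, `ear_thickness_um`.
#' @param sham_label Label of the sham group in `dose_rate_label`.
#' @return The input with a `swelling_um` column added.
#' @export
ear_swelling <- function(measurements, sham_label = "Sham") {
  check_columns(measurements, c("mouse_id", "dose_rate_label", "day", "ear_thickness_um"),
                "measurement table")
  ref <- sham_reference(measurements, sham_label)
  measurements |>
    dplyr::mutate(
      swelling_um = .data$ear_thickness_um -
        interp_clamped(ref$day, ref$sham_mean_um, .data$day)
    )
}

#' Group mean +/- SEM time course
#'
#' Aggregates per-mouse longitudinal series into group curves. Because mice
#' are monitored on individually varying days, each mouse's series is first
#' linearly interpolated onto a common day grid (by default the union of all
#' observed days, clamped at each mouse's own range), then the per-day mean,
#' SEM and n over mice are taken. With `align = "observed"` only mice actually
#' measured on a day contribute (SEM missing where n = 1).
#'
#' @param measurements Measurement table; for `quantity = "swelling"` the
#'   `swelling_um` column is computed via [ear_swelling()] if absent, for
#'   `"score"` the `score` column via [inflammation_score()].
#' @param quantity `"swelling"` (µm) or `"score"` (inflammation score).
#' @param days Optional day grid for interpolation.
#' @param align `"interpolate"` (default) or `"observed"`.
#' @param sham_label Sham group label.
#' @return A tibble of class `flash_curve`: `dose_Gy`, `dose_rate_label`,
#'   `day`, `mean`, `sem`, `n`, plus a `quantity` attribute.
#' @export
group_curve <- function(measurements,
                        quantity = c("swelling", "score"),
                        days = NULL,
                        align = c("interpolate", "observed"),
                        sham_label = "Sham") {
  quantity <- match.arg(quantity)
  align <- match.arg(align)
  check_columns(measurements, c("mouse_id", "dose_Gy", "dose_rate_label", "day"),
                "measurement table")
  if (nrow(measurements) == 0) {
    abort("no observations to build a group curve from.",
          class = c("flashear_empty_group", "flashear_error"))
  }
  if (quantity == "swelling" && !"swelling_um" %in% names(measurements)) {
    measurements <- ear_swelling(measurements, sham_label)
  }
  if (quantity == "score" && !"score" %in% names(measurements)) {
    check_columns(measurements, c("erythema", "desquamation"), "measurement table")
    measurements <- dplyr::mutate(
      measurements,
      score = inflammation_score(.data$erythema, .data$desquamation)
    )
  }
  value_col <- if (quantity == "swelling") "swelling_um" else "score"
  sem_or_na <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_

  if (align == "observed") {
    out <- measurements |>
      dplyr::group_by(.data$dose_Gy, .data$dose_rate_label, .data$day) |>
      dplyr::summarise(
        mean = mean(.data[[value_col]]),
        sem = sem_or_na(.data[[value_col]]),
        n = dplyr::n(),
        .groups = "drop"
      )
  } else {
    if (is.null(days)) days <- sort(unique(measurements$day))
    out <- measurements |>
      dplyr::group_by(.data$dose_Gy, .data$dose_rate_label, .data$mouse_id) |>
      dplyr::reframe(
        value = interp_clamped(.data$day, .data[[value_col]], days),
        day = days
      ) |>
      dplyr::group_by(.data$dose_Gy, .data$dose_rate_label, .data$day) |>
      dplyr::summarise(
        mean = mean(.data$value),
        sem = sem_or_na(.data$value),
        n = dplyr::n(),
        .groups = "drop"
      )
  }
  attr(out, "quantity") <- quantity
  class(out) <- c("flash_curve", class(out))
  out
}

#' Peak reaction of group curves
#'
#' Finds, per group, the day at which the group mean is maximal within a day
#' window (full follow-up by default). Ties are broken by the earliest day.
#'
#' @param curve A `flash_curve` from [group_curve()].
#' @param window Optional `c(first_day, last_day)` restriction.
#' @return Tibble with `dose_Gy`, `dose_rate_label`, `peak_day`, `peak_mean`,
#'   `peak_sem`, `n`.
#' @export
peak_reaction <- function(curve, window = NULL) {
  check_columns(curve, c("dose_Gy", "dose_rate_label", "day", "mean", "sem", "n"),
                "group curve")
  if (!is.null(window)) {
    curve <- dplyr::filter(curve, .data$day >= window[1], .data$day <= window[2])
  }
  curve <- dplyr::filter(curve, !is.na(.data$mean))
  if (nrow(curve) == 0) {
    abort("no data in the requested peak window.",
          class = c("flashear_no_data", "flashear_error"))
  }
  curve |>
    dplyr::group_by(.data$dose_Gy, .data$dose_rate_label) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      peak_day = .data$day[which.max(.data$mean)],
      peak_mean = max(.data$mean),
      peak_sem = .data$sem[which.max(.data$mean)],
      n = .data$n[which.max(.data$mean)],
      .groups = "drop"
    )
}

#' Percent reduction between a test and a reference peak
#'
#' `R = 100 (1 - m_test / m_ref)` with first-order error propagation
#' `sigma_R = 100 sqrt((s_test / m_ref)^2 + (m_test s_ref / m_ref^2)^2)`.
#' Scale-invariant: rescaling both means and SEMs leaves both outputs
#' unchanged.
#'
#' @param ref_mean,ref_sem Reference group peak mean and SEM (`ref_mean > 0`).
#' @param test_mean,test_sem Test group peak mean and SEM.
#' @return Tibble with `percent` and `sem`.
#' @export
#' @examples
#' percent_reduction(100, 10, 50, 5) # 50 % +/- 7.07 %
percent_reduction <- function(ref_mean, ref_sem, test_mean, test_sem) {
  check_number(ref_mean, "ref_mean")
  if (any(ref_mean <= 0)) {
    stop_invalid("`ref_mean` must be > 0 for a percent reduction.",
                 class = "flashear_undefined_reduction")
  }
  tibble(
    percent = 100 * (1 - test_mean / ref_mean),
    sem = 100 * sqrt((test_sem / ref_mean)^2 +
                       (test_mean * ref_sem / ref_mean^2)^2)
  )
}

#' Two-sample t-test
#'
#' Two-sided Student's t-test with pooled variance by default (the
#' spreadsheet-tool convention the field reports); Welch via
#' `var_equal = FALSE`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return Tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  check_number(a, "a")
  check_number(b, "b")
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("both samples need at least 2 observations.",
                 class = "flashear_invalid_input")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate limit: no within-group variability (possible for ordinal
    # scores); report the limiting statistic rather than failing
    warn("both samples have zero variance; reporting the limiting t statistic.")
    delta <- mean(a) - mean(b)
    return(tibble(
      t = if (delta == 0) 0 else sign(delta) * Inf,
      df = length(a) + length(b) - 2,
      p_value = if (delta == 0) 1 else 0,
      mean_a = mean(a), mean_b = mean(b)
    ))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  tibble(
    t = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}

# Per-mouse value at a given day: linear interpolation of the mouse's own
# series, clamped to its observed range.
mouse_values_at_day <- function(measurements, value_col, at_day) {
  measurements |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(
      value = interp_clamped(.data$day, .data[[value_col]], at_day),
      .groups = "drop"
    ) |>
    dplyr::pull(.data$value)
}

#' Compare dose-rate groups at the peak reaction
#'
#' End-to-end group comparison at one dose level: builds group curves of the
#' chosen quantity, locates each group's peak (its own peak day by default, or
#' the reference group's day with `peak_mode = "common_day"`), computes the
#' percent reduction of every test group relative to the reference with
#' first-order error propagation, and runs a two-sample t-test on the
#' per-mouse values at the respective peak days. No multiple-testing
#' correction is applied; p-values are reported raw.
#'
#' @param measurements Measurement table (sham rows included; they provide the
#'   swelling reference but are not compared).
#' @param dose_Gy Dose level to compare at.
#' @param reference Reference group label (e.g. `"Conv"`).
#' @param quantity `"swelling"` or `"score"`.
#' @param window Optional peak-search day window.
#' @param peak_mode `"own_peak"` (each group's maximum) or `"common_day"`
#'   (all groups evaluated at the reference group's peak day).
#' @param var_equal Student (pooled, default) or Welch t-test.
#' @param sham_label Sham group label.
#' @param days Optional day grid passed to [group_curve()].
#' @return An object of class `flash_comparison`: list with `curves`, `peaks`,
#'   `reductions` (one row per test group with percent, sem, t, df, p_value)
#'   and the settings used. Use [generics::tidy()] for the reduction table.
#' @export
compare_groups <- function(measurements, dose_Gy = 33, reference = "Conv",
                           quantity = c("swelling", "score"), window = NULL,
                           peak_mode = c("own_peak", "common_day"),
                           var_equal = TRUE, sham_label = "Sham", days = NULL) {
  quantity <- match.arg(quantity)
  peak_mode <- match.arg(peak_mode)
  value_col <- if (quantity == "swelling") "swelling_um" else "score"

  if (quantity == "swelling" && !"swelling_um" %in% names(measurements)) {
    measurements <- ear_swelling(measurements, sham_label)
  }
  if (quantity == "score" && !"score" %in% names(measurements)) {
    measurements <- dplyr::mutate(
      measurements,
      score = inflammation_score(.data$erythema, .data$desquamation)
    )
  }
  at_dose <- measurements |>
    dplyr::filter(.data$dose_Gy == !!dose_Gy,
                  !sham_groups(measurements, sham_label))
  if (!reference %in% at_dose$dose_rate_label) {
    stop_missing_reference(sprintf(
      "reference group '%s' has no observations at %g Gy.", reference, dose_Gy
    ))
  }
  curves <- group_curve(at_dose, quantity = quantity, days = days,
                        sham_label = sham_label)
  peaks <- peak_reaction(curves, window = window)
  ref_peak <- dplyr::filter(peaks, .data$dose_rate_label == reference)
  if (peak_mode == "common_day") {
    peaks <- curves |>
      dplyr::filter(.data$day == ref_peak$peak_day) |>
      dplyr::transmute(.data$dose_Gy, .data$dose_rate_label,
                       peak_day = .data$day, peak_mean = .data$mean,
                       peak_sem = .data$sem, .data$n)
    ref_peak <- dplyr::filter(peaks, .data$dose_rate_label == reference)
  }

  ref_data <- dplyr::filter(at_dose, .data$dose_rate_label == reference)
  ref_values <- mouse_values_at_day(ref_data, value_col, ref_peak$peak_day)

  test_groups <- setdiff(unique(at_dose$dose_rate_label), reference)
  reductions <- purrr::map_dfr(test_groups, function(g) {
    pk <- dplyr::filter(peaks, .data$dose_rate_label == g)
    red <- percent_reduction(ref_peak$peak_mean, ref_peak$peak_sem,
                             pk$peak_mean, pk$peak_sem)
    g_data <- dplyr::filter(at_dose, .data$dose_rate_label == g)
    g_values <- mouse_values_at_day(g_data, value_col, pk$peak_day)
    tt <- two_sample_ttest(ref_values, g_values, var_equal = var_equal)
    tibble(
      dose_Gy = dose_Gy, reference = reference, group = g,
      peak_day_ref = ref_peak$peak_day, peak_day_test = pk$peak_day,
      reduction_percent = red$percent, reduction_sem = red$sem,
      t = tt$t, df = tt$df, p_value = tt$p_value
    )
  })

  structure(
    list(
      quantity = quantity, dose_Gy = dose_Gy, reference = reference,
      peak_mode = peak_mode, var_equal = var_equal,
      curves = curves, peaks = peaks, reductions = reductions
    ),
    class = "flash_comparison"
  )
}

#' @export
print.flash_comparison <- function(x, ...) {
  cat(sprintf(
    "Group comparison of %s at %g Gy (reference: %s, %s t-test, no multiplicity correction)\n",
    x$quantity, x$dose_Gy, x$reference,
    if (x$var_equal) "pooled Student" else "Welch"
  ))
  print(x$reductions, ...)
  invisible(x)
}
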