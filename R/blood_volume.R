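# Irradiated-blood-volume model for the mouse ear: static blood held in the
# traced vessels of the field (cylinders in three diameter classes) plus the
# blood exchanged through entry veins during the irradiation.

#' Vessel diameter table
#'
#' Mean diameters of the three by-eye thickness classes of ear vessels, mm.
#' Defaults are the morphometric values for Balb/c pinnae (thick 0.09 mm,
#' middle 0.05 mm, thin 0.04 mm).
#'
#' @param thick,middle,thin Class diameters in mm, `thick >= middle >= thin > 0`.
#' @return Named numeric vector of diameters.
#' @export
vessel_diameters <- function(thick = 0.09, middle = 0.05, thin = 0.04) {
  d <- c(thick = thick, middle = middle, thin = thin)
  check_number(d, "diameters", min = 0, strict = TRUE)
  if (!(thick >= middle && middle >= thin)) {
    stop_invalid("diameters must satisfy thick >= middle >= thin.")
  }
  d
}

#' Polyline lengths of traced vessels
#'
#' Consumes segmented-line traces (ImageJ style): one point per row, ordered
#' by `point_index` within `vessel_id`. Length is the sum of Euclidean
#' distances between consecutive points.
#'
#' @param polylines Data frame with columns `vessel_id`, `point_index`,
#'   `x_mm`, `y_mm`.
#' @return Tibble with `vessel_id` and `length_mm`.
#' @export
#' @examples
#' pts <- tibble::tibble(vessel_id = "v1", point_index = 1:2,
#'                       x_mm = c(0, 3), y_mm = c(0, 4))
#' polyline_lengths(pts) # 5 mm
polyline_lengths <- function(polylines) {
  check_columns(polylines, c("vessel_id", "point_index", "x_mm", "y_mm"),
                "polyline table")
  if (anyNA(polylines$x_mm) || anyNA(polylines$y_mm) ||
      any(!is.finite(polylines$x_mm)) || any(!is.finite(polylines$y_mm))) {
    stop_invalid("polyline coordinates must be finite.",
                 class = "flashear_invalid_input")
  }
  res <- polylines |>
    dplyr::group_by(.data$vessel_id) |>
    dplyr::arrange(.data$point_index, .by_group = TRUE) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      length_mm = sum(sqrt(diff(.data$x_mm)^2 + diff(.data$y_mm)^2)),
      .groups = "drop"
    )
  if (any(res$n_points < 2)) {
    bad <- res$vessel_id[res$n_points < 2]
    stop_invalid(sprintf("vessel(s) %s have fewer than 2 points.",
                         paste(bad, collapse = ", ")),
                 class = "flashear_invalid_input")
  }
  dplyr::select(res, "vessel_id", "length_mm")
}

#' Static blood volume of traced vessels
#'
#' Models every traced vessel as a cylinder of its class diameter:
#' `V_static = sum over classes of pi d_class^2 / 4 * sum of lengths`.
#' A per-segment `diameter_mm` column, when present and non-missing,
#' overrides the class diameter for that segment.
#'
#' @param segments Data frame with columns `size_class` (thick/middle/thin)
#'   and `length_mm`; optional `diameter_mm` override.
#' @param diameters Named diameter table, see [vessel_diameters()].
#' @return Static volume in µl (1 µl = 1 mm³).
#' @export
#' @examples
#' static_volume(tibble::tibble(size_class = "thick", length_mm = 10))
static_volume <- function(segments, diameters = vessel_diameters()) {
  check_columns(segments, c("size_class", "length_mm"), "vessel segment table")
  if (nrow(segments) == 0) return(0)
  check_number(segments$length_mm, "length_mm", min = 0)
  cls <- tolower(as.character(segments$size_class))
  unknown <- which(!cls %in% names(diameters))
  if (length(unknown) > 0) {
    stop_data_format(sprintf(
      "unknown size_class '%s' in row(s) %s (expected %s).",
      segments$size_class[unknown[1]], paste(unknown, collapse = ", "),
      paste(names(diameters), collapse = "/")
    ))
  }
  d <- unname(diameters[cls])
  if ("diameter_mm" %in% names(segments)) {
    override <- !is.na(segments$diameter_mm)
    check_number(segments$diameter_mm[override], "diameter_mm",
                 min = 0, strict = TRUE, allow_zero_len = TRUE)
    d[override] <- segments$diameter_mm[override]
  }
  sum(pi * d^2 / 4 * segments$length_mm)
}

#' Blood flow volume through entry veins
#'
#' Blood exchanged with the field during the irradiation time: each entry
#' vein contributes its cross-section times the flow speed times the time,
#' `V_flow = sum_i pi d_i^2 / 4 * v * t`. Entry vessels are expected to be
#' thick or middle-thick veins; a `size_class` column of `"thin"` only warns.
#'
#' @param entry_veins Data frame with column `diameter_mm` (optional
#'   `size_class` for the eligibility warning).
#' @param time_s Irradiation time, s.
#' @param flow_speed_mm_s Venous blood flow speed, mm/s (about 2 mm/s in
#'   Balb/c ear veins).
#' @return Flow volume in µl.
#' @export
flow_volume <- function(entry_veins, time_s, flow_speed_mm_s = 2) {
  check_columns(entry_veins, "diameter_mm", "entry vein table")
  check_number(time_s, "time_s", min = 0)
  check_number(flow_speed_mm_s, "flow_speed_mm_s", min = 0)
  if (nrow(entry_veins) == 0) return(0)
  if (any(entry_veins$diameter_mm <= 0) || anyNA(entry_veins$diameter_mm)) {
    stop_invalid("entry vein diameters must be positive.",
                 class = "flashear_invalid_input")
  }
  if ("size_class" %in% names(entry_veins) &&
      any(tolower(entry_veins$size_class) == "thin")) {
    warn("thin vessels in the entry-vein list: only thick and middle-thick vessels are usually counted as entry veins.")
  }
  sum(pi * entry_veins$diameter_mm^2 / 4 * flow_speed_mm_s * time_s)
}

#' Irradiated blood volume
#'
#' The total blood exposed in one irradiation is the static volume plus the
#' flow volume: `V_irr = V_static + V_flow`.
#'
#' @param static_ul,flow_ul Component volumes, µl (>= 0).
#' @return Irradiated volume in µl.
#' @export
irradiated_volume <- function(static_ul, flow_ul) {
  check_number(static_ul, "static_ul", min = 0)
  check_number(flow_ul, "flow_ul", min = 0)
  static_ul + flow_ul
}

#' Total blood volume of a mouse
#'
#' Linear allometric scaling: Balb/c mice carry about 10.35 ml of blood per
#' 100 g of body weight.
#'
#' @param body_weight_g Body weight, g.
#' @param per_100g_ml Blood volume per 100 g body weight, ml.
#' @return Total blood volume in ml.
#' @export
#' @examples
#' total_blood_volume(19.2) # about 2 ml
total_blood_volume <- function(body_weight_g, per_100g_ml = 10.35) {
  check_number(body_weight_g, "body_weight_g", min = 0)
  check_number(per_100g_ml, "per_100g_ml", min = 0, strict = TRUE)
  body_weight_g * per_100g_ml / 100
}

#' Irradiated fraction of the total blood
#'
#' @param irradiated_ul Irradiated volume, µl.
#' @param total_blood_ml Total blood volume, ml.
#' @return Percentage of total blood irradiated.
#' @export
blood_fraction <- function(irradiated_ul, total_blood_ml) {
  check_number(irradiated_ul, "irradiated_ul", min = 0)
  check_number(total_blood_ml, "total_blood_ml", min = 0, strict = TRUE)
  100 * irradiated_ul / (total_blood_ml * 1000)
}

#' Mean dose to the irradiated blood
#'
#' Blood flowing through the field spends only part of the irradiation inside
#' it; the average dose to the exposed blood is the prescribed dose diluted by
#' the residence fraction: `D_blood = D * V_static / V_irr`. It equals the
#' prescribed dose when nothing flows (`V_irr == V_static`) and is strictly
#' smaller otherwise.
#'
#' @param total_dose_Gy Prescribed dose, Gy.
#' @param static_ul Static volume, µl (> 0).
#' @param irradiated_ul Irradiated volume, µl (>= static).
#' @return Mean blood dose in Gy, in `(0, total_dose_Gy]`.
#' @export
#' @examples
#' mean_blood_dose(33, 0.20, 27) # about 0.24 Gy
mean_blood_dose <- function(total_dose_Gy, static_ul, irradiated_ul) {
  check_number(total_dose_Gy, "total_dose_Gy", min = 0)
  check_number(static_ul, "static_ul", min = 0, strict = TRUE)
  check_number(irradiated_ul, "irradiated_ul", min = 0, strict = TRUE)
  if (any(irradiated_ul < static_ul * (1 - 1e-12))) {
    stop_invalid("`irradiated_ul` cannot be smaller than `static_ul`.",
                 class = "flashear_invalid_input")
  }
  total_dose_Gy * static_ul / irradiated_ul
}

#' Full blood-volume estimate for one traced ear
#'
#' Chains the static, flow, irradiated-volume, blood-fraction and mean-dose
#' steps for one vessel trace across one or more irradiation durations.
#'
#' @param segments Vessel segment table (see [static_volume()]).
#' @param entry_veins Entry vein table (see [flow_volume()]).
#' @param time_s Irradiation times, s (vectorised; one row per time).
#' @param label Optional labels for the times (recycled).
#' @param dose_Gy Prescribed dose, Gy.
#' @param flow_speed_mm_s Blood flow speed, mm/s.
#' @param diameters Class diameter table.
#' @param body_weight_g,per_100g_ml Total-blood-volume scaling.
#' @return A tibble of class `blood_volume_estimate`, one row per time, with
#'   `static_ul`, `flow_ul`, `irradiated_ul`, `blood_fraction_pct`,
#'   `mean_blood_dose_Gy`.
#' @export
#' @examples
#' segs <- tibble::tibble(size_class = "thick", length_mm = 10)
#' veins <- tibble::tibble(diameter_mm = rep(0.09, 4))
#' estimate_blood_volume(segs, veins, time_s = c(0.035, 550.2))
estimate_blood_volume <- function(segments, entry_veins, time_s,
                                  label = NULL, dose_Gy = 33,
                                  flow_speed_mm_s = 2,
                                  diameters = vessel_diameters(),
                                  body_weight_g = 19.2, per_100g_ml = 10.35) {
  v_static <- static_volume(segments, diameters)
  total_ml <- total_blood_volume(body_weight_g, per_100g_ml)
  if (is.null(label)) label <- sprintf("t=%gs", time_s)
  res <- tibble(
    label = rep_len(label, length(time_s)),
    time_s = time_s,
    static_ul = v_static,
    flow_ul = purrr::map_dbl(time_s, \(t) flow_volume(entry_veins, t, flow_speed_mm_s))
  ) |>
    dplyr::mutate(
      irradiated_ul = irradiated_volume(.data$static_ul, .data$flow_ul),
      total_blood_ml = total_ml,
      blood_fraction_pct = blood_fraction(.data$irradiated_ul, total_ml),
      total_dose_Gy = dose_Gy,
      mean_blood_dose_Gy = mean_blood_dose(dose_Gy, .data$static_ul, .data$irradiated_ul)
    )
  class(res) <- c("blood_volume_estimate", class(res))
  res
}

#' Across-replicate summary of blood-volume estimates
#'
#' Combines per-ear replicate estimates (one [estimate_blood_volume()] result
#' per traced ear) into mean, standard deviation and standard error per
#' irradiation mode. With fewer than two replicates the spread statistics are
#' reported as missing, never as zero. For the blood fraction, a first-order
#' (delta-method) SD propagated from the irradiated-volume spread is also
#' reported.
#'
#' @param estimates A `blood_volume_estimate` tibble with one row per
#'   replicate and time (stack replicates with [dplyr::bind_rows()], adding a
#'   `replicate` identifier if desired).
#' @return Tibble with per-label mean/sd/sem of each volume component and the
#'   blood fraction.
#' @export
replicate_summary <- function(estimates) {
  check_columns(estimates,
                c("label", "static_ul", "flow_ul", "irradiated_ul",
                  "blood_fraction_pct", "total_blood_ml"),
                "blood-volume estimate table")
  sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  estimates |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        c("static_ul", "flow_ul", "irradiated_ul", "blood_fraction_pct"),
        list(mean = mean, sd = sd_or_na, sem = \(x) sd_or_na(x) / sqrt(length(x)))
      ),
      total_blood_ml = .data$total_blood_ml[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      # delta-method SD of the fraction treating total blood as fixed
      blood_fraction_pct_sd_propagated =
        100 * .data$irradiated_ul_sd / (.data$total_blood_ml * 1000)
    )
}
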