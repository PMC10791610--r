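# Synthetic cohorts, vessel traces and qPCR plates with known ground truth.
# The generators emulate the structure of the study's longitudinal monitoring
# table, its traced vessel morphometry and its cytokine Ct plates, so every
# downstream stage can be validated against injected truth.

#' Default group table of the study design
#'
#' Dose (Gy), dose-rate label and group size per arm, including the sham arm.
#'
#' @return Tibble with `dose_Gy`, `dose_rate_label`, `n`.
#' @export
flash_groups <- function() {
  tibble(
    dose_Gy = c(23, 33, 23, 33, 23, 33, 0),
    dose_rate_label = c("Conv", "Conv", "Flash9", "Flash9",
                        "Flash930", "Flash930", "Sham"),
    n = c(7, 7, 9, 3, 7, 9, 7)
  )
}

default_response <- function() {
  tibble(
    dose_Gy = c(33, 33, 33, 23, 23, 23, 0),
    dose_rate_label = c("Conv", "Flash9", "Flash930",
                        "Conv", "Flash9", "Flash930", "Sham"),
    # peak swelling amplitudes (µm); the 33 Gy FLASH amplitudes encode true
    # reductions of exactly 57 % (Flash9) and 40 % (Flash930) vs Conv
    amplitude_um = c(155, 66.65, 93, 49, 40, 30, 0)
  )
}

#' Synthetic-study scenario
#'
#' Bundles every ground-truth parameter of the generators: group sizes,
#' baseline ear thickness and measurement noise, per-group swelling response
#' (amplitude, onset/peak timing, gamma-shaped time course), thresholds that
#' convert noiseless swelling into ordinal skin grades, the qPCR design
#' (genes, baseline dCt, injected log2 fold changes, Ct noise) and the vessel
#' trace spec (per-class total lengths calibrated to a 0.20 µl static volume,
#' four 0.09 mm entry veins).
#'
#' @param groups Group table, see [flash_groups()].
#' @param baseline_um Baseline ear thickness, µm.
#' @param noise_sd_um Gaussian thickness measurement noise SD, µm.
#' @param response Per-group response amplitudes (tibble like
#'   `default_response()`).
#' @param onset_day,peak_day Response onset and peak days.
#' @param shape Gamma shape parameter of the response curve (> 1).
#' @param followup_days Length of the monitoring period, days.
#' @param erythema_cuts,desquamation_cuts Named swelling thresholds (µm of
#'   noiseless swelling) above which each ordinal grade is assigned.
#' @param qpcr_genes Target genes assayed.
#' @param qpcr_log2fc Injected true log2 fold change, either a single number
#'   for all gene/group/day cells or a tibble with `gene`, `group`, `day`,
#'   `log2_fc`.
#' @param qpcr_ct_sd Within-well replicate Ct noise SD, cycles.
#' @param qpcr_sample_sd Between-sample biological Ct noise SD, cycles.
#' @param qpcr_days Blood sampling days.
#' @param vessel_lengths_mm Named per-class total trace length, mm.
#' @param entry_veins Entry-vein spec tibble (`diameter_mm`).
#' @param field_mm Side length of the square irradiation field, mm.
#' @return A list of class `flash_scenario`.
#' @export
flash_scenario <- function(groups = flash_groups(),
                           baseline_um = 230,
                           noise_sd_um = 25,
                           response = default_response(),
                           onset_day = 12, peak_day = 23, shape = 5,
                           followup_days = 180,
                           erythema_cuts = c(mild = 40, definite = 120, severe = 250),
                           desquamation_cuts = c(dry = 100, `crust formation` = 160,
                                                 moist = 250),
                           qpcr_genes = c("TGF-b1", "TNF-a", "IL1a", "IL1b"),
                           qpcr_log2fc = 0,
                           qpcr_ct_sd = 0.2,
                           qpcr_sample_sd = 0.4,
                           qpcr_days = c(7, 21, 28, 180),
                           vessel_lengths_mm = c(thick = 12, middle = 35,
                                                 thin = 43.72),
                           entry_veins = tibble(diameter_mm = rep(0.09, 4)),
                           field_mm = 6.5) {
  check_number(baseline_um, "baseline_um", min = 0, strict = TRUE)
  check_number(noise_sd_um, "noise_sd_um", min = 0)
  check_number(peak_day, "peak_day", min = 0)
  if (peak_day > followup_days || onset_day >= peak_day) {
    stop_invalid("need onset_day < peak_day <= followup_days.",
                 class = "flashear_configuration")
  }
  if (any(groups$n < 1)) {
    stop_invalid("every group needs n >= 1 mice.", class = "flashear_configuration")
  }
  structure(
    list(
      groups = groups, baseline_um = baseline_um, noise_sd_um = noise_sd_um,
      response = response, onset_day = onset_day, peak_day = peak_day,
      shape = shape, followup_days = followup_days,
      erythema_cuts = erythema_cuts, desquamation_cuts = desquamation_cuts,
      qpcr_genes = qpcr_genes, qpcr_log2fc = qpcr_log2fc,
      qpcr_ct_sd = qpcr_ct_sd, qpcr_sample_sd = qpcr_sample_sd,
      qpcr_days = qpcr_days,
      vessel_lengths_mm = vessel_lengths_mm, entry_veins = entry_veins,
      field_mm = field_mm
    ),
    class = "flash_scenario"
  )
}

#' Unimodal response curve
#'
#' Gamma-kernel time course of the skin reaction: zero before `onset_day`,
#' rising to 1 at `peak_day`, decaying towards zero afterwards (effectively
#' zero again by about day 60 with the defaults).
#'
#' @param day Days since irradiation.
#' @param onset_day,peak_day,shape Curve landmarks, see [flash_scenario()].
#' @return Values in `[0, 1]`, equal to 1 at `peak_day`.
#' @export
response_curve <- function(day, onset_day = 12, peak_day = 23, shape = 5) {
  x <- pmax(day - onset_day, 0)
  xm <- peak_day - onset_day
  theta <- xm / (shape - 1)
  ifelse(x == 0, 0, (x / xm)^(shape - 1) * exp((xm - x) / theta))
}

grade_from_swelling <- function(swelling, cuts, none = "No") {
  labels <- c(none, names(cuts))
  display <- c(
    "no" = "No", "mild" = "Mild", "definite" = "Definite", "severe" = "Severe",
    "dry" = "Dry", "crust formation" = "Crust formation", "moist" = "Moist"
  )
  idx <- rowSums(outer(swelling, unname(cuts), `>=`)) + 1
  unname(display[tolower(labels[idx])])
}

sample_days <- function(followup_days) {
  days <- 0
  while (days[length(days)] < followup_days) {
    days <- c(days, days[length(days)] + sample(2:7, 1))
  }
  days[days <= followup_days]
}

#' Simulate a longitudinal cohort
#'
#' Generates per-mouse ear-thickness series and ordinal skin grades:
#' measurement days drawn every 2-7 days over the follow-up; thickness
#' `ET(day) = baseline + A_group * g(day) + N(0, noise_sd)` with `g` the
#' [response_curve()]; erythema and desquamation grades by thresholding the
#' noiseless swelling `A_group * g(day)`. Fully reproducible given the seed;
#' the generator draws from its own seed stream, so producing the other
#' synthetic datasets never perturbs the cohort.
#'
#' @param scenario A [flash_scenario()].
#' @param seed Integer master seed.
#' @return Measurement tibble (`mouse_id`, `dose_Gy`, `dose_rate_label`,
#'   `day`, `ear_thickness_um`, `erythema`, `desquamation`) with the injected
#'   truth (amplitudes and implied reductions) in `attr(, "truth")`.
#' @export
simulate_cohort <- function(scenario = flash_scenario(), seed = 1) {
  if (!inherits(scenario, "flash_scenario")) {
    stop_invalid("`scenario` must be a flash_scenario().",
                 class = "flashear_configuration")
  }
  groups <- dplyr::left_join(scenario$groups, scenario$response,
                             by = c("dose_Gy", "dose_rate_label"))
  if (anyNA(groups$amplitude_um)) {
    stop_invalid("every group needs a response amplitude in the scenario.",
                 class = "flashear_configuration")
  }
  measurements <- withr::with_seed(derive_seed(seed, "cohort"), {
    mice <- groups |>
      tidyr::uncount(.data$n, .id = "mouse_no") |>
      dplyr::select(-dplyr::any_of("n")) |>
      dplyr::mutate(mouse_id = sprintf("m%02d", dplyr::row_number()))
    purrr::pmap_dfr(mice, function(dose_Gy, dose_rate_label, mouse_no,
                                   mouse_id, amplitude_um) {
      days <- sample_days(scenario$followup_days)
      g <- response_curve(days, scenario$onset_day, scenario$peak_day,
                          scenario$shape)
      true_swelling <- amplitude_um * g
      tibble(
        mouse_id = mouse_id, dose_Gy = dose_Gy,
        dose_rate_label = dose_rate_label, day = days,
        ear_thickness_um = scenario$baseline_um + true_swelling +
          stats::rnorm(length(days), 0, scenario$noise_sd_um),
        erythema = grade_from_swelling(true_swelling, scenario$erythema_cuts),
        desquamation = grade_from_swelling(true_swelling,
                                           scenario$desquamation_cuts)
      )
    })
  })
  conv33 <- groups$amplitude_um[groups$dose_rate_label == "Conv" &
                                  groups$dose_Gy == 33]
  truth <- list(
    amplitudes = dplyr::select(groups, "dose_Gy", "dose_rate_label", "n",
                               "amplitude_um"),
    baseline_um = scenario$baseline_um,
    noise_sd_um = scenario$noise_sd_um,
    peak_day = scenario$peak_day,
    reductions_33Gy = if (length(conv33) == 1 && conv33 > 0) {
      groups |>
        dplyr::filter(.data$dose_Gy == 33, .data$dose_rate_label != "Conv") |>
        dplyr::transmute(
          group = .data$dose_rate_label,
          true_reduction_percent = 100 * (1 - .data$amplitude_um / conv33)
        )
    } else NULL
  )
  attr(measurements, "truth") <- truth
  measurements
}

# Random polyline of exactly `length_mm` inside the square field: a smooth
# random walk whose step lengths sum to the target. The walk is generated
# unconstrained and placed inside the field by translation only (rejection on
# the bounding box), so the requested length is preserved exactly; a straight
# diagonal path is the deterministic fallback for walks too sprawling to fit.
random_polyline <- function(length_mm, field_mm, n_steps = 8) {
  w <- stats::rgamma(n_steps, shape = 4)
  steps <- length_mm * w / sum(w)
  for (try in seq_len(50)) {
    turns <- c(0, stats::rnorm(n_steps - 1, 0, 0.6))
    angles <- stats::runif(1, 0, 2 * pi) + cumsum(turns)
    x <- c(0, cumsum(steps * cos(angles)))
    y <- c(0, cumsum(steps * sin(angles)))
    wx <- diff(range(x))
    wy <- diff(range(y))
    if (wx < field_mm && wy < field_mm) {
      ox <- stats::runif(1, 0, field_mm - wx) - min(x)
      oy <- stats::runif(1, 0, field_mm - wy) - min(y)
      return(cbind(x + ox, y + oy))
    }
  }
  u <- 1 / sqrt(2)
  cbind(c(0, cumsum(steps * u)), c(0, cumsum(steps * u)))
}

#' Simulate a traced vessel field
#'
#' Generates random vessel polylines inside the square irradiation field with
#' per-class total lengths exactly as requested, plus the entry-vein table and
#' the analytically known static volume.
#'
#' @param scenario A [flash_scenario()].
#' @param seed Integer master seed.
#' @return List with `polylines` (vessel_id, point_index, x_mm, y_mm),
#'   `segments` (vessel_id, size_class, length_mm), `entry_veins`, and
#'   `truth$static_ul` (closed-form static volume of the generated trace).
#' @export
simulate_vessels <- function(scenario = flash_scenario(), seed = 1) {
  lengths <- scenario$vessel_lengths_mm
  check_number(lengths, "vessel_lengths_mm", min = 0)
  withr::with_seed(derive_seed(seed, "vessels"), {
    per_vessel <- c(thick = 4, middle = 5, thin = 6) # mm, target per polyline
    rows <- purrr::imap_dfr(lengths, function(total, cls) {
      if (total <= 0) return(tibble())
      n <- max(1, round(total / per_vessel[[cls]]))
      li <- rep(total / n, n)
      tibble(size_class = cls, length_mm = li)
    })
    if (nrow(rows) == 0) {
      segments <- tibble(vessel_id = character(), size_class = character(),
                         length_mm = numeric())
      polylines <- tibble(vessel_id = character(), point_index = integer(),
                          x_mm = numeric(), y_mm = numeric())
    } else {
      rows <- dplyr::mutate(rows, vessel_id = sprintf("v%02d", dplyr::row_number()))
      polylines <- purrr::pmap_dfr(rows, function(size_class, length_mm, vessel_id) {
        pos <- random_polyline(length_mm, scenario$field_mm)
        tibble(vessel_id = vessel_id, point_index = seq_len(nrow(pos)),
               x_mm = pos[, 1], y_mm = pos[, 2])
      })
      segments <- dplyr::select(rows, "vessel_id", "size_class", "length_mm")
    }
    list(
      polylines = polylines,
      segments = segments,
      entry_veins = scenario$entry_veins,
      truth = list(static_ul = static_volume(segments))
    )
  })
}

resolve_log2fc <- function(scenario, grid) {
  spec <- scenario$qpcr_log2fc
  if (is.numeric(spec) && length(spec) == 1) {
    return(dplyr::mutate(grid, log2_fc = spec))
  }
  check_columns(spec, c("gene", "group", "day", "log2_fc"), "qpcr_log2fc spec")
  if (!all(spec$gene %in% scenario$qpcr_genes)) {
    stop_invalid("qpcr_log2fc names a gene not in the scenario's gene list.",
                 class = "flashear_configuration")
  }
  grid |>
    dplyr::left_join(spec, by = c("gene", "group", "day")) |>
    dplyr::mutate(log2_fc = dplyr::coalesce(.data$log2_fc, 0))
}

#' Simulate a qPCR Ct plate
#'
#' Triplicate Ct wells for the target cytokines and both housekeeping genes,
#' for every 33 Gy mouse and sham mouse at each blood-sampling day. Per
#' sample, the housekeeping level is drawn as `N(base, sample_sd)`; each
#' target's true Ct is the housekeeping Ct plus a gene-specific baseline dCt
#' minus the injected log2 fold change (sham cells always 0); wells add
#' `N(0, ct_sd)` replicate noise.
#'
#' @param scenario A [flash_scenario()].
#' @param seed Integer master seed.
#' @return Wide Ct tibble (`sample_id`, `mouse_id`, `group`, `day`, `gene`,
#'   `ct_rep1..3`) with the injected truth table in `attr(, "truth")`.
#' @export
simulate_qpcr <- function(scenario = flash_scenario(), seed = 1) {
  hk_base <- c(B2M = 18, GAPDH = 16)
  dct0 <- stats::setNames(
    seq(4, by = 1.5, length.out = length(scenario$qpcr_genes)),
    scenario$qpcr_genes
  )
  groups <- scenario$groups |>
    dplyr::filter(.data$dose_Gy == 33 | .data$dose_rate_label == "Sham")
  withr::with_seed(derive_seed(seed, "qpcr"), {
    mice <- groups |>
      tidyr::uncount(.data$n, .id = "mouse_no") |>
      dplyr::select(-dplyr::any_of("n")) |>
      dplyr::mutate(mouse_id = sprintf("q%02d", dplyr::row_number()))
    grid <- tidyr::expand_grid(
      mice |> dplyr::select("mouse_id", group = "dose_rate_label"),
      day = scenario$qpcr_days,
      gene = scenario$qpcr_genes
    )
    truth <- resolve_log2fc(scenario, dplyr::distinct(
      grid, .data$group, .data$day, .data$gene
    )) |>
      dplyr::mutate(log2_fc = ifelse(.data$group == "Sham", 0, .data$log2_fc))

    samples <- grid |>
      dplyr::distinct(.data$mouse_id, .data$group, .data$day) |>
      dplyr::mutate(
        sample_id = sprintf("%s_d%d", .data$mouse_id, .data$day),
        hk_level = stats::rnorm(dplyr::n(), 0, scenario$qpcr_sample_sd)
      )

    wells <- grid |>
      dplyr::left_join(samples, by = c("mouse_id", "group", "day")) |>
      dplyr::left_join(truth, by = c("group", "day", "gene")) |>
      dplyr::mutate(
        true_ct = .data$hk_level + mean(hk_base) + dct0[.data$gene] - .data$log2_fc
      )
    hk_wells <- samples |>
      tidyr::expand_grid(gene = names(hk_base)) |>
      dplyr::mutate(true_ct = .data$hk_level + hk_base[.data$gene])

    all_wells <- dplyr::bind_rows(
      dplyr::select(wells, "sample_id", "mouse_id", "group", "day", "gene",
                    "true_ct"),
      dplyr::select(hk_wells, "sample_id", "mouse_id", "group", "day", "gene",
                    "true_ct")
    )
    out <- all_wells |>
      dplyr::mutate(
        ct_rep1 = .data$true_ct + stats::rnorm(dplyr::n(), 0, scenario$qpcr_ct_sd),
        ct_rep2 = .data$true_ct + stats::rnorm(dplyr::n(), 0, scenario$qpcr_ct_sd),
        ct_rep3 = .data$true_ct + stats::rnorm(dplyr::n(), 0, scenario$qpcr_ct_sd)
      ) |>
      dplyr::select(-"true_ct") |>
      dplyr::arrange(.data$sample_id, .data$gene)
    attr(out, "truth") <- truth
    out
  })
}
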