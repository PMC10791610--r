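# Pulsed proton-beam dosimetry: current/LET/field -> dose rate, chopper pulse
# timing -> duty cycle, and irradiation durations for a prescribed dose.

ELEMENTARY_CHARGE_C <- 1.602176634e-19

#' Dose rate delivered by a proton current
#'
#' Converts a beam current into an absorbed dose rate in a thin target slab:
#' the proton rate is `current / e`, each proton deposits `LET` per unit path,
#' and the energy is absorbed by the mass `area * density` per unit path
#' length. All unit conversions live here; the result is exactly linear in
#' current and LET and inverse-linear in area and density.
#'
#' @param current_nA Beam current at the target, nanoamperes (may be 0).
#' @param let_keV_um Linear energy transfer, keV/µm.
#' @param field_area_mm2 Irradiated field area, mm².
#' @param density_g_cm3 Mass density of the medium, g/cm³ (water-equivalent
#'   tissue by default).
#' @return Dose rate in Gy/s.
#' @export
#' @examples
#' dose_rate_from_current(15, 2.6, 42) # about 930 Gy/s
dose_rate_from_current <- function(current_nA, let_keV_um, field_area_mm2,
                                   density_g_cm3 = 1) {
  check_number(current_nA, "current_nA", min = 0)
  check_number(let_keV_um, "let_keV_um", min = 0, strict = TRUE)
  check_number(field_area_mm2, "field_area_mm2", min = 0, strict = TRUE)
  check_number(density_g_cm3, "density_g_cm3", min = 0, strict = TRUE)

  protons_per_s <- current_nA * 1e-9 / ELEMENTARY_CHARGE_C
  # keV/µm -> J/mm: 1e3 eV/keV * 1e3 µm/mm * e J/eV
  let_J_mm <- let_keV_um * 1e6 * ELEMENTARY_CHARGE_C
  # g/cm³ -> kg/mm³ is 1e-6; mass per mm of path in the field:
  mass_kg_per_mm <- field_area_mm2 * density_g_cm3 * 1e-6
  protons_per_s * let_J_mm / mass_kg_per_mm
}

#' Pulse-to-pulse distance of a chopped beam
#'
#' A chopper passing every `frequency_partition`-th pulse of a
#' `base_frequency_MHz` pulse train stretches the pulse period to
#' `partition / base_frequency`.
#'
#' @param base_frequency_MHz Base pulse frequency, MHz.
#' @param frequency_partition Integer divider (a power of two on the hardware,
#'   any integer >= 1 accepted).
#' @return Pulse-to-pulse distance in µs.
#' @export
#' @examples
#' chopper_period(5, 2^6) # 12.8 µs
chopper_period <- function(base_frequency_MHz, frequency_partition) {
  check_number(base_frequency_MHz, "base_frequency_MHz", min = 0, strict = TRUE)
  check_number(frequency_partition, "frequency_partition", min = 1)
  frequency_partition / base_frequency_MHz
}

#' Mean dose rate of a pulsed beam
#'
#' The mean rate is the in-pulse (peak) rate scaled by the duty cycle
#' `pulse_width / pulse_period`. A continuous beam has `width == period` and
#' mean equal to peak.
#'
#' @param peak_rate_Gy_s Dose rate inside a pulse, Gy/s.
#' @param pulse_width_ns Pulse (beam-on) width, ns.
#' @param pulse_period_us Pulse-to-pulse distance, µs.
#' @return Mean dose rate in Gy/s, never above the peak rate.
#' @export
#' @examples
#' mean_dose_rate(930, 128, 12.8) # 9.3 Gy/s
mean_dose_rate <- function(peak_rate_Gy_s, pulse_width_ns, pulse_period_us) {
  check_number(peak_rate_Gy_s, "peak_rate_Gy_s", min = 0)
  check_number(pulse_width_ns, "pulse_width_ns", min = 0, strict = TRUE)
  check_number(pulse_period_us, "pulse_period_us", min = 0, strict = TRUE)
  if (any(pulse_width_ns * 1e-3 > pulse_period_us * (1 + 1e-12))) {
    stop_invalid("`pulse_width_ns` must not exceed `pulse_period_us`.")
  }
  peak_rate_Gy_s * (pulse_width_ns * 1e-3) / pulse_period_us
}

#' Irradiation time for a prescribed dose
#'
#' @param total_dose_Gy Prescribed dose, Gy.
#' @param mean_rate_Gy_s Mean dose rate, Gy/s (> 0).
#' @return Duration in seconds (divide by 60 for minutes).
#' @export
#' @examples
#' duration_for_dose(33, 9.3) # 3.548... s
duration_for_dose <- function(total_dose_Gy, mean_rate_Gy_s) {
  check_number(total_dose_Gy, "total_dose_Gy", min = 0)
  check_number(mean_rate_Gy_s, "mean_rate_Gy_s", min = 0, strict = TRUE)
  total_dose_Gy / mean_rate_Gy_s
}

#' Build a beam configuration table
#'
#' One row per irradiation mode. Pulsed modes need the chopper pulse width and
#' period; continuous modes have duty cycle 1.
#'
#' @param label Mode label (e.g. `"Flash930"`).
#' @param mode `"continuous"` or `"pulsed"`.
#' @param peak_current_nA In-pulse beam current at the target, nA.
#' @param energy_MeV Proton energy, MeV (informational).
#' @param let_keV_um Linear energy transfer, keV/µm.
#' @param field_area_mm2 Field area, mm².
#' @param density_g_cm3 Target density, g/cm³.
#' @param pulse_width_ns Pulse width, ns (pulsed only, `NA` otherwise).
#' @param pulse_period_us Pulse-to-pulse distance, µs (pulsed only).
#' @return A tibble with one row per mode.
#' @export
beam_config <- function(label, mode = c("continuous", "pulsed"),
                        peak_current_nA, energy_MeV = 20, let_keV_um = 2.6,
                        field_area_mm2 = 42, density_g_cm3 = 1,
                        pulse_width_ns = NA_real_, pulse_period_us = NA_real_) {
  mode <- match.arg(mode)
  check_number(peak_current_nA, "peak_current_nA", min = 0)
  if (mode == "pulsed") {
    check_number(pulse_width_ns, "pulse_width_ns", min = 0, strict = TRUE)
    check_number(pulse_period_us, "pulse_period_us", min = 0, strict = TRUE)
    if (pulse_width_ns * 1e-3 > pulse_period_us) {
      stop_invalid("`pulse_width_ns` must not exceed `pulse_period_us`.")
    }
  }
  tibble(
    label = label, mode = mode, peak_current_nA = peak_current_nA,
    energy_MeV = energy_MeV, let_keV_um = let_keV_um,
    field_area_mm2 = field_area_mm2, density_g_cm3 = density_g_cm3,
    pulse_width_ns = pulse_width_ns, pulse_period_us = pulse_period_us
  )
}

#' Default beam configurations of the three irradiation modes
#'
#' Flash930 runs the full 15 nA current continuously; Flash9 chops it with a
#' 128 ns pulse every 12.8 µs (partition 2^6 of the 5 MHz train, duty 1/100);
#' Conv lowers the in-pulse current to 0.4 nA and stretches the period to
#' 51.2 µs (partition 2^8, duty 1/400).
#'
#' @return A three-row beam configuration tibble.
#' @export
flash_beams <- function() {
  dplyr::bind_rows(
    beam_config("Flash930", "continuous", peak_current_nA = 15),
    beam_config("Flash9", "pulsed", peak_current_nA = 15,
                pulse_width_ns = 128, pulse_period_us = chopper_period(5, 2^6)),
    beam_config("Conv", "pulsed", peak_current_nA = 0.4,
                pulse_width_ns = 128, pulse_period_us = chopper_period(5, 2^8))
  )
}

#' Derive an irradiation plan from beam configurations
#'
#' For each configured mode, computes the peak dose rate from the in-pulse
#' current, the mean dose rate from the chopper duty cycle, and the time
#' needed to deliver `dose_Gy`.
#'
#' @param beams A beam configuration tibble, see [beam_config()].
#' @param dose_Gy Prescribed dose, Gy.
#' @return A tibble with one row per mode: peak/mean dose rate (Gy/s), duty
#'   cycle, duration in seconds and minutes.
#' @export
#' @examples
#' irradiation_plan(flash_beams(), dose_Gy = 33)
irradiation_plan <- function(beams, dose_Gy = 33) {
  check_columns(beams, c("label", "mode", "peak_current_nA", "let_keV_um",
                         "field_area_mm2", "density_g_cm3"),
                "beam configuration")
  check_number(dose_Gy, "dose_Gy", min = 0)
  beams |>
    dplyr::rowwise() |>
    dplyr::mutate(
      peak_dose_rate_Gy_s = dose_rate_from_current(
        .data$peak_current_nA, .data$let_keV_um,
        .data$field_area_mm2, .data$density_g_cm3
      ),
      duty_cycle = ifelse(
        .data$mode == "continuous", 1,
        (.data$pulse_width_ns * 1e-3) / .data$pulse_period_us
      ),
      mean_dose_rate_Gy_s = .data$peak_dose_rate_Gy_s * .data$duty_cycle,
      mean_current_nA = .data$peak_current_nA * .data$duty_cycle,
      total_dose_Gy = dose_Gy,
      duration_s = ifelse(
        .data$mean_dose_rate_Gy_s > 0,
        dose_Gy / .data$mean_dose_rate_Gy_s, NA_real_
      ),
      duration_min = .data$duration_s / 60
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "label", "mode", "peak_current_nA", "mean_current_nA",
      "peak_dose_rate_Gy_s", "mean_dose_rate_Gy_s", "duty_cycle",
      "total_dose_Gy", "duration_s", "duration_min"
    )
}
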