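# Validated CSV readers/writers for the measurement, vessel and Ct tables,
# and the umbrella pipeline that chains the analysis stages into one report.

# Normalize European decimal commas ("0,001") that sometimes survive in
# exported tables; warns once per column.
normalize_decimal <- function(x, column, path) {
  if (is.numeric(x)) return(x)
  x_chr <- stringr::str_squish(as.character(x))
  if (any(grepl(",", x_chr))) {
    warn(sprintf("column '%s' in %s uses decimal commas; normalizing to '.'.",
                 column, path))
    x_chr <- gsub(",", ".", x_chr, fixed = TRUE)
  }
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- which(!is.na(x_chr) & x_chr != "" & is.na(out))
  if (length(bad) > 0) {
    stop_data_format(sprintf(
      "column '%s' in %s has unparseable number '%s' in row %d.",
      column, path, x_chr[bad[1]], bad[1]
    ))
  }
  out
}

read_validated_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    stop_data_format(sprintf("%s file not found: %s.", what, path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, sprintf("%s file %s", what, path))
  df
}

#' Read a longitudinal measurement table
#'
#' One row per mouse and monitoring day. Validates the schema, rejects
#' duplicate mouse-day rows, checks ordinal levels against [score_table()]
#' and normalizes decimal commas.
#'
#' @param path CSV with columns `mouse_id,dose_Gy,dose_rate_label,day,
#'   ear_thickness_um,erythema,desquamation`.
#' @return Validated measurement tibble.
#' @export
read_measurements <- function(path) {
  cols <- c("mouse_id", "dose_Gy", "dose_rate_label", "day",
            "ear_thickness_um", "erythema", "desquamation")
  df <- read_validated_csv(path, cols, "measurement")
  for (col in c("dose_Gy", "day", "ear_thickness_um")) {
    df[[col]] <- normalize_decimal(df[[col]], col, path)
  }
  dup <- duplicated(df[c("mouse_id", "day")])
  if (any(dup)) {
    stop_data_format(sprintf(
      "duplicate mouse-day row(s) in %s: row(s) %s.",
      path, paste(which(dup), collapse = ", ")
    ))
  }
  if (any(df$ear_thickness_um <= 0, na.rm = TRUE)) {
    stop_data_format(sprintf("non-positive ear thickness in %s.", path))
  }
  # validates the vocabulary; errors carry the offending row and column
  invisible(inflammation_score(df$erythema, df$desquamation))
  df
}

#' Write a measurement table
#' @param measurements Measurement tibble.
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(measurements)
}

#' Read a vessel segment table
#' @param path CSV with columns `vessel_id,size_class,length_mm` (or
#'   `vessel_id,size_class` plus a companion polyline file, see
#'   [read_polylines()]).
#' @return Validated segment tibble.
#' @export
read_vessel_segments <- function(path) {
  df <- read_validated_csv(path, c("vessel_id", "size_class"), "vessel trace")
  if ("length_mm" %in% names(df)) {
    df$length_mm <- normalize_decimal(df$length_mm, "length_mm", path)
  }
  df
}

#' Read a polyline coordinate table
#' @param path CSV with columns `vessel_id,point_index,x_mm,y_mm` (segmented
#'   -line export, one point per row).
#' @return Validated polyline tibble.
#' @export
read_polylines <- function(path) {
  df <- read_validated_csv(path, c("vessel_id", "point_index", "x_mm", "y_mm"),
                           "polyline")
  for (col in c("x_mm", "y_mm")) df[[col]] <- normalize_decimal(df[[col]], col, path)
  df
}

#' Read an entry-vein table
#' @param path CSV with columns `vein_id,diameter_mm`.
#' @return Validated entry-vein tibble.
#' @export
read_entry_veins <- function(path) {
  df <- read_validated_csv(path, c("vein_id", "diameter_mm"), "entry vein")
  df$diameter_mm <- normalize_decimal(df$diameter_mm, "diameter_mm", path)
  if (any(df$diameter_mm <= 0, na.rm = TRUE)) {
    stop_data_format(sprintf("non-positive vein diameter in %s.", path))
  }
  df
}

#' Read a qPCR Ct table
#' @param path CSV, wide (`sample_id,mouse_id,group,day,gene,ct_rep1..3`) or
#'   long (`...,replicate,ct`).
#' @return Validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  df <- read_validated_csv(path, c("sample_id", "mouse_id", "group", "day", "gene"),
                           "Ct")
  num_cols <- intersect(c(grep("^ct_rep", names(df), value = TRUE), "ct", "day"),
                        names(df))
  for (col in num_cols) df[[col]] <- normalize_decimal(df[[col]], col, path)
  invisible(tidy_ct(df))
  df
}

stage_inputs <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Chains the stages present in the configuration — beam dosimetry,
#' blood-volume estimation, swelling/score comparison and qPCR fold-change
#' analysis — and optionally writes a machine-readable report bundle
#' (`report.json` plus tidy CSVs) to `out_dir`. Each input may be a path to a
#' CSV or an in-memory data frame. The report records the seed and a hash of
#' the configuration, so identical configurations reproduce identical reports.
#'
#' @param measurements Measurement table or path (enables the swelling and
#'   score comparisons).
#' @param segments,entry_veins Vessel trace inputs or paths (enable the
#'   blood-volume stage).
#' @param polylines Optional polyline table or path; lengths computed via
#'   [polyline_lengths()] are joined onto `segments`.
#' @param ct Ct table or path (enables the qPCR stage).
#' @param beams Beam configuration tibble (default [flash_beams()]).
#' @param dose_Gy Prescribed dose used for the plan, blood dose and group
#'   comparison.
#' @param reference Reference dose-rate group.
#' @param flow_speed_mm_s Blood flow speed for the flow volume.
#' @param seed Seed recorded in the report metadata.
#' @param out_dir Optional output directory for the report bundle.
#' @return List with `metadata` and the per-stage results (`beam`,
#'   `blood_volume`, `swelling`, `score`, `qpcr`).
#' @export
run_pipeline <- function(measurements = NULL, segments = NULL,
                         entry_veins = NULL, polylines = NULL, ct = NULL,
                         beams = flash_beams(), dose_Gy = 33,
                         reference = "Conv", flow_speed_mm_s = 2,
                         seed = NULL, out_dir = NULL) {
  measurements <- stage_inputs(measurements, read_measurements)
  segments <- stage_inputs(segments, read_vessel_segments)
  entry_veins <- stage_inputs(entry_veins, read_entry_veins)
  polylines <- stage_inputs(polylines, read_polylines)
  ct <- stage_inputs(ct, read_ct_table)
  if (is.null(measurements) && is.null(segments) && is.null(ct)) {
    stop_invalid("nothing to do: provide measurements, a vessel trace or a Ct table.",
                 class = "flashear_configuration")
  }

  report <- list()
  plan <- irradiation_plan(beams, dose_Gy = dose_Gy)
  report$beam <- plan

  if (!is.null(segments)) {
    if (!is.null(polylines) && !"length_mm" %in% names(segments)) {
      segments <- dplyr::left_join(segments, polyline_lengths(polylines),
                                   by = "vessel_id")
    }
    if (is.null(entry_veins)) {
      stop_invalid("blood-volume stage needs an entry-vein table.",
                   class = "flashear_configuration")
    }
    report$blood_volume <- estimate_blood_volume(
      segments, entry_veins,
      time_s = plan$duration_s, label = plan$label,
      dose_Gy = dose_Gy, flow_speed_mm_s = flow_speed_mm_s
    )
  }

  if (!is.null(measurements)) {
    report$swelling <- compare_groups(measurements, dose_Gy = dose_Gy,
                                      reference = reference,
                                      quantity = "swelling")
    report$score <- compare_groups(measurements, dose_Gy = dose_Gy,
                                   reference = reference, quantity = "score")
  }

  if (!is.null(ct)) {
    ddct <- delta_delta_ct(ct)
    report$qpcr <- list(per_sample = ddct, summary = summarize_log2fc(ddct))
  }

  config <- list(dose_Gy = dose_Gy, reference = reference,
                 flow_speed_mm_s = flow_speed_mm_s, beams = beams,
                 seed = seed)
  report$metadata <- list(
    package = "flashear",
    version = as.character(utils::packageVersion("flashear")),
    seed = seed,
    config_hash = rlang::hash(config),
    note = "p-values are reported raw; no multiple-testing correction applied."
  )

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

json_report <- function(report) {
  list(
    metadata = report$metadata,
    beam = report$beam,
    blood_volume = if (!is.null(report$blood_volume))
      as.data.frame(report$blood_volume),
    swelling_reductions = if (!is.null(report$swelling))
      as.data.frame(report$swelling$reductions),
    score_reductions = if (!is.null(report$score))
      as.data.frame(report$score$reductions),
    qpcr_summary = if (!is.null(report$qpcr))
      as.data.frame(report$qpcr$summary)
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(json_report(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  readr::write_csv(report$beam, file.path(out_dir, "beam_plan.csv"))
  if (!is.null(report$blood_volume)) {
    readr::write_csv(report$blood_volume, file.path(out_dir, "blood_volume.csv"))
  }
  if (!is.null(report$swelling)) {
    readr::write_csv(report$swelling$curves, file.path(out_dir, "swelling_curves.csv"))
    readr::write_csv(report$swelling$reductions,
                     file.path(out_dir, "swelling_reductions.csv"))
  }
  if (!is.null(report$qpcr)) {
    readr::write_csv(report$qpcr$per_sample, file.path(out_dir, "qpcr_ddct.csv"))
    readr::write_csv(report$qpcr$summary, file.path(out_dir, "qpcr_summary.csv"))
  }
  invisible(report)
}
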