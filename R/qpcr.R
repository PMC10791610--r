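# Delta-delta-Ct qPCR analysis: triplicate Ct means, housekeeping
# normalization, sham-referenced delta-delta-Ct, fold change and log2 fold
# change (Livak-style relative quantification without efficiency correction).

#' Mean of replicate Ct values
#'
#' Arithmetic mean of the (up to triplicate) well replicates. Undetermined
#' (`NA`/non-finite) wells are dropped with a warning, never imputed.
#'
#' @param cts Numeric vector of replicate Ct values (>= 1 usable value).
#' @return Mean Ct.
#' @export
ct_mean <- function(cts) {
  if (length(cts) == 0) {
    abort("no Ct replicates to average.",
          class = c("flashear_missing_data", "flashear_error"))
  }
  usable <- is.finite(cts)
  if (!all(usable)) {
    warn(sprintf("dropping %d undetermined Ct well(s) from the replicate mean.",
                 sum(!usable)))
  }
  if (!any(usable)) {
    abort("all Ct replicates are undetermined.",
          class = c("flashear_missing_data", "flashear_error"))
  }
  if (any(cts[usable] <= 0)) {
    stop_invalid("Ct values must be positive.", class = "flashear_invalid_input")
  }
  mean(cts[usable])
}

#' Fold change from delta-delta-Ct
#'
#' `FC = 2^(-ddct)`, the assay's relative expression under perfect doubling
#' per cycle. Always strictly positive.
#'
#' @param ddct Delta-delta-Ct value(s), finite.
#' @return Fold change(s).
#' @export
#' @examples
#' fold_change(-2) # 4
fold_change <- function(ddct) {
  check_number(ddct, "ddct")
  2^(-ddct)
}

#' Log2 fold change
#'
#' `log2(FC)`; composed with [fold_change()] it returns exactly `-ddct`.
#'
#' @param fc Fold change(s), > 0.
#' @return Log2 fold change(s).
#' @export
log2_fold_change <- function(fc) {
  check_number(fc, "fc")
  if (any(fc <= 0)) {
    stop_invalid("fold changes must be > 0.", class = "flashear_invalid_input")
  }
  log2(fc)
}

# Accept wide (ct_rep1..ct_rep3) or long (replicate, ct) layouts and return
# one row per well replicate.
tidy_ct <- function(ct_data) {
  check_columns(ct_data, c("sample_id", "mouse_id", "group", "day", "gene"),
                "Ct table")
  rep_cols <- grep("^ct_rep[0-9]+$", names(ct_data), value = TRUE)
  if (length(rep_cols) > 0) {
    ct_data |>
      tidyr::pivot_longer(dplyr::all_of(rep_cols),
                          names_to = "replicate", values_to = "ct",
                          names_prefix = "ct_rep") |>
      dplyr::filter(!is.na(.data$ct))
  } else if ("ct" %in% names(ct_data)) {
    ct_data
  } else {
    stop_data_format("Ct table needs either ct_rep1..ct_rep3 columns or a long `ct` column.")
  }
}

#' Delta-delta-Ct analysis of a Ct table
#'
#' Per sample and target gene: averages the replicate Cts, normalizes against
#' the housekeeping gene(s) of the same sample
#' (`dCt = Ct_gene - Ct_housekeeping`), references against the mean sham dCt
#' of the same gene and day (`ddCt = dCt - mean dCt_sham`), and derives
#' `FC = 2^(-ddCt)` and `log2FC = -ddCt`. With two housekeeping genes the
#' default normalizer is the arithmetic mean of their Ct means (equivalent to
#' geometric-mean expression normalization); `hk_mode = "single"` uses the
#' first listed gene only.
#'
#' @param ct_data Ct table, wide (`sample_id,mouse_id,group,day,gene,
#'   ct_rep1..3`) or long (`..., replicate, ct`).
#' @param housekeeping Character vector of housekeeping gene names.
#' @param reference_group Group label used as the unirradiated reference.
#' @param hk_mode `"mean"` of all listed housekeeping genes or `"single"`.
#' @return Tibble of class `flash_ddct`, one row per sample x target gene:
#'   `ct`, `hk_ct`, `dct`, `ddct`, `fold_change`, `log2_fc`.
#' @export
delta_delta_ct <- function(ct_data, housekeeping = c("B2M", "GAPDH"),
                           reference_group = "Sham",
                           hk_mode = c("mean", "single")) {
  hk_mode <- match.arg(hk_mode)
  long <- tidy_ct(ct_data)
  if (hk_mode == "single") housekeeping <- housekeeping[1]

  well_means <- long |>
    dplyr::group_by(.data$sample_id, .data$mouse_id, .data$group, .data$day,
                    .data$gene) |>
    dplyr::summarise(ct = ct_mean(.data$ct), .groups = "drop")

  hk <- well_means |>
    dplyr::filter(.data$gene %in% housekeeping) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hk_ct = mean(.data$ct), n_hk = dplyr::n(), .groups = "drop")

  targets <- well_means |>
    dplyr::filter(!.data$gene %in% housekeeping) |>
    dplyr::left_join(hk, by = "sample_id")
  if (anyNA(targets$hk_ct)) {
    bad <- unique(targets$sample_id[is.na(targets$hk_ct)])
    stop_missing_reference(sprintf(
      "no housekeeping Ct for sample(s): %s.", paste(bad, collapse = ", ")
    ))
  }
  targets <- dplyr::mutate(targets, dct = .data$ct - .data$hk_ct)

  sham_ref <- targets |>
    dplyr::filter(tolower(.data$group) == tolower(reference_group)) |>
    dplyr::group_by(.data$gene, .data$day) |>
    dplyr::summarise(ref_dct = mean(.data$dct), .groups = "drop")
  if (nrow(sham_ref) == 0) {
    stop_missing_reference(sprintf(
      "no samples of reference group '%s' to normalize against.", reference_group
    ))
  }

  out <- targets |>
    dplyr::left_join(sham_ref, by = c("gene", "day"))
  if (anyNA(out$ref_dct)) {
    bad <- out |> dplyr::filter(is.na(.data$ref_dct))
    stop_missing_reference(sprintf(
      "no %s reference dCt for gene/day: %s.", reference_group,
      paste(unique(paste0(bad$gene, "/day ", bad$day)), collapse = ", ")
    ))
  }
  out <- out |>
    dplyr::mutate(
      ddct = .data$dct - .data$ref_dct,
      fold_change = fold_change(.data$ddct),
      log2_fc = -.data$ddct
    ) |>
    dplyr::select("sample_id", "mouse_id", "group", "day", "gene",
                  "ct", "hk_ct", "dct", "ddct", "fold_change", "log2_fc")
  class(out) <- c("flash_ddct", class(out))
  out
}

#' Per-group log2 fold-change summary
#'
#' Sample mean and standard deviation (n-1 denominator) of the log2 fold
#' change per gene, group and day — the quantities shown as bars and error
#' bars in cytokine panels. SD is missing (not zero) for single-sample cells.
#'
#' @param ddct A `flash_ddct` tibble from [delta_delta_ct()].
#' @return Tibble with `gene`, `group`, `day`, `mean_log2_fc`, `sd_log2_fc`, `n`.
#' @export
summarize_log2fc <- function(ddct) {
  check_columns(ddct, c("gene", "group", "day", "log2_fc"), "ddCt table")
  ddct |>
    dplyr::group_by(.data$gene, .data$group, .data$day) |>
    dplyr::summarise(
      mean_log2_fc = mean(.data$log2_fc),
      sd_log2_fc = if (dplyr::n() >= 2) stats::sd(.data$log2_fc) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
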