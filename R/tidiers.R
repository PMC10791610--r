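# broom-style accessors for the comparison object.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a group comparison
#'
#' One row per test group with its percent reduction, propagated SEM and
#' t-test against the reference.
#'
#' @param x A `flash_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return Tibble of reductions.
#' @export
tidy.flash_comparison <- function(x, ...) {
  x$reductions
}

#' One-row summary of a group comparison
#'
#' @param x A `flash_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble: quantity, dose, reference peak day/mean/SEM,
#'   number of groups compared, smallest raw p-value.
#' @export
glance.flash_comparison <- function(x, ...) {
  ref <- dplyr::filter(x$peaks, .data$dose_rate_label == x$reference)
  tibble(
    quantity = x$quantity, dose_Gy = x$dose_Gy, reference = x$reference,
    ref_peak_day = ref$peak_day, ref_peak_mean = ref$peak_mean,
    ref_peak_sem = ref$peak_sem,
    n_groups = nrow(x$reductions) + 1L,
    min_p_value = suppressWarnings(min(x$reductions$p_value))
  )
}
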