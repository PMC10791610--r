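test_that("replicate Ct means drop undetermined wells and never impute", {
  expect_equal(ct_mean(c(20, 20, 20)), 20)
  expect_equal(ct_mean(c(19.8, 20.0, 20.2)), 20)
  expect_equal(ct_mean(c(21.1, 21.4)), 21.25)
  expect_warning(m <- ct_mean(c(21, NA, 22)), "undetermined")
  expect_equal(m, 21.5)
  expect_error(ct_mean(numeric(0)), class = "flashear_missing_data")
  expect_error(suppressWarnings(ct_mean(c(NA_real_, NA_real_))),
               class = "flashear_missing_data")
})

test_that("fold change and log2 fold change are exact inverses of ddCt", {
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(1), 0.5)
  expect_equal(fold_change(-2), 4)
  expect_equal(log2_fold_change(1), 0)
  expect_equal(log2_fold_change(4), 2)
  expect_error(log2_fold_change(0), class = "flashear_invalid_input")
  expect_error(fold_change(Inf), class = "flashear_invalid_parameter")
  withr::with_seed(31, {
    x <- rnorm(100, 0, 3)
    expect_equal(log2_fold_change(fold_change(x)), -x)
    expect_true(all(fold_change(x) > 0))
  })
})

toy_plate <- function(ddct_shift = 0) {
  # two groups x two mice, one gene + one housekeeping gene, one day
  grid <- expand.grid(mouse = 1:2, group = c("Sham", "Conv"),
                      gene = c("TNF-a", "B2M"), stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste0(grid$group, grid$mouse),
    mouse_id = paste0(grid$group, grid$mouse),
    group = grid$group,
    day = 7,
    gene = grid$gene,
    ct_rep1 = ifelse(grid$gene == "B2M", 18,
                     22 + ifelse(grid$group == "Conv", ddct_shift, 0)),
    ct_rep2 = ifelse(grid$gene == "B2M", 18,
                     22 + ifelse(grid$group == "Conv", ddct_shift, 0)),
    ct_rep3 = ifelse(grid$gene == "B2M", 18,
                     22 + ifelse(grid$group == "Conv", ddct_shift, 0))
  )
}

test_that("ddCt is the sample dCt minus the sham mean dCt", {
  # sample dCt equal to the sham mean -> 0; shifted by 2 cycles -> 2
  flat <- delta_delta_ct(toy_plate(0), housekeeping = "B2M")
  expect_equal(flat$ddct, rep(0, 4))
  expect_equal(flat$fold_change, rep(1, 4))
  shifted <- delta_delta_ct(toy_plate(2), housekeeping = "B2M")
  conv <- dplyr::filter(shifted, group == "Conv")
  expect_equal(conv$ddct, rep(2, 2))
  expect_equal(conv$fold_change, rep(0.25, 2))
  expect_equal(conv$log2_fc, -conv$ddct) # exact identity
  # sham group's own mean ddCt is zero by construction
  sham <- dplyr::filter(shifted, group == "Sham")
  expect_equal(mean(sham$ddct), 0)
  no_ref <- dplyr::filter(toy_plate(0), group != "Sham")
  expect_error(delta_delta_ct(no_ref, housekeeping = "B2M"),
               class = "flashear_missing_reference")
})

test_that("adding a constant to every Ct of a sample leaves ddCt unchanged", {
  plate <- simulate_qpcr(seed = 6)
  base <- delta_delta_ct(plate)
  shifted_plate <- plate
  one_sample <- shifted_plate$sample_id == shifted_plate$sample_id[1]
  shifted_plate[one_sample, c("ct_rep1", "ct_rep2", "ct_rep3")] <-
    shifted_plate[one_sample, c("ct_rep1", "ct_rep2", "ct_rep3")] + 3
  shifted <- delta_delta_ct(shifted_plate)
  expect_equal(shifted$ddct, base$ddct)
})

test_that("housekeeping modes: mean of both genes vs a single gene", {
  plate <- simulate_qpcr(seed = 6)
  both <- delta_delta_ct(plate, hk_mode = "mean")
  single <- delta_delta_ct(plate, housekeeping = c("B2M", "GAPDH"),
                           hk_mode = "single")
  expect_false(isTRUE(all.equal(both$dct, single$dct)))
  # the sham-centering identity holds in both modes
  expect_equal(mean(both$ddct[both$group == "Sham" & both$gene == "IL1a" &
                                both$day == 7]), 0)
  expect_equal(mean(single$ddct[single$group == "Sham" & single$gene == "IL1a" &
                                  single$day == 7]), 0)
})

test_that("injected fold changes are recovered from synthetic plates", {
  spec <- tidyr::expand_grid(gene = "TNF-a", group = c("Conv", "Flash9", "Flash930"),
                             day = 7, log2_fc = -1.5)
  sc <- flash_scenario(qpcr_log2fc = spec)
  plate <- simulate_qpcr(sc, seed = 12)
  s <- summarize_log2fc(delta_delta_ct(plate))
  hit <- dplyr::filter(s, gene == "TNF-a", day == 7, group == "Conv")
  expect_lt(abs(hit$mean_log2_fc - (-1.5)), 0.3)
  others <- dplyr::filter(s, !(gene == "TNF-a" & day == 7), group != "Sham")
  expect_lt(max(abs(others$mean_log2_fc)), 0.5)
})

test_that("log2FC summaries report mean, n-1 SD and missing SD for singletons", {
  d <- tibble::tibble(gene = "TNF-a", group = "Conv", day = 7,
                      log2_fc = c(-0.5, 0, 0.5))
  s <- summarize_log2fc(d)
  expect_equal(s$mean_log2_fc, 0)
  expect_equal(s$sd_log2_fc, 0.5)
  s1 <- summarize_log2fc(d[1, ])
  expect_equal(s1$mean_log2_fc, -0.5)
  expect_true(is.na(s1$sd_log2_fc))
})

test_that("a null plate mirrors the no-change cytokine finding", {
  plate <- simulate_qpcr(seed = 19) # true log2FC = 0 everywhere
  s <- summarize_log2fc(delta_delta_ct(plate))
  irr <- dplyr::filter(s, group != "Sham", !is.na(sd_log2_fc))
  # group means stay within ~3 standard errors of zero
  expect_true(all(abs(irr$mean_log2_fc) < 3 * irr$sd_log2_fc / sqrt(irr$n) + 0.15))
})
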