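test_that("inflammation score sums the two ordinal maps and is bounded", {
  expect_equal(inflammation_score("No", "No"), 0)
  expect_equal(inflammation_score("Mild", "Dry"), 1.5)
  expect_equal(inflammation_score("Severe", "Moist"), 6)
  expect_equal(inflammation_score("severe", "CRUST FORMATION"), 5) # case-insensitive
  expect_equal(inflammation_score(1.5, 2), 3.5) # numeric passthrough
  expect_error(inflammation_score("purple", "No"),
               "erythema.*purple.*row 1", class = "flashear_data_format")
  # monotone non-decreasing in each component's severity
  ery <- c("No", "Mild", "Definite", "Severe")
  des <- c("No", "Dry", "Crust formation", "Moist")
  for (d in des) expect_true(all(diff(inflammation_score(ery, d)) >= 0))
  for (e in ery) expect_true(all(diff(inflammation_score(e, des)) >= 0))
  grid <- expand.grid(e = ery, d = des, stringsAsFactors = FALSE)
  all_scores <- inflammation_score(grid$e, grid$d)
  expect_true(all(all_scores >= 0 & all_scores <= 6))
})

test_that("ear swelling is sham-referenced and centres the sham group exactly", {
  m <- toy_measurements()
  sw <- ear_swelling(m)
  # sham mice average to exactly zero on every measured day
  sham_means <- sw |>
    dplyr::filter(dose_rate_label == "Sham") |>
    dplyr::group_by(day) |>
    dplyr::summarise(m = mean(swelling_um))
  expect_equal(sham_means$m, rep(0, nrow(sham_means)))
  # plain difference against the sham mean: at day 24 Conv sits 100 µm above
  conv24 <- sw$swelling_um[sw$dose_rate_label == "Conv" & sw$day == 24]
  expect_equal(conv24, rep(100, 4))
  no_sham <- dplyr::filter(m, dose_rate_label != "Sham")
  expect_error(ear_swelling(no_sham), class = "flashear_missing_reference")
})

test_that("sham centering survives noisy, per-mouse measurement schedules", {
  m <- simulate_cohort(seed = 4)
  sw <- ear_swelling(m)
  centred <- sw |>
    dplyr::filter(dose_rate_label == "Sham") |>
    dplyr::group_by(day) |>
    dplyr::summarise(m = mean(swelling_um))
  expect_equal(centred$m, rep(0, nrow(centred)))
})

test_that("group curves aggregate to per-day mean and SEM", {
  two <- tibble::tibble(
    mouse_id = c("a", "b"), dose_Gy = 33, dose_rate_label = "Conv",
    day = 10, swelling_um = c(100, 200)
  )
  curve <- group_curve(two, quantity = "swelling")
  expect_equal(curve$mean, 150)
  expect_equal(curve$sem, 50)
  expect_equal(curve$n, 2)
  one <- two[1, ]
  c1 <- group_curve(one, quantity = "swelling")
  expect_equal(c1$mean, 100)
  expect_true(is.na(c1$sem)) # SEM undefined for n = 1, never zero
  empty <- two[0, ]
  expect_error(group_curve(empty, quantity = "swelling"),
               class = "flashear_empty_group")
})

test_that("group curves recover a known mean function on a synthetic cohort", {
  # common measurement grid and an exactly known sham reference, so the
  # group-mean SEM is the only source of uncertainty; +/- 2 SEM with an
  # estimated SD at n = 30 has ~94.6% nominal coverage
  withr::with_seed(14, {
    days <- seq(0, 60, by = 3)
    truth_fun <- function(d) 155 * response_curve(d)
    irr <- purrr::map_dfr(1:30, function(i) tibble::tibble(
      mouse_id = paste0("c", i), dose_Gy = 33, dose_rate_label = "Conv",
      day = days,
      ear_thickness_um = 230 + truth_fun(days) + rnorm(length(days), 0, 25),
      erythema = "No", desquamation = "No"
    ))
    sham <- purrr::map_dfr(1:5, function(i) tibble::tibble(
      mouse_id = paste0("s", i), dose_Gy = 0, dose_rate_label = "Sham",
      day = days, ear_thickness_um = 230,
      erythema = "No", desquamation = "No"
    ))
    curve <- group_curve(dplyr::bind_rows(irr, sham), quantity = "swelling") |>
      dplyr::filter(dose_rate_label == "Conv")
    covered <- abs(curve$mean - truth_fun(curve$day)) <= 2 * curve$sem
    expect_gte(mean(covered), 0.90)
  })
})

test_that("peak reaction picks the day of maximal mean, earliest on ties", {
  curve <- tibble::tibble(
    dose_Gy = 33, dose_rate_label = "Conv",
    day = c(10, 23, 40), mean = c(10, 155, 20), sem = 5, n = 7
  )
  class(curve) <- c("flash_curve", class(curve))
  pk <- peak_reaction(curve)
  expect_equal(pk$peak_day, 23)
  expect_equal(pk$peak_mean, 155)
  flat <- dplyr::mutate(curve, mean = 7)
  expect_equal(peak_reaction(flat)$peak_day, 10) # tie -> earliest day
  expect_equal(peak_reaction(curve, window = c(30, 50))$peak_day, 40)
  expect_error(peak_reaction(curve, window = c(100, 120)),
               class = "flashear_no_data")
})

test_that("synthetic peak amplitude is recovered within 2 SEM", {
  m <- simulate_cohort(seed = 15)
  cmp <- compare_groups(m, 33, "Conv")
  ref <- dplyr::filter(cmp$peaks, dose_rate_label == "Conv")
  expect_lt(abs(ref$peak_mean - 155), 2 * ref$peak_sem + 1e-9)
  expect_lt(abs(ref$peak_day - 23), 6)
})

test_that("percent reduction propagates first-order uncertainty", {
  expect_equal(percent_reduction(100, 5, 100, 5)$percent, 0)
  expect_equal(percent_reduction(100, 5, 0, 0)$percent, 100)
  red <- percent_reduction(100, 10, 50, 5)
  expect_equal(red$percent, 50)
  expect_equal(red$sem, 100 * sqrt(0.05^2 + 0.05^2))
  expect_equal(round_half_up(red$sem, 2), 7.07)
  # scale invariance
  for (c_scale in c(0.1, 3, 42)) {
    scaled <- percent_reduction(100 * c_scale, 10 * c_scale,
                                50 * c_scale, 5 * c_scale)
    expect_equal(scaled$percent, red$percent)
    expect_equal(scaled$sem, red$sem)
  }
  expect_error(percent_reduction(0, 1, 10, 1),
               class = "flashear_undefined_reduction")
  # propagation formula vs Monte-Carlo
  mc <- withr::with_seed(77, {
    sd(100 * (1 - rnorm(1e5, 50, 5) / rnorm(1e5, 100, 10)))
  })
  expect_lt(abs(red$sem - mc) / mc, 0.05)
})

test_that("two-sample t-test matches the closed-form pooled computation", {
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  tt <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  oracle <- pooled_t_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, oracle$t, tolerance = 1e-12)
  expect_equal(tt$df, oracle$df)
  expect_equal(tt$p_value, oracle$p, tolerance = 1e-12)
  expect_error(two_sample_ttest(1, c(1, 2)), class = "flashear_invalid_input")
  # Welch flag changes the degrees of freedom under unequal variances
  welch <- two_sample_ttest(c(1, 2, 3), c(0, 5, 10), var_equal = FALSE)
  expect_lt(welch$df, 4)
})

test_that("group comparison recovers the constructed reduction", {
  m <- toy_measurements(noise_sd = 0)
  curves <- group_curve(ear_swelling(m), quantity = "swelling")
  pk <- peak_reaction(curves) |> dplyr::filter(dose_Gy == 33)
  expect_equal(pk$peak_mean[pk$dose_rate_label == "Conv"], 100)
  expect_equal(pk$peak_day, c(24, 24))
  expect_equal(
    percent_reduction(100, 0, pk$peak_mean[pk$dose_rate_label == "Flash930"], 0)$percent,
    40
  )
  # with measurement noise the full comparison still recovers it within its
  # own propagated uncertainty
  mn <- toy_measurements(noise_sd = 10, seed = 21)
  cmp <- compare_groups(mn, 33, "Conv")
  red <- tidy(cmp)
  expect_lt(abs(red$reduction_percent - 40), 3 * red$reduction_sem)
  g <- glance(cmp)
  expect_equal(g$reference, "Conv")
  expect_equal(g$n_groups, 2L)
})
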