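# Shared fixtures and independent oracles.

# Calibrated vessel fixture: per-class total lengths chosen so the analytic
# static volume is 0.20 µl, plus four thick (0.09 mm) entry veins.
calibrated_segments <- function() {
  tibble::tibble(
    vessel_id = c("t1", "m1", "n1"),
    size_class = c("thick", "middle", "thin"),
    length_mm = c(12, 35, 43.72)
  )
}

calibrated_veins <- function() {
  tibble::tibble(vein_id = paste0("e", 1:4), diameter_mm = rep(0.09, 4))
}

# Irradiation times (s) of the three modes for 33 Gy at the printed mean
# dose rates.
mode_times <- c(Flash930 = 0.035, Flash9 = 3.55, Conv = 550.2)

# Monte-Carlo volume of one cylinder around a straight segment: sample points
# uniformly in the segment's 3D bounding box and count those within d/2 of
# the axis (between the end planes). Independent of the analytic formula.
mc_cylinder_volume <- function(p1, p2, diameter, n = 2e4) {
  r <- diameter / 2
  axis <- p2 - p1
  len <- sqrt(sum(axis^2))
  u <- axis / len
  lo <- pmin(p1, p2) - r
  hi <- pmax(p1, p2) + r
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, -r, r))
  rel <- cbind(pts[, 1] - p1[1], pts[, 2] - p1[2], pts[, 3])
  t_ax <- rel %*% c(u, 0)
  perp2 <- rowSums(rel^2) - t_ax^2
  inside <- t_ax >= 0 & t_ax <= len & perp2 <= r^2
  mean(inside) * prod(hi - lo) * 2 * r
}

# Monte-Carlo static volume of a traced field: per-segment cylinder volumes
# summed (the additive per-segment convention of the estimator).
mc_static_volume <- function(polylines, segments,
                             diameters = flashear::vessel_diameters(),
                             n = 2e4) {
  total <- 0
  for (vid in unique(polylines$vessel_id)) {
    pts <- polylines[polylines$vessel_id == vid, ]
    pts <- pts[order(pts$point_index), ]
    d <- diameters[[tolower(segments$size_class[segments$vessel_id == vid])]]
    for (i in seq_len(nrow(pts) - 1)) {
      p1 <- c(pts$x_mm[i], pts$y_mm[i])
      p2 <- c(pts$x_mm[i + 1], pts$y_mm[i + 1])
      total <- total + mc_cylinder_volume(p1, p2, d, n = n)
    }
  }
  total
}

# Closed-form pooled two-sample t-test, written out independently of t.test.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Small three-group measurement table on a fixed day grid with a triangular
# response, for deterministic cohort tests.
toy_measurements <- function(noise_sd = 0, seed = 42) {
  withr::with_seed(seed, {
    days <- seq(0, 60, by = 3)
    bump <- pmax(0, 1 - abs(days - 24) / 12) # peaks at day 24
    grid <- expand.grid(mouse = 1:4, grp = c("Conv", "Flash930", "Sham"),
                        stringsAsFactors = FALSE)
    purrr::pmap_dfr(grid, function(mouse, grp) {
      amp <- c(Conv = 100, Flash930 = 60, Sham = 0)[[grp]]
      tibble::tibble(
        mouse_id = paste0(grp, mouse),
        dose_Gy = if (grp == "Sham") 0 else 33,
        dose_rate_label = grp,
        day = days,
        ear_thickness_um = 230 + amp * bump + rnorm(length(days), 0, noise_sd),
        erythema = "No", desquamation = "No"
      )
    })
  })
}
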