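# Peak metrics and the peak-time vs S-phase-length correlation.

test_that("peak metrics of a centred Lorentzian are exact", {
  prof <- sim_profile("lorentzian", c(B = 0, A = 1, t0 = 300, gamma = 120),
                      seq(0, 600, 15))
  fit <- fit_recruitment(prof, "lorentzian")
  pm <- peak_metrics(fit, cs = 0, neb = 600)
  expect_equal(pm$peak_intensity, 1, tolerance = 1e-6)
  expect_equal(pm$normalized_peak_centre, 0.5, tolerance = 1e-6)
  expect_equal(pm$time_to_peak, 300, tolerance = 1e-4)
  # same fit, longer S-phase: normalized centre shrinks to 1/3
  pm2 <- peak_metrics(fit, cs = 0, neb = 900)
  expect_equal(pm2$normalized_peak_centre, 1 / 3, tolerance = 1e-6)
})

test_that("plateau model peak centre is the plateau midpoint", {
  par <- c(y0 = 0.1, m1 = 1 / 200, m2 = -1 / 200, t1 = 200, t2 = 400)
  prof <- sim_profile("inc_const_dec", par, seq(0, 585, 15))
  fit <- fit_recruitment(prof, "inc_const_dec")
  pm <- peak_metrics(fit, cs = 0, neb = 585)
  expect_equal(pm$peak_centre, 300, tolerance = 1)
})

test_that("peaks outside the S-phase window are flagged", {
  prof <- sim_profile("gaussian", c(B = 0, A = 1, t0 = 60, sigma = 100),
                      seq(0, 600, 15))
  fit <- fit_recruitment(prof, "gaussian")
  pm <- peak_metrics(fit, cs = 120, neb = 600)
  expect_true(pm$out_of_window)
})

test_that("points exactly on a rising line give r = 1 and 'strong'", {
  d <- tibble::tibble(sphase_length = c(400, 500, 600, 700),
                      peak_centre = 0.5 * c(400, 500, 600, 700) + 10)
  cr <- correlate_peak_with_sphase(d)
  expect_equal(cr$r, 1, tolerance = 1e-12)
  expect_equal(cr$slope, 0.5, tolerance = 1e-12)
  expect_equal(cr$strength_label, "strong")
})

test_that("strength bands follow the moderate/strong cutoffs", {
  expect_equal(centriodyn:::strength_label(0.5), "moderate")
  expect_equal(centriodyn:::strength_label(0.39), "weak")
  expect_equal(centriodyn:::strength_label(0.61), "strong")
  expect_equal(centriodyn:::strength_label(-0.8), "weak")
})

test_that("r is invariant to affine rescaling of either variable", {
  set.seed(3)
  d <- tibble::tibble(sphase_length = runif(12, 400, 900),
                      peak_centre = runif(12, 100, 500))
  r0 <- correlate_peak_with_sphase(d)$r
  d2 <- dplyr::mutate(d, sphase_length = 3.7 * .data$sphase_length - 120,
                      peak_centre = 0.2 * .data$peak_centre + 55)
  expect_equal(correlate_peak_with_sphase(d2)$r, r0, tolerance = 1e-12)
})

test_that("degenerate correlations are rejected", {
  expect_error(correlate_peak_with_sphase(
    tibble::tibble(sphase_length = c(1, 2), peak_centre = c(1, 2))), ">= 3")
  expect_error(correlate_peak_with_sphase(
    tibble::tibble(sphase_length = c(500, 500, 500),
                   peak_centre = c(1, 2, 3))), "zero variance")
})

test_that("per-embryo programmed peak times are recovered within a frame", {
  coh <- sim_embryo_cohort(cohort_spec(n_embryos = 8), seed = 31)
  prof <- preprocess_tracks(coh$tracks, coh$landmarks, scale_max1 = TRUE)
  fits <- fit_embryos(prof, model = "lorentzian")
  m <- dplyr::left_join(dplyr::select(fits, "embryo_id", "peak_centre"),
                        coh$truth, by = "embryo_id")
  expect_lt(median(abs(m$peak_centre - m$peak_time)), 30)
})

test_that("end-to-end cohort correlation recovers the programmed coupling", {
  coh <- sim_embryo_cohort(cohort_spec(n_embryos = 20), seed = 7)
  prof <- preprocess_tracks(coh$tracks, coh$landmarks, scale_max1 = TRUE)
  fits <- fit_embryos(prof, model = "lorentzian")
  cr <- correlate_peak_with_sphase(fits)
  expect_gt(cr$r, 0.6)
  expect_lt(cr$p_value, 0.05)
})
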