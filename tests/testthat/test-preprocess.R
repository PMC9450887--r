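# Track preprocessing: windowing, background, bleach correction, scaling.

test_that("identity preprocessing reproduces the generating curve exactly", {
  coh <- clean_cohort(n_embryos = 2, seed = 4)
  prof <- preprocess_tracks(coh$tracks, coh$landmarks, background = 0)
  for (e in coh$truth$embryo_id) {
    p <- embryo_profile(prof, e)
    tr <- coh$truth[coh$truth$embryo_id == e, ]
    y <- model_curve(tr$model, tr$par[[1]], p$time_s)
    expect_equal(p$mean, y, tolerance = 1e-12)
    expect_equal(p$sd, rep(0, nrow(p)))
  }
})

test_that("scaling sets the cycle maximum of the mean to exactly 1", {
  coh <- sim_embryo_cohort(cohort_spec(n_embryos = 3,
                                       centrioles_per_embryo = 8), seed = 2)
  prof <- preprocess_tracks(coh$tracks, coh$landmarks, scale_max1 = TRUE)
  maxes <- tapply(prof$mean, prof$embryo_id, max)
  expect_equal(as.numeric(maxes), rep(1, 3))
})

test_that("scaling an already-scaled profile changes nothing", {
  coh <- sim_embryo_cohort(cohort_spec(n_embryos = 2,
                                       centrioles_per_embryo = 6), seed = 3)
  p1 <- preprocess_tracks(coh$tracks, coh$landmarks, scale_max1 = TRUE)
  # feed the scaled means back through as single-centriole tracks
  tracks2 <- dplyr::transmute(p1, embryo_id = .data$embryo_id,
                              centriole_id = 1L, time_s = .data$time_s,
                              intensity = .data$mean)
  p2 <- preprocess_tracks(tracks2, coh$landmarks, background = 0,
                          scale_max1 = TRUE)
  expect_equal(p2$mean, p1$mean, tolerance = 1e-12)
})

test_that("bleach correction with a matching reference recovers the truth", {
  spec <- cohort_spec(n_embryos = 2, centrioles_per_embryo = 10,
                      bleach_tau = 600, background_level = 0,
                      centriole_scatter_cv = 0, noise_sd = 0)
  coh <- sim_embryo_cohort(spec, seed = 3)
  ref <- tibble::tibble(time_s = seq(0, 900, 30),
                        intensity = 10 * exp(-seq(0, 900, 30) / 600))
  prof <- preprocess_tracks(coh$tracks, coh$landmarks, background = 0,
                            bleach_ref = ref)
  for (e in coh$truth$embryo_id) {
    p <- embryo_profile(prof, e)
    tr <- coh$truth[coh$truth$embryo_id == e, ]
    y <- model_curve(tr$model, tr$par[[1]], p$time_s)
    expect_lt(max(abs(p$mean - y)) / max(y), 0.02)
  }
})

test_that("non-finite intensities are dropped and counted", {
  coh <- clean_cohort(n_embryos = 1, seed = 5)
  tracks <- coh$tracks
  tracks$intensity[c(2, 7)] <- c(NA, Inf)
  prof <- preprocess_tracks(tracks, coh$landmarks)
  expect_equal(attr(prof, "preprocessing")$dropped_rows, 2)
})

test_that("background defaults to the 5th percentile per embryo", {
  coh <- clean_cohort(n_embryos = 1, seed = 6)
  tracks <- dplyr::mutate(coh$tracks, intensity = .data$intensity + 2)
  prof <- preprocess_tracks(tracks, coh$landmarks)
  bg <- attr(prof, "preprocessing")$background$background
  expect_equal(bg, quantile(tracks$intensity, 0.05, names = FALSE))
})

test_that("mitotic frames outside [CS, NEB] are excluded", {
  coh <- clean_cohort(n_embryos = 1, seed = 7)
  extra <- tibble::tibble(embryo_id = coh$landmarks$embryo_id,
                          centriole_id = 1L,
                          time_s = coh$landmarks$neb_s + 60,
                          intensity = 99)
  prof <- preprocess_tracks(dplyr::bind_rows(coh$tracks, extra),
                            coh$landmarks)
  expect_lte(max(prof$time_s), coh$landmarks$neb_s)
})

test_that("invalid landmarks and empty windows raise errors", {
  coh <- clean_cohort(n_embryos = 1, seed = 8)
  bad_lmk <- dplyr::mutate(coh$landmarks, neb_s = -1)
  expect_error(preprocess_tracks(coh$tracks, bad_lmk), "cs_s < neb_s")
  shifted <- dplyr::mutate(coh$tracks, time_s = .data$time_s + 1e6)
  expect_error(preprocess_tracks(shifted, coh$landmarks), "window")
})
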