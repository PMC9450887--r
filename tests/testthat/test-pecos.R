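# Peak counting spectroscopy: threshold, counting, ROUT screen.

test_that("threshold is Mean + 7 s.d. of the pooled control bins", {
  # construct controls with pooled mean 100 and sd 10 exactly
  x <- c(90, 110)
  ctrl <- list(rep(x, 50), rep(x, 50))
  pooled <- unlist(ctrl)
  expect_equal(mean(pooled), 100)
  thr <- compute_threshold(ctrl)
  expect_equal(thr$threshold, 100 + 7 * sd(pooled), tolerance = 1e-12)
})

test_that("constant controls give threshold = mean with a warning", {
  expect_warning(thr <- compute_threshold(list(rep(5, 100))), "degenerate")
  expect_equal(thr$threshold, 5)
})

test_that("simulated pure-noise controls are valid (well under 5 peaks)", {
  ctrl <- sim_pecos_traces(pecos_spec(duration = 30, transit_rate = 0),
                           6, seed = 9)
  thr <- compute_threshold(ctrl)
  expect_true(thr$valid)
  expect_lt(thr$control_mean_peaks, 5)
})

test_that("peaks are maximal contiguous supra-threshold runs", {
  expect_equal(count_peaks(c(0, 9, 9, 0, 9, 0), 5), 2)
  expect_equal(count_peaks(rep(1, 10), 5), 0)
  expect_equal(count_peaks(c(9, 0, 9, 0, 9), 5), 3)
  expect_equal(count_peaks(numeric(0), 5), 0L)
})

test_that("adding a constant to bins and threshold leaves counts unchanged", {
  set.seed(2)
  trace <- rpois(5000, 20)
  thr <- 30
  n0 <- count_peaks(trace, thr)
  expect_equal(count_peaks(trace + 17, thr + 17), n0)
})

test_that("counts are bounded by ceiling(n_bins / 2)", {
  worst <- rep(c(9, 0), 50)
  expect_lte(count_peaks(worst, 5), ceiling(100 / 2))
  set.seed(4)
  for (i in 1:20) {
    tr <- rpois(200, 5)
    expect_lte(count_peaks(tr, 4), ceiling(200 / 2))
  }
})

test_that("a larger threshold never increases the count", {
  set.seed(6)
  trace <- rpois(10000, 50)
  thrs <- c(60, 70, 80, 90)
  counts <- vapply(thrs, function(th) count_peaks(trace, th), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("doubling the transit rate increases the mean counted peaks", {
  ctrl <- sim_pecos_traces(pecos_spec(duration = 20, transit_rate = 0),
                           5, seed = 1)
  thr <- compute_threshold(ctrl)$threshold
  m <- vapply(c(0.2, 0.4), function(r) {
    tr <- sim_pecos_traces(pecos_spec(duration = 20, transit_rate = r),
                           40, seed = 77)
    mean(count_peaks_all(tr, thr)$n_peaks)
  }, numeric(1))
  expect_gt(m[2], m[1])
})

test_that("trace generator honours its degenerate limits and determinism", {
  off <- sim_pecos_traces(pecos_spec(duration = 5, transit_rate = 0,
                                     background_rate = 0), 3, seed = 1)
  expect_true(all(vapply(off$counts, function(x) all(x == 0), logical(1))))
  expect_equal(off$truth$n_events, rep(0, 3))
  a <- sim_pecos_traces(pecos_spec(duration = 5), 2, seed = 5)
  b <- sim_pecos_traces(pecos_spec(duration = 5), 2, seed = 5)
  expect_identical(a$counts, b$counts)
})

test_that("ROUT removes a gross outlier and keeps tight clusters intact", {
  res <- rout_filter(c(10.0, 10.1, 9.9, 10.05, 9.95, 50.0), Q = 0.01)
  expect_equal(res$outliers, 50.0)
  expect_equal(sort(res$kept), sort(c(10.0, 10.1, 9.9, 10.05, 9.95)))
  # identical values: nothing removed
  expect_length(rout_filter(rep(3, 6))$outliers, 0)
})

test_that("ROUT is permutation invariant and monotone in Q", {
  set.seed(8)
  x <- c(rnorm(10), 8)
  res1 <- rout_filter(x, Q = 0.01)
  res2 <- rout_filter(sample(x), Q = 0.01)
  expect_equal(sort(res1$outliers), sort(res2$outliers))
  # lowering Q can only shrink the outlier set
  for (q in c(0.05, 0.01, 0.001)) {
    res_hi <- rout_filter(x, Q = q)
    res_lo <- rout_filter(x, Q = q / 5)
    expect_true(all(res_lo$outliers %in% res_hi$outliers))
  }
})

test_that("ROUT false-removal on clean Gaussian samples is at the percent level", {
  fr <- vapply(1:300, function(k) {
    length(rout_filter(with_seed_local(k, rnorm(12)), Q = 0.01)$outliers) > 0
  }, logical(1))
  expect_lt(mean(fr), 0.05)
})

test_that("pecos_summary reports ROUT-screened group statistics", {
  counts <- list(rep(c(9, 0), 10), rep(c(9, 0, 0), 7), rep(0, 20),
                 rep(c(9, 9, 0), 7))
  s <- pecos_summary(counts, threshold = 5, Q = 0.01)
  expect_equal(nrow(s$counts), 4)
  expect_equal(s$n_kept + s$n_outliers, 4)
})
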