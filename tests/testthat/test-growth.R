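# Cartwheel-growth (rise-then-plateau) and oscillation parameter extraction.

test_that("noise-free growth parameters are recovered exactly", {
  prof <- sim_profile("rise_plateau", c(y0 = 0, rate = 2 / 60, period = 300),
                      seq(0, 720, 30))
  g <- fit_growth(prof)
  expect_lt(abs(g$rate - 2 / 60) / (2 / 60), 1e-6)
  expect_lt(abs(g$period - 300) / 300, 1e-6)
  expect_lt(abs(g$size - 10) / 10, 1e-6)
  expect_equal(g$size, g$y0 + g$rate * g$period, tolerance = 1e-12)
})

test_that("rescaling data scales rate and size but not period", {
  prof <- sim_profile("rise_plateau", c(y0 = 0.2, rate = 0.02, period = 240),
                      seq(0, 600, 30), noise_sd = 0.05, seed = 8)
  g1 <- fit_growth(prof)
  prof_k <- dplyr::mutate(prof, intensity = 4 * .data$intensity)
  g2 <- fit_growth(prof_k)
  expect_equal(g2$rate, 4 * g1$rate, tolerance = 1e-8)
  expect_equal(g2$size, 4 * g1$size, tolerance = 1e-8)
  expect_equal(g2$period, g1$period, tolerance = 1e-8)
})

test_that("monotone data with no plateau pins the period at the window end", {
  prof <- tibble::tibble(time_s = seq(0, 600, 30),
                         intensity = 0.01 * seq(0, 600, 30))
  g <- fit_growth(prof)
  expect_true(g$boundary)
  expect_equal(g$period, 600)
})

test_that("noisy growth cohorts recover rate and period within 10%", {
  gp <- sim_growth_profiles(20, noise_sd = 0.05 * 10, seed = 3)
  gf <- fit_growth_profiles(gp$profiles)
  expect_lt(median(abs(gf$rate - 2 / 60) / (2 / 60)), 0.1)
  expect_lt(median(abs(gf$period - 300) / 300), 0.1)
  expect_equal(gf$size, gf$y0 + gf$rate * gf$period, tolerance = 1e-10)
})

test_that("programmed homeostatic regimes are recovered in the right order", {
  # fast/short vs slow/long growth, same target size
  fast <- sim_growth_profiles(8, rate = 0.05, period = 200,
                              noise_sd = 0.3, seed = 11)
  slow <- sim_growth_profiles(8, rate = 0.025, period = 400,
                              noise_sd = 0.3, seed = 12)
  f_fit <- fit_growth_profiles(fast$profiles)
  s_fit <- fit_growth_profiles(slow$profiles)
  expect_gt(mean(f_fit$rate), mean(s_fit$rate))
  expect_lt(mean(f_fit$period), mean(s_fit$period))
  expect_equal(mean(f_fit$size), mean(s_fit$size), tolerance = 0.1)
})

test_that("oscillation amplitude and centre match a noise-free Lorentzian", {
  prof <- sim_profile("lorentzian", c(B = 0.2, A = 0.8, t0 = 120,
                                      gamma = 90), seq(0, 600, 15))
  osc <- fit_oscillation(prof)
  expect_equal(osc$amplitude, 0.8, tolerance = 1e-4)
  expect_equal(osc$centre, 120, tolerance = 1e-3)
})

test_that("time-shifting a profile shifts the centre, not the amplitude", {
  par <- c(B = 0.2, A = 0.8, t0 = 180, gamma = 90)
  prof <- sim_profile("lorentzian", par, seq(0, 600, 15),
                      noise_sd = 0.02, seed = 4)
  osc1 <- fit_oscillation(prof)
  prof2 <- dplyr::mutate(prof, time_s = .data$time_s + 60)
  osc2 <- fit_oscillation(prof2)
  expect_equal(osc2$centre - osc1$centre, 60, tolerance = 1)
  expect_equal(osc2$amplitude, osc1$amplitude, tolerance = 1e-6)
})

test_that("cohorts with different programmed amplitudes are separated", {
  times <- seq(0, 585, 15)
  amp <- function(a, seed0) {
    vapply(1:16, function(i) {
      prof <- sim_profile("lorentzian",
                          c(B = 0.2, A = a, t0 = 300, gamma = 120),
                          times, noise_sd = 0.05 * a, seed = seed0 + i)
      fit_oscillation(prof)$amplitude
    }, numeric(1))
  }
  hi <- amp(1.0, 900)
  lo <- amp(0.6, 950)
  expect_gt(mean(hi), mean(lo))
  expect_lt(t.test(hi, lo)$p.value, 0.05)
})
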