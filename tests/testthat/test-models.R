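# Temporal model fitting and BIC model selection.

test_that("noise-free Lorentzian parameters are recovered essentially exactly", {
  prof <- sim_profile("lorentzian", c(B = 0.1, A = 1, t0 = 300, gamma = 120),
                      times = seq(0, 600, length.out = 40))
  fit <- fit_recruitment(prof, "lorentzian")
  expect_true(fit$converged)
  truth <- c(B = 0.1, A = 1, t0 = 300, gamma = 120)
  expect_lt(max(abs(fit$par - truth) / truth), 1e-6)
})

test_that("each noise-free generator is recovered by its own model class", {
  times <- seq(0, 585, 15)
  for (m in names(repertoire_params())) {
    par <- repertoire_params()[[m]]
    prof <- sim_profile(m, par, times)
    fit <- fit_recruitment(prof, m)
    expect_lt(fit$rss, 1e-12)
    expect_equal(unname(fit$par[names(par)]), unname(par), tolerance = 1e-4)
  }
})

test_that("BIC consistency: the generating model wins on noise-free data", {
  times <- seq(0, 585, 15)
  for (m in names(repertoire_params())) {
    fit <- select_best_model(sim_profile(m, repertoire_params()[[m]], times))
    expect_equal(fit$model, m)
    cand <- fit$candidates
    expect_true(all(cand$bic[cand$model == m] <= cand$bic))
  }
})

test_that("a constant profile degenerates gracefully (near-zero slopes)", {
  prof <- tibble::tibble(time_s = seq(0, 585, 15), intensity = 0.5)
  fit <- fit_recruitment(prof, "inc_const_dec")
  expect_lt(abs(fit$par[["m1"]]), 1e-8)
  expect_lt(abs(fit$par[["m2"]]), 1e-8)
  expect_lt(fit$rss, 1e-12)
})

test_that("ties are broken toward fewer parameters then repertoire order", {
  # constant data: every model can reach rss ~ 0; inc_const_dec (k = 5)
  # must not win, and lorentzian (listed first among k = 4) must
  prof <- tibble::tibble(time_s = seq(0, 585, 15),
                         intensity = rep(0.5, 40))
  fit <- select_best_model(prof)
  expect_equal(fit$k_params, 4)
})

test_that("model selection distinguishes the smooth models at 5% noise", {
  hits <- vapply(1:25, function(i) {
    prof <- sim_profile("gaussian", repertoire_params()$gaussian,
                        seq(0, 585, 15), noise_sd = 0.05, seed = 500 + i)
    select_best_model(prof)$model == "gaussian"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("selection accuracy does not degrade with more timepoints", {
  acc <- vapply(c(15, 30, 60), function(n) {
    mean(vapply(1:20, function(i) {
      prof <- sim_profile("lorentzian", repertoire_params()$lorentzian,
                          seq(0, 585, length.out = n), noise_sd = 0.05,
                          seed = 700 + i)
      select_best_model(prof)$model == "lorentzian"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.051)) # non-decreasing up to MC wobble
  expect_gte(acc[3], acc[1])
})

test_that("too few points for a model is an explicit error", {
  prof <- tibble::tibble(time_s = seq(0, 120, 30), intensity = 1:5 / 5)
  expect_error(fit_recruitment(prof, "inc_const_dec"), "more points")
})

test_that("model_curve validates names and model identity", {
  expect_error(model_curve("lorentzian", c(B = 0, A = 1), 0:10), "needs")
  expect_error(model_curve("sine", c(B = 0), 0:10))
  t <- seq(0, 600, 30)
  y <- model_curve("inc_dec", c(y0 = 0, m1 = 2, m2 = -1, t_b = 300), t)
  expect_equal(y[t <= 300], 2 * t[t <= 300])
  expect_equal(y[t > 300], 600 - (t[t > 300] - 300))
})

test_that("predict() reproduces the fitted curve on new data", {
  prof <- lorentzian_profile()
  fit <- fit_recruitment(prof, "lorentzian")
  expect_equal(predict(fit, tibble::tibble(time_s = c(0, 300))),
               model_curve("lorentzian", fit$par, c(0, 300)))
})

test_that("tidy and glance expose parameters and fit diagnostics", {
  fit <- fit_recruitment(lorentzian_profile(), "lorentzian")
  td <- tidy(fit)
  expect_equal(td$term, c("B", "A", "t0", "gamma"))
  gl <- glance(fit)
  expect_equal(gl$model, "lorentzian")
  expect_true(is.finite(gl$bic))
})
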