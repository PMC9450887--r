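# Elliptical annular Gaussian fitting, orientation filter, radius summary.

test_that("noise-free circle is recovered to well under 0.1%", {
  img <- sim_ring_image(ring_spec(a = 150, b = 150, w = 40))
  fit <- fit_ring(img)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 150) / 150, 1e-3)
  expect_lt(abs(fit$b - 150) / 150, 1e-3)
  expect_lt(abs(fit$w - 40) / 40, 1e-3)
  expect_lt(abs(fit$eccentricity - 1), 1e-3)
})

test_that("noise-free ellipse recovers eccentricity 1.30 and orientation", {
  img <- sim_ring_image(ring_spec(a = 130, b = 100, w = 30, theta = 0.7))
  fit <- fit_ring(img)
  expect_equal(fit$eccentricity, 1.30, tolerance = 1e-3)
  expect_equal(fit$theta, 0.7, tolerance = 1e-3)
  expect_equal(fit$mean_radius, 115, tolerance = 0.1)
})

test_that("adding a constant shifts only the background estimate", {
  img <- sim_ring_image(ring_spec(a = 160, b = 120, theta = 0.3, w = 35))
  fit0 <- fit_ring(img)
  img_c <- img
  img_c$pixels <- img$pixels + 0.7
  fit_c <- fit_ring(img_c)
  expect_equal(fit_c$B, fit0$B + 0.7, tolerance = 1e-6)
  expect_equal(fit_c$a, fit0$a, tolerance = 1e-6)
  expect_equal(fit_c$b, fit0$b, tolerance = 1e-6)
  expect_equal(fit_c$A, fit0$A, tolerance = 1e-6)
})

test_that("intensity rescaling scales A and B, leaving geometry unchanged", {
  img <- sim_ring_image(ring_spec(a = 170, b = 140, theta = 1.1, w = 45,
                                  noise = "gaussian", noise_sd = 0.02),
                        seed = 5)
  fit0 <- fit_ring(img)
  img_k <- img
  img_k$pixels <- img$pixels * 3
  fit_k <- fit_ring(img_k)
  expect_equal(fit_k$A, 3 * fit0$A, tolerance = 1e-4)
  expect_equal(fit_k$B, 3 * fit0$B, tolerance = 1e-3)
  expect_equal(fit_k$mean_radius, fit0$mean_radius, tolerance = 1e-4)
  expect_equal(fit_k$w, fit0$w, tolerance = 1e-4)
})

test_that("rotating the image 90 degrees leaves the geometry unchanged", {
  img <- sim_ring_image(ring_spec(a = 160, b = 125, theta = 0.4, w = 40,
                                  noise = "gaussian", noise_sd = 0.03),
                        seed = 9)
  fit0 <- fit_ring(img)
  rot <- img
  rot$pixels <- t(img$pixels)[, rev(seq_len(ncol(img$pixels)))]
  fit_r <- fit_ring(rot)
  expect_lt(abs(fit_r$eccentricity - fit0$eccentricity) / fit0$eccentricity,
            0.005)
  expect_lt(abs(fit_r$w - fit0$w) / fit0$w, 0.005)
  expect_lt(abs(fit_r$mean_radius - fit0$mean_radius) / fit0$mean_radius,
            0.005)
})

test_that("constant images are rejected as no-ring failures", {
  img <- list(pixels = matrix(1, 32, 32), pixel_size = 40)
  expect_error(fit_ring(img), "constant")
})

test_that("eccentricity filter keeps exactly the sub-threshold fits", {
  fits <- tibble::tibble(eccentricity = c(1.05, 1.19, 1.25))
  kept <- select_oriented(fits, ecc_max = 1.2)
  expect_equal(kept$eccentricity, c(1.05, 1.19))
  # all circular: everything kept
  circ <- tibble::tibble(eccentricity = rep(1, 4))
  expect_equal(nrow(select_oriented(circ)), 4)
})

test_that("paired filtering requires both markers to pass", {
  fits <- tibble::tibble(eccentricity = c(1.1, 1.1))
  ref <- tibble::tibble(eccentricity = c(1.1, 1.3))
  kept <- select_oriented(fits, paired = ref)
  expect_equal(nrow(kept), 1)
  expect_error(select_oriented(fits,
                               paired = tibble::tibble(eccentricity = 1.1)),
               "same number of rows")
})

test_that("raising ecc_max never removes a previously kept fit", {
  set.seed(11)
  fits <- tibble::tibble(eccentricity = 1 + runif(50, 0, 0.6))
  kept_strict <- select_oriented(fits, ecc_max = 1.15)$eccentricity
  kept_loose <- select_oriented(fits, ecc_max = 1.35)$eccentricity
  expect_true(all(kept_strict %in% kept_loose))
})

test_that("radius summary reports mean, sample s.d. and n", {
  s <- summarize_radii(tibble::tibble(mean_radius = c(100, 200),
                                      w = c(40, 42)))
  expect_equal(s$mean_radius, 150)
  expect_equal(s$sd_radius, sd(c(100, 200)), tolerance = 1e-12)
  expect_equal(s$n, 2)
  expect_warning(s1 <- summarize_radii(tibble::tibble(mean_radius = 150,
                                                      w = 40)), "single")
  expect_equal(s1$sd_radius, 0)
  expect_error(summarize_radii(tibble::tibble(mean_radius = numeric(0),
                                              w = numeric(0))), "empty")
})

test_that("summary over noisy synthetic rings recovers the true radius", {
  rs <- sim_ring_set(25, radius_range = c(150, 150), ecc_range = c(1, 1),
                     noise = "gaussian", noise_sd = 0.05, seed = 21)
  fits <- fit_rings(rs$images)
  s <- summarize_radii(select_oriented(fits))
  expect_lt(abs(s$mean_radius - 150) / 150, 0.02)
})
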