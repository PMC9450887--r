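# Elliptical annular Gaussian fitting of end-on centriolar rings.
#
# The fitted model is the generator's noise-free model without the PSF term:
# the fitted width w absorbs the blur (a known, documented bias). Eight free
# parameters: centre (x, y), semi-axes a >= b, orientation theta, ring width
# w, amplitude A and background B.

#' Fit an elliptical annular Gaussian to a ring image
#'
#' Bounded Levenberg-Marquardt least squares of the elliptical annular
#' Gaussian ring model over its 8 parameters. Initialization (when `init` is
#' not supplied): centre from the intensity centroid after subtracting the
#' image median; initial radius from the argmax of the azimuthally averaged
#' radial profile; initial width from the profile FWHM / 2.355; initial
#' orientation 0. Axes are canonicalized to `a >= b` (swapping and rotating
#' theta by pi/2 if needed) and theta is reported in `[0, pi)`; for a circle
#' the orientation is unidentifiable and 0 is reported by convention.
#'
#' @param image A `ring_image` (see [sim_ring_image()]) or a list with
#'   `pixels` (matrix, at least 16x16) and `pixel_size` (nm/pixel).
#' @param init Optional named numeric vector or `ring_fit` supplying starting
#'   values (`center_x`, `center_y`, `a`, `b`, `theta`, `w`, `A`, `B`).
#' @param psf_sigma Known (calibrated) Gaussian PSF standard deviation (nm).
#'   Default 0 fits the unblurred ring model, in which case the fitted width
#'   absorbs the blur and the radius of small rings is biased inward; when
#'   the instrument PSF is known, supplying it makes the forward model blur
#'   the ring before computing residuals, removing that bias.
#' @return A `ring_fit`: centre, semi-axes (nm), `theta` (radians),
#'   `w` (nm), `A`, `B`, derived `eccentricity = a/b` and
#'   `mean_radius = (a + b)/2`, `rss` and a `converged` flag. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' img <- sim_ring_image(ring_spec(a = 150, b = 150, w = 40))
#' fit <- fit_ring(img)
#' fit$mean_radius
#' @export
fit_ring <- function(image, init = NULL, psf_sigma = 0) {
  if (!is.list(image) || is.null(image$pixels) || is.null(image$pixel_size)) {
    abort("`image` must have `pixels` and `pixel_size`.")
  }
  px <- image$pixels
  if (!is.matrix(px) || any(dim(px) < 16L)) {
    abort("`pixels` must be a matrix of at least 16x16.")
  }
  if (!all(is.finite(px))) abort("`pixels` must be finite.")
  psize <- check_number(image$pixel_size, "pixel_size", lower = 0,
                        strict_lower = TRUE)
  if (sd(px) == 0) abort("image is constant: no ring to fit.")
  n <- nrow(px)
  if (ncol(px) != n) abort("ring images must be square.")
  half_field <- n * psize / 2
  coord <- (seq_len(n) - (n + 1) / 2) * psize
  xg <- outer(rep(1, n), coord)
  yg <- outer(coord, rep(1, n))

  starts <- if (!is.null(init)) {
    p <- if (inherits(init, "ring_fit")) {
      unlist(init[c("center_x", "center_y", "a", "b", "theta", "w", "A", "B")])
    } else {
      init[c("center_x", "center_y", "a", "b", "theta", "w", "A", "B")]
    }
    list(unname(p))
  } else {
    ring_fit_init(px, xg, yg, psize)
  }

  nm <- c("center_x", "center_y", "a", "b", "theta", "w", "A", "B")
  lower <- c(-half_field, -half_field, 20, 20, -2 * pi, 5, 1e-12, -Inf)
  upper <- c(half_field, half_field, half_field, half_field, 2 * pi, 200, Inf,
             Inf)
  check_number(psf_sigma, "psf_sigma", lower = 0)
  sigma_px <- psf_sigma / psize
  resid_fun <- function(p) {
    names(p) <- nm
    model <- ring_model_image(as.list(p), psize, n)
    if (sigma_px > 0) model <- gaussian_blur(model, sigma_px)
    as.numeric(px - model)
  }
  # the orientation objective is multimodal: run from each candidate start
  # (moment-based theta plus rotated fallbacks) and keep the best optimum
  tol_rss <- 1e-12 * sum((px - mean(px))^2)
  best <- NULL
  for (start in starts) {
    start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    if (rss <= tol_rss) break # exact fit: no need for more starts
  }
  if (is.null(best)) {
    par <- setNames(starts[[1]], nm)
    return(new_ring_fit(par, rss = Inf, converged = FALSE, image = image))
  }
  par <- setNames(best$fit$par, nm)
  geom_idx <- c(3, 4, 6) # a, b, w
  at_bound <- any(abs(par[geom_idx] - lower[geom_idx]) < 1e-6) ||
    any(abs(par[geom_idx] - upper[geom_idx]) < 1e-6)
  converged <- best$fit$info %in% 1:4 && !at_bound
  new_ring_fit(par, rss = best$rss, converged = converged, image = image)
}

# Centroid + radial-profile + second-moment initialization. Returns a list
# of candidate starting vectors: the moment-based orientation/axis-ratio
# estimate first, then rotated fallbacks to escape orientation local optima.
ring_fit_init <- function(px, xg, yg, psize) {
  bg <- median(px)
  w0 <- pmax(px - bg, 0)
  tot <- sum(w0)
  if (tot <= 0) {
    cx <- 0; cy <- 0
  } else {
    cx <- sum(xg * w0) / tot
    cy <- sum(yg * w0) / tot
  }
  r <- sqrt((xg - cx)^2 + (yg - cy)^2)
  bins <- floor(r / psize)
  prof <- tapply(as.numeric(w0), bins, mean)
  radii <- (as.numeric(names(prof)) + 0.5) * psize
  if (length(prof) >= 3) { # light smoothing against pixel noise
    prof <- as.numeric(stats::filter(prof, rep(1 / 3, 3), sides = 2))
    prof[is.na(prof)] <- 0
  }
  imax <- which.max(prof)
  r0 <- radii[imax]
  half <- prof[imax] / 2
  above <- which(prof >= half)
  fwhm <- if (length(above) > 1) diff(range(radii[above])) else 2 * psize
  w0_est <- max(fwhm / 2.355, 1.5 * psize)
  # orientation and axis ratio from intensity second moments: for a thin
  # annulus var along the principal axes is ~ a^2/2 + w^2 vs b^2/2 + w^2
  mxx <- sum((xg - cx)^2 * w0) / tot
  myy <- sum((yg - cy)^2 * w0) / tot
  mxy <- sum((xg - cx) * (yg - cy) * w0) / tot
  theta0 <- 0.5 * atan2(2 * mxy, mxx - myy)
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)$values
  ratio <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12)) # >= 1
  ratio <- min(ratio, 2)
  r0 <- max(r0, 25)
  a0 <- r0 * sqrt(ratio)
  b0 <- r0 / sqrt(ratio)
  amp0 <- max(px) - bg
  lapply(c(0, pi / 4, -pi / 4, pi / 2), function(dth) {
    c(cx, cy, a0, b0, theta0 + dth, w0_est, amp0, bg)
  })
}

new_ring_fit <- function(par, rss, converged, image = NULL) {
  # canonicalize: a >= b, theta in [0, pi); circle -> theta 0
  if (par[["b"]] > par[["a"]]) {
    tmp <- par[["a"]]; par[["a"]] <- par[["b"]]; par[["b"]] <- tmp
    par[["theta"]] <- par[["theta"]] + pi / 2
  }
  par[["theta"]] <- par[["theta"]] %% pi
  if (abs(par[["a"]] - par[["b"]]) < 1e-9 * par[["a"]]) par[["theta"]] <- 0
  structure(
    list(center_x = par[["center_x"]], center_y = par[["center_y"]],
         a = par[["a"]], b = par[["b"]], theta = par[["theta"]],
         w = par[["w"]], A = par[["A"]], B = par[["B"]],
         eccentricity = par[["a"]] / par[["b"]],
         mean_radius = (par[["a"]] + par[["b"]]) / 2,
         rss = rss, converged = converged, image = image),
    class = "ring_fit"
  )
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf(
    "<ring_fit> radius = %.1f nm (a = %.1f, b = %.1f, ecc = %.3f), w = %.1f nm\n",
    x$mean_radius, x$a, x$b, x$eccentricity, x$w))
  cat(sprintf("  A = %.3g, B = %.3g, theta = %.3f rad, rss = %.3g, converged = %s\n",
              x$A, x$B, x$theta, x$rss, x$converged))
  invisible(x)
}

#' Fit a set of ring images
#'
#' Applies [fit_ring()] to each image and collects the results into one row
#' per ring.
#'
#' @param images List of `ring_image` objects (e.g. `sim_ring_set()$images`).
#' @param psf_sigma Known PSF standard deviation (nm) passed to [fit_ring()].
#' @return Tibble with one row per image: all fit parameters plus
#'   `eccentricity`, `mean_radius`, `rss`, `converged` and `ring_id`.
#' @examples
#' rs <- sim_ring_set(2, seed = 1)
#' fit_rings(rs$images)
#' @export
fit_rings <- function(images, psf_sigma = 0) {
  dplyr::bind_rows(lapply(seq_along(images), function(i) {
    f <- fit_ring(images[[i]], psf_sigma = psf_sigma)
    dplyr::mutate(tidy_ring_row(f), ring_id = i, .before = 1)
  }))
}

tidy_ring_row <- function(f) {
  tibble::tibble(
    center_x = f$center_x, center_y = f$center_y, a = f$a, b = f$b,
    theta = f$theta, w = f$w, A = f$A, B = f$B,
    eccentricity = f$eccentricity, mean_radius = f$mean_radius,
    rss = f$rss, converged = f$converged
  )
}

#' Filter ring fits by orientation (eccentricity)
#'
#' Keeps rings whose fitted eccentricity (major:minor axis ratio) is below
#' `ecc_max`; rings below 1.2 are considered well oriented (viewed end-on).
#' When a paired reference-marker fit table is supplied (one reference ring
#' per centriole), both members of the pair must pass the filter for the
#' centriole to be kept.
#'
#' @param fits Data frame of ring fits with an `eccentricity` column (e.g.
#'   from [fit_rings()]).
#' @param ecc_max Eccentricity threshold; fits with `eccentricity < ecc_max`
#'   are kept. Default 1.2.
#' @param paired Optional data frame of the same length with the paired
#'   reference-marker fits.
#' @return The kept rows of `fits` (a tibble).
#' @examples
#' fits <- tibble::tibble(eccentricity = c(1.05, 1.19, 1.25))
#' select_oriented(fits)
#' @export
select_oriented <- function(fits, ecc_max = 1.2, paired = NULL) {
  check_columns(fits, "eccentricity", "fits")
  check_number(ecc_max, "ecc_max", lower = 1)
  keep <- fits$eccentricity < ecc_max
  if (!is.null(paired)) {
    check_columns(paired, "eccentricity", "paired")
    if (nrow(paired) != nrow(fits)) {
      abort("`paired` must have the same number of rows as `fits`.")
    }
    keep <- keep & paired$eccentricity < ecc_max
  }
  if ("converged" %in% names(fits)) keep <- keep & fits$converged
  tibble::as_tibble(fits[keep, , drop = FALSE])
}

#' Summarize ring radii and widths
#'
#' Mean and sample standard deviation of the mean radius `(a + b)/2` and of
#' the ring width across a set of (typically orientation-filtered) ring fits.
#'
#' @param fits Data frame with `mean_radius` and `w` columns.
#' @return One-row tibble: `n`, `mean_radius`, `sd_radius`, `mean_width`,
#'   `sd_width`. With a single fit the standard deviations are reported as 0
#'   and a warning is issued.
#' @examples
#' summarize_radii(tibble::tibble(mean_radius = c(100, 200), w = c(40, 42)))
#' @export
summarize_radii <- function(fits) {
  check_columns(fits, c("mean_radius", "w"), "fits")
  if (nrow(fits) == 0) abort("no ring fits to summarize (empty input).")
  n <- nrow(fits)
  if (n == 1L) {
    warn("single ring fit: standard deviations reported as 0.")
  }
  tibble::tibble(
    n = n,
    mean_radius = mean(fits$mean_radius),
    sd_radius = if (n > 1) sd(fits$mean_radius) else 0,
    mean_width = mean(fits$w),
    sd_width = if (n > 1) sd(fits$w) else 0
  )
}
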