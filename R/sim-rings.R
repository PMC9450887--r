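# Synthetic generator for super-resolution images of end-on centriolar rings.
#
# A ring is modelled as an elliptical annular Gaussian: at image position p
# with rotated, centred coordinates (u, v),
#   I(p) = B + A * exp(-d(p)^2 / (2 w^2)),
#   d(p) = (sqrt((u/a)^2 + (v/b)^2) - 1) * sqrt(a * b),
# i.e. a Gaussian cross-section of width w (nm, via the geometric-mean radius
# scaling) around an ellipse with semi-axes a >= b. The image is then blurred
# with a Gaussian PSF and corrupted with noise; the generating parameters are
# stored with the image so downstream fits can be scored exactly.

#' Specify a synthetic ring image
#'
#' Parameters of the elliptical annular Gaussian ground truth plus the imaging
#' model (pixel size, PSF, noise) used by [sim_ring_image()].
#'
#' @param center_x,center_y Ring centre offset from the image centre (nm).
#' @param a,b Semi-major and semi-minor axes (nm); `a >= b > 0`.
#' @param theta Ellipse orientation (radians).
#' @param w Ring (annulus cross-section) Gaussian width (nm).
#' @param A Ring amplitude above background (a.u.).
#' @param B Constant background (a.u.).
#' @param pixel_size Pixel size (nm/pixel).
#' @param image_size Image side length (pixels, >= 16).
#' @param psf_sigma Gaussian PSF standard deviation (nm); 0 disables blurring.
#' @param noise Noise model: `"none"`, `"gaussian"` (additive, sd `noise_sd`)
#'   or `"poisson"` (shot noise at `gain` photons per a.u.).
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param gain Photons per intensity unit for Poisson noise.
#' @return A `ring_spec` list.
#' @examples
#' ring_spec(a = 150, b = 150, w = 40)
#' @export
ring_spec <- function(center_x = 0, center_y = 0, a = 150, b = a, theta = 0,
                      w = 40, A = 1, B = 0.1, pixel_size = 40,
                      image_size = 64, psf_sigma = 0,
                      noise = c("none", "gaussian", "poisson"),
                      noise_sd = 0.05, gain = 100) {
  noise <- match.arg(noise)
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  if (a < b) abort("`a` must be >= `b` (semi-major >= semi-minor).")
  check_number(w, "w", lower = 0, strict_lower = TRUE)
  check_number(A, "A", lower = 0, strict_lower = TRUE)
  check_number(B, "B", lower = 0)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_count(image_size, "image_size", lower = 16L)
  check_number(psf_sigma, "psf_sigma", lower = 0)
  half_field <- image_size * pixel_size / 2
  if (a + 3 * w > half_field) {
    abort(sprintf(
      "ring does not fit the field: a + 3w = %.0f nm exceeds half-field %.0f nm.",
      a + 3 * w, half_field))
  }
  structure(
    list(center_x = center_x, center_y = center_y, a = a, b = b,
         theta = theta, w = w, A = A, B = B, pixel_size = pixel_size,
         image_size = as.integer(image_size), psf_sigma = psf_sigma,
         noise = noise, noise_sd = noise_sd, gain = gain),
    class = "ring_spec"
  )
}

# Noise-free elliptical annular Gaussian evaluated on the pixel grid.
ring_model_image <- function(par, pixel_size, image_size) {
  n <- image_size
  coord <- (seq_len(n) - (n + 1) / 2) * pixel_size
  dx <- outer(rep(1, n), coord) - par[["center_x"]] # x varies along columns
  dy <- outer(coord, rep(1, n)) - par[["center_y"]] # y varies along rows
  ct <- cos(par[["theta"]]); st <- sin(par[["theta"]])
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  d <- (sqrt((u / par[["a"]])^2 + (v / par[["b"]])^2) - 1) *
    sqrt(par[["a"]] * par[["b"]])
  par[["B"]] + par[["A"]] * exp(-d^2 / (2 * par[["w"]]^2))
}

# Separable Gaussian convolution with replicate padding (exact for a constant
# background extending beyond the field).
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(x) { # one column/row with replicate padding
    xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Generate a synthetic ring image
#'
#' Renders the noise-free elliptical annular Gaussian of a [ring_spec()] on
#' the pixel grid, convolves with the Gaussian PSF, applies the noise model,
#' and stores the ground-truth parameters alongside the pixels.
#'
#' @param spec A [ring_spec()].
#' @param seed Integer seed for the noise draw (ignored for `noise = "none"`).
#' @return A `ring_image`: list with `pixels` (matrix, rows = y), `pixel_size`
#'   (nm/pixel) and `truth` (the generating parameters).
#' @examples
#' img <- sim_ring_image(ring_spec(a = 150, w = 40), seed = 1)
#' dim(img$pixels)
#' @export
sim_ring_image <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ring_spec"))
  clean <- ring_model_image(spec, spec$pixel_size, spec$image_size)
  img <- gaussian_blur(clean, spec$psf_sigma / spec$pixel_size)
  img <- with_seed(seed, {
    switch(spec$noise,
      none = img,
      gaussian = img + rnorm(length(img), sd = spec$noise_sd),
      poisson = {
        lam <- pmax(img, 0) * spec$gain
        matrix(rpois(length(lam), lam) / spec$gain, nrow = nrow(img))
      }
    )
  })
  structure(
    list(pixels = img, pixel_size = spec$pixel_size, truth = spec),
    class = "ring_image"
  )
}

#' Generate a set of rings with randomized geometry
#'
#' Draws `n` ring specifications with mean radius and eccentricity sampled
#' uniformly from the given ranges (orientation uniform on `[0, pi)`, centre
#' jittered by up to one pixel) and renders each with [sim_ring_image()].
#'
#' @param n Number of rings.
#' @param radius_range Range of the mean radius `(a + b)/2` (nm).
#' @param ecc_range Range of the axis ratio `a/b` (>= 1).
#' @param w Ring width (nm).
#' @param A,B Amplitude and background (a.u.).
#' @param pixel_size,image_size,psf_sigma,noise,noise_sd Imaging model passed
#'   to [ring_spec()].
#' @param seed Integer seed; each ring gets a derived child seed.
#' @return List with `images` (list of `ring_image`) and `truth` (tibble of
#'   generating parameters, one row per ring).
#' @examples
#' rs <- sim_ring_set(3, seed = 1)
#' rs$truth
#' @export
sim_ring_set <- function(n, radius_range = c(100, 250), ecc_range = c(1, 1.4),
                         w = 40, A = 1, B = 0.1, pixel_size = 40,
                         image_size = 64, psf_sigma = 0, noise = "none",
                         noise_sd = 0.05, seed = 1) {
  n <- check_count(n, "n")
  draws <- with_seed(seed, {
    tibble::tibble(
      ring_id = seq_len(n),
      radius = runif(n, radius_range[1], radius_range[2]),
      ecc = runif(n, ecc_range[1], ecc_range[2]),
      theta = runif(n, 0, pi),
      center_x = runif(n, -pixel_size, pixel_size),
      center_y = runif(n, -pixel_size, pixel_size)
    )
  })
  draws$a <- 2 * draws$radius * draws$ecc / (1 + draws$ecc)
  draws$b <- 2 * draws$radius / (1 + draws$ecc)
  images <- lapply(seq_len(n), function(i) {
    sp <- ring_spec(center_x = draws$center_x[i], center_y = draws$center_y[i],
                    a = draws$a[i], b = draws$b[i], theta = draws$theta[i],
                    w = w, A = A, B = B, pixel_size = pixel_size,
                    image_size = image_size, psf_sigma = psf_sigma,
                    noise = noise, noise_sd = noise_sd)
    sim_ring_image(sp, seed = child_seed(seed, i))
  })
  truth <- dplyr::mutate(draws, w = w, A = A, B = B)
  list(images = images, truth = truth)
}
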