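# Synthetic generator for multi-embryo recruitment cohorts.
#
# Emulates live spinning-disk recordings of centriolar fluorescence in
# syncytial embryos: per embryo an S-phase window from centrosome separation
# (CS, t = 0) to nuclear envelope breakdown (NEB), per centriole an intensity
# track sampled every 30 s from a programmed temporal model, with
# photobleaching, constant background, multiplicative per-centriole brightness
# scatter and additive Gaussian noise. The peak time of each embryo's curve is
# programmed as an affine function of its S-phase length, which is what the
# cross-embryo correlation analysis is meant to recover.

#' Specify a synthetic recruitment cohort
#'
#' Defaults emulate the study conditions: ~20 embryos per group with ~50
#' tracked centrioles each, frames every 30 s, S-phase lengths spanning the
#' range of nuclear cycles 11-13 (~7-15 min), recruitment peaking around
#' mid-S-phase (slope 0.5 of S-phase length), Lorentzian-shaped recruitment,
#' 5% additive noise and 20% per-centriole brightness scatter.
#'
#' @param n_embryos Number of embryos (>= 1).
#' @param centrioles_per_embryo Tracked centrioles per embryo.
#' @param frame_interval Sampling interval (s); 30 s as in the recordings.
#' @param sphase_length_range Range (s) from which each embryo's S-phase
#'   length (CS to NEB) is drawn uniformly.
#' @param peak_time_slope,peak_time_intercept Programmed linear coupling
#'   `peak_time = intercept + slope * sphase_length + noise`.
#' @param peak_time_sd Embryo-to-embryo scatter (s) of the peak time around
#'   the programmed line.
#' @param true_model Generating temporal model (see [model_curve()]); one of
#'   `"lorentzian"`, `"gaussian"`, `"inc_const_dec"`, `"inc_dec"`.
#' @param amplitude,baseline Curve amplitude and baseline (a.u.).
#' @param width Width parameter (s) of the smooth models (`gamma` for the
#'   Lorentzian, `sigma` for the Gaussian).
#' @param plateau_frac For `"inc_const_dec"`: plateau length as a fraction of
#'   S-phase length, centred on the peak time.
#' @param bleach_tau Photobleaching time constant (s); `Inf` disables.
#' @param background_level Constant background (a.u.).
#' @param centriole_scatter_cv Coefficient of variation of the multiplicative
#'   (lognormal, mean 1) per-centriole brightness factor.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_embryos = 20, centrioles_per_embryo = 50,
                        frame_interval = 30,
                        sphase_length_range = c(420, 900),
                        peak_time_slope = 0.5, peak_time_intercept = 0,
                        peak_time_sd = 30,
                        true_model = "lorentzian",
                        amplitude = 1, baseline = 0.1, width = 120,
                        plateau_frac = 0.2,
                        bleach_tau = Inf, background_level = 0.1,
                        centriole_scatter_cv = 0.2, noise_sd = 0.05) {
  n_embryos <- check_count(n_embryos, "n_embryos")
  centrioles_per_embryo <- check_count(centrioles_per_embryo,
                                       "centrioles_per_embryo")
  check_number(frame_interval, "frame_interval", lower = 0,
               strict_lower = TRUE)
  if (length(sphase_length_range) != 2 || any(sphase_length_range <= 0) ||
      diff(sphase_length_range) < 0) {
    abort("`sphase_length_range` must be a positive, non-decreasing range.")
  }
  true_model <- match.arg(true_model, RECRUIT_MODELS)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(centriole_scatter_cv, "centriole_scatter_cv", lower = 0)
  check_number(background_level, "background_level", lower = 0)
  structure(
    list(n_embryos = n_embryos,
         centrioles_per_embryo = centrioles_per_embryo,
         frame_interval = frame_interval,
         sphase_length_range = as.numeric(sphase_length_range),
         peak_time_slope = peak_time_slope,
         peak_time_intercept = peak_time_intercept,
         peak_time_sd = peak_time_sd,
         true_model = true_model, amplitude = amplitude,
         baseline = baseline, width = width, plateau_frac = plateau_frac,
         bleach_tau = bleach_tau, background_level = background_level,
         centriole_scatter_cv = centriole_scatter_cv, noise_sd = noise_sd),
    class = "cohort_spec"
  )
}

# Model parameters for one embryo given its S-phase length and peak time.
cohort_model_par <- function(spec, sphase, peak_time) {
  switch(spec$true_model,
    lorentzian = c(B = spec$baseline, A = spec$amplitude, t0 = peak_time,
                   gamma = spec$width),
    gaussian = c(B = spec$baseline, A = spec$amplitude, t0 = peak_time,
                 sigma = spec$width),
    inc_dec = c(y0 = spec$baseline, m1 = spec$amplitude / peak_time,
                m2 = -spec$amplitude / max(sphase - peak_time,
                                           spec$frame_interval),
                t_b = peak_time),
    inc_const_dec = {
      half <- spec$plateau_frac * sphase / 2
      t1 <- max(peak_time - half, 2 * spec$frame_interval)
      t2 <- min(peak_time + half, sphase - 2 * spec$frame_interval)
      c(y0 = spec$baseline, m1 = spec$amplitude / t1,
        m2 = -spec$amplitude / max(sphase - t2, spec$frame_interval),
        t1 = t1, t2 = t2)
    }
  )
}

#' Simulate a multi-embryo recruitment cohort
#'
#' Draws per-embryo S-phase lengths and programmed peak times, then generates
#' per-centriole intensity tracks from the chosen temporal model with
#' bleaching, background, brightness scatter and noise. All randomness derives
#' from `seed` via per-embryo child seeds, so identical spec + seed gives
#' bit-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return An `embryo_cohort`: list with
#'   * `tracks`: tibble (`embryo_id`, `centriole_id`, `time_s`, `intensity`),
#'   * `landmarks`: tibble (`embryo_id`, `cs_s`, `neb_s`),
#'   * `truth`: tibble of generating parameters per embryo (`sphase_length`,
#'     `peak_time`, `model`, `par` list-column),
#'   * `spec`: the generating spec.
#' @examples
#' coh <- sim_embryo_cohort(cohort_spec(n_embryos = 3), seed = 1)
#' head(coh$tracks)
#' @export
sim_embryo_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  cv <- spec$centriole_scatter_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2 # lognormal scatter with mean exactly 1
  embryos <- lapply(seq_len(spec$n_embryos), function(e) {
    with_seed(child_seed(seed, e), {
      sphase <- runif(1, spec$sphase_length_range[1],
                      spec$sphase_length_range[2])
      peak_time <- spec$peak_time_intercept +
        spec$peak_time_slope * sphase +
        rnorm(1, sd = spec$peak_time_sd)
      par <- cohort_model_par(spec, sphase, peak_time)
      times <- seq(0, sphase, by = spec$frame_interval)
      curve <- model_curve(spec$true_model, par, times) *
        exp(-times / spec$bleach_tau)
      nc <- spec$centrioles_per_embryo
      scatter <- if (cv > 0) rlnorm(nc, meanlog, sdlog) else rep(1, nc)
      tracks <- tibble::tibble(
        embryo_id = sprintf("embryo_%02d", e),
        centriole_id = rep(seq_len(nc), each = length(times)),
        time_s = rep(times, times = nc),
        intensity = rep(scatter, each = length(times)) * rep(curve, nc) +
          spec$background_level +
          rnorm(nc * length(times), sd = spec$noise_sd)
      )
      list(
        tracks = tracks,
        landmarks = tibble::tibble(embryo_id = sprintf("embryo_%02d", e),
                                   cs_s = 0, neb_s = sphase),
        truth = tibble::tibble(embryo_id = sprintf("embryo_%02d", e),
                               sphase_length = sphase,
                               peak_time = peak_time,
                               model = spec$true_model,
                               par = list(par))
      )
    })
  })
  structure(
    list(tracks = dplyr::bind_rows(lapply(embryos, `[[`, "tracks")),
         landmarks = dplyr::bind_rows(lapply(embryos, `[[`, "landmarks")),
         truth = dplyr::bind_rows(lapply(embryos, `[[`, "truth")),
         spec = spec, seed = seed),
    class = "embryo_cohort"
  )
}

#' @export
print.embryo_cohort <- function(x, ...) {
  cat(sprintf(
    "<embryo_cohort> %d embryos x %d centrioles, model = %s, seed = %s\n",
    x$spec$n_embryos, x$spec$centrioles_per_embryo, x$spec$true_model,
    format(x$seed)))
  invisible(x)
}

#' Simulate a single intensity profile from a temporal model
#'
#' Evaluates a model curve on a time grid and adds Gaussian noise; the small
#' building block used for single-profile tests and growth/oscillation series.
#'
#' @param model,par Model name and parameters as in [model_curve()].
#' @param times Time grid (s).
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param seed Optional integer seed.
#' @return Tibble with `time_s` and `intensity`.
#' @examples
#' sim_profile("rise_plateau", c(y0 = 0, rate = 1 / 30, period = 300),
#'             times = seq(0, 600, 30))
#' @export
sim_profile <- function(model, par, times, noise_sd = 0, seed = NULL) {
  y <- model_curve(model, par, times)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(times), sd = noise_sd))
  }
  tibble::tibble(time_s = as.numeric(times), intensity = y)
}

#' Simulate a set of cartwheel-growth profiles
#'
#' Linear-rise-then-plateau incorporation curves with additive noise; ground
#' truth (`y0`, `rate`, `period`, `size`) is returned alongside.
#'
#' @param n Number of profiles.
#' @param times Time grid (s), typically `seq(0, sphase, 30)`.
#' @param y0 Baseline (a.u.).
#' @param rate Initial growth rate (a.u./s).
#' @param period Time (s) from CS to plateau onset.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param seed Integer seed.
#' @return List with `profiles` (tibble: `profile_id`, `time_s`, `intensity`)
#'   and `truth` (tibble, one row per profile).
#' @export
sim_growth_profiles <- function(n = 20, times = seq(0, 720, by = 30),
                                y0 = 0, rate = 2 / 60, period = 300,
                                noise_sd = 0, seed = 1) {
  n <- check_count(n, "n")
  profiles <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- sim_profile("rise_plateau", c(y0 = y0, rate = rate, period = period),
                     times, noise_sd = noise_sd, seed = child_seed(seed, i))
    dplyr::mutate(p, profile_id = i, .before = 1)
  }))
  truth <- tibble::tibble(profile_id = seq_len(n), y0 = y0, rate = rate,
                          period = period, size = y0 + rate * period)
  list(profiles = profiles, truth = truth)
}
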