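# Cartwheel-growth and kinase-oscillation parameter extraction.

#' Fit the cartwheel-growth model (linear rise, then plateau)
#'
#' Least-squares fit of `y = y0 + rate * min(t, period)` to an incorporation
#' profile: `rate` is the initial growth rate (a.u./s), `period` the time
#' from CS to plateau onset (s), and the plateau value
#' `size = y0 + rate * period` (a.u.) estimates the final cartwheel size.
#' The breakpoint is profiled over a grid of observed time points and refined
#' continuously. Monotonically increasing data with no plateau inside the
#' window pins `period` at the window end and sets the `boundary` flag.
#'
#' @param profile Data frame with `time_s` and `intensity` (or `mean`)
#'   columns spanning the S-phase window.
#' @return A `growth_fit`: `rate`, `period`, `size`, `y0`, `rss`, `bic`,
#'   `converged`, `boundary`, plus the underlying `recruit_fit`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' prof <- sim_profile("rise_plateau", c(y0 = 0, rate = 2/60, period = 300),
#'                     seq(0, 720, 30))
#' fit_growth(prof)
#' @export
fit_growth <- function(profile) {
  fit <- fit_recruitment(profile, model = "rise_plateau")
  rate <- unname(fit$par[["rate"]])
  period <- unname(fit$par[["period"]])
  y0 <- unname(fit$par[["y0"]])
  structure(
    list(rate = rate, period = period,
         size = y0 + rate * period, # algebraic identity, enforced here
         y0 = y0, rss = fit$rss, bic = fit$bic,
         converged = fit$converged, boundary = fit$boundary, fit = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> rate = %.4g a.u./s, period = %.4g s, size = %.4g a.u.%s\n",
    x$rate, x$period, x$size,
    if (x$boundary) " (period pinned at window end)" else ""))
  invisible(x)
}

#' Fit many growth profiles
#'
#' @param profiles Tibble with `profile_id`, `time_s`, `intensity` (e.g.
#'   `sim_growth_profiles()$profiles`).
#' @return Tibble, one row per profile: `profile_id`, `rate`, `period`,
#'   `size`, `y0`, `rss`, `boundary`.
#' @export
fit_growth_profiles <- function(profiles) {
  check_columns(profiles, c("profile_id", "time_s", "intensity"), "profiles")
  split <- dplyr::group_split(dplyr::group_by(profiles, .data$profile_id))
  dplyr::bind_rows(lapply(split, function(p) {
    g <- fit_growth(p)
    tibble::tibble(profile_id = p$profile_id[1], rate = g$rate,
                   period = g$period, size = g$size, y0 = g$y0,
                   rss = g$rss, boundary = g$boundary)
  }))
}

#' Fit the kinase-reporter oscillation
#'
#' Runs four-model selection on the profile and summarizes the oscillation
#' by its amplitude (peak intensity minus the fitted baseline: `B` for the
#' smooth models, `y0` for the piecewise models) and its centre (the peak
#' centre of [peak_metrics()]).
#'
#' @inheritParams fit_growth
#' @param cs,neb Optional S-phase landmarks (s); default to the fitted
#'   window.
#' @return An `oscillation_fit`: `amplitude` (a.u.), `centre` (s from CS),
#'   `model`, and the underlying `recruit_fit`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' prof <- sim_profile("lorentzian", c(B = 0.2, A = 0.8, t0 = 120, gamma = 90),
#'                     seq(0, 600, 15))
#' fit_oscillation(prof)
#' @export
fit_oscillation <- function(profile, cs = NULL, neb = NULL) {
  fit <- select_best_model(profile)
  pm <- peak_metrics(fit, cs = cs, neb = neb)
  baseline <- if (fit$model %in% c("lorentzian", "gaussian")) {
    unname(fit$par[["B"]])
  } else {
    unname(fit$par[["y0"]])
  }
  structure(
    list(amplitude = pm$peak_intensity - baseline,
         centre = pm$peak_centre,
         baseline = baseline,
         model = fit$model, fit = fit),
    class = "oscillation_fit"
  )
}

#' @export
print.oscillation_fit <- function(x, ...) {
  cat(sprintf(
    "<oscillation_fit> model = %s, amplitude = %.4g a.u., centre = %.4g s\n",
    x$model, x$amplitude, x$centre))
  invisible(x)
}
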