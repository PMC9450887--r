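# broom-style tidy()/glance() methods for the fitted-object classes.

#' @describeIn fit_ring Tidy the fitted ring parameters (one row per
#'   parameter).
#' @param x A `ring_fit`.
#' @param ... Unused.
#' @method tidy ring_fit
#' @export
tidy.ring_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_x", "center_y", "a", "b", "theta", "w", "A", "B"),
    estimate = c(x$center_x, x$center_y, x$a, x$b, x$theta, x$w, x$A, x$B),
    unit = c("nm", "nm", "nm", "nm", "rad", "nm", "a.u.", "a.u.")
  )
}

#' @describeIn fit_ring One-row fit summary (geometry, rss, convergence).
#' @method glance ring_fit
#' @export
glance.ring_fit <- function(x, ...) {
  tidy_ring_row(x)
}

#' @describeIn fit_recruitment Tidy the fitted parameters (one row per
#'   parameter).
#' @param x A `recruit_fit`.
#' @param ... Unused.
#' @method tidy recruit_fit
#' @export
tidy.recruit_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @describeIn fit_recruitment One-row fit summary (model, rss, BIC,
#'   convergence).
#' @method glance recruit_fit
#' @export
glance.recruit_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_points = x$n_points,
                 k_params = x$k_params, rss = x$rss, bic = x$bic,
                 converged = x$converged)
}

#' @describeIn fit_growth Tidy the growth parameters.
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rate", "period", "size", "y0"),
    estimate = c(x$rate, x$period, x$size, x$y0),
    unit = c("a.u./s", "s", "a.u.", "a.u.")
  )
}

#' @describeIn fit_growth One-row summary.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, period = x$period, size = x$size, y0 = x$y0,
                 rss = x$rss, bic = x$bic, boundary = x$boundary,
                 converged = x$converged)
}

#' @describeIn fit_oscillation Tidy the oscillation parameters.
#' @param x An `oscillation_fit`.
#' @param ... Unused.
#' @method tidy oscillation_fit
#' @export
tidy.oscillation_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "centre", "baseline"),
                 estimate = c(x$amplitude, x$centre, x$baseline),
                 unit = c("a.u.", "s", "a.u."))
}

#' @describeIn fit_oscillation One-row summary.
#' @method glance oscillation_fit
#' @export
glance.oscillation_fit <- function(x, ...) {
  tibble::tibble(model = x$model, amplitude = x$amplitude,
                 centre = x$centre, baseline = x$baseline)
}

#' @describeIn correlate_peak_with_sphase Tidy the correlation result.
#' @param x An `sphase_cor`.
#' @param ... Unused.
#' @method tidy sphase_cor
#' @export
tidy.sphase_cor <- function(x, ...) {
  tibble::tibble(
    term = c("r", "slope", "intercept"),
    estimate = c(x$r, x$slope, x$intercept)
  )
}

#' @describeIn correlate_peak_with_sphase One-row summary with the strength
#'   label.
#' @method glance sphase_cor
#' @export
glance.sphase_cor <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, slope = x$slope,
                 intercept = x$intercept,
                 strength_label = x$strength_label, n = x$n)
}
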