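# Peak metrics of fitted recruitment curves and the cross-embryo correlation
# between peak timing and S-phase length.

peak_centre_of <- function(fit) {
  switch(fit$model,
    lorentzian = fit$par[["t0"]],
    gaussian = fit$par[["t0"]],
    inc_dec = fit$par[["t_b"]],
    inc_const_dec = (fit$par[["t1"]] + fit$par[["t2"]]) / 2, # plateau midpoint
    rise_plateau = fit$par[["period"]]
  )
}

#' Peak metrics of a fitted recruitment curve
#'
#' Derives the quantities used to compare recruitment dynamics across
#' genotypes: peak intensity (model maximum over the S-phase window), the
#' absolute peak centre, the S-phase normalized peak centre, and the time
#' taken to reach peak intensity. The peak centre is `t0` for the smooth
#' models, the breakpoint for increase-decrease, and the plateau midpoint
#' `(t1 + t2)/2` for increase-constant-decrease.
#'
#' @param fit A `recruit_fit` from [fit_recruitment()].
#' @param cs,neb S-phase landmarks (s): centrosome separation and nuclear
#'   envelope breakdown. Default to the fitted window.
#' @return One-row tibble: `peak_intensity` (a.u.), `peak_centre` (s from
#'   CS), `normalized_peak_centre` (`peak_centre / (NEB - CS)`, in `[0, 1]`
#'   when the peak lies inside S-phase), `time_to_peak` (s) and an
#'   `out_of_window` flag set when the peak centre falls outside
#'   `[CS, NEB]`.
#' @examples
#' prof <- sim_profile("lorentzian", c(B = 0, A = 1, t0 = 300, gamma = 120),
#'                     seq(0, 600, 30))
#' fit <- fit_recruitment(prof, "lorentzian")
#' peak_metrics(fit, cs = 0, neb = 600)
#' @export
peak_metrics <- function(fit, cs = NULL, neb = NULL) {
  stopifnot(inherits(fit, "recruit_fit"))
  cs <- cs %||% fit$window[1]
  neb <- neb %||% fit$window[2]
  if (neb <= cs) abort("`neb` must exceed `cs`.")
  grid <- seq(cs, neb, length.out = 2001)
  peak_intensity <- max(model_curve(fit$model, fit$par, grid))
  centre <- unname(peak_centre_of(fit))
  tibble::tibble(
    peak_intensity = peak_intensity,
    peak_centre = centre,
    normalized_peak_centre = (centre - cs) / (neb - cs),
    time_to_peak = centre - cs,
    out_of_window = centre < cs | centre > neb
  )
}

#' Fit every embryo's profile and extract peak metrics
#'
#' Per-embryo wrapper: fits the chosen model (or selects among the four by
#' BIC) on each embryo's mean profile and combines fit diagnostics, peak
#' metrics and S-phase length into one row per embryo.
#'
#' @param profiles Output of [preprocess_tracks()] (or any tibble with
#'   `embryo_id`, `time_s`, `mean`), with a `landmarks` attribute or a
#'   `landmarks` argument.
#' @param model `"auto"` or a model name, as in [fit_recruitment()].
#' @param landmarks Optional landmarks table (`embryo_id`, `cs_s`, `neb_s`)
#'   overriding the attribute.
#' @return Tibble, one row per embryo: `embryo_id`, `model`, `bic`, `rss`,
#'   `converged`, `sphase_length`, the [peak_metrics()] columns, and a `fit`
#'   list-column with the underlying `recruit_fit` objects.
#' @examples
#' coh <- sim_embryo_cohort(cohort_spec(n_embryos = 3), seed = 1)
#' prof <- preprocess_tracks(coh$tracks, coh$landmarks)
#' fit_embryos(prof, model = "lorentzian")
#' @export
fit_embryos <- function(profiles, model = "auto", landmarks = NULL) {
  check_columns(profiles, c("embryo_id", "time_s", "mean"), "profiles")
  lmk <- landmarks %||% attr(profiles, "landmarks")
  if (is.null(lmk)) abort("supply `landmarks` (embryo_id, cs_s, neb_s).")
  check_columns(lmk, c("embryo_id", "cs_s", "neb_s"), "landmarks")
  split <- dplyr::group_split(dplyr::group_by(profiles, .data$embryo_id))
  rows <- lapply(split, function(p) {
    id <- p$embryo_id[1]
    li <- lmk[lmk$embryo_id == id, ]
    if (nrow(li) != 1) abort(sprintf("no landmarks for embryo '%s'.", id))
    sphase <- li$neb_s - li$cs_s
    fit <- fit_recruitment(p, model = model)
    pm <- peak_metrics(fit, cs = 0, neb = sphase)
    dplyr::bind_cols(
      tibble::tibble(embryo_id = id, model = fit$model, bic = fit$bic,
                     rss = fit$rss, converged = fit$converged,
                     sphase_length = sphase),
      pm,
      tibble::tibble(fit = list(fit)))
  })
  dplyr::bind_rows(rows)
}

strength_label <- function(r) {
  # correlation-strength bands: 0.40 < r < 0.60 moderate; r > 0.60 strong
  if (r > 0.6) "strong" else if (r > 0.4) "moderate" else "weak"
}

#' Correlate recruitment peak time with S-phase length
#'
#' Pearson correlation (two-sided p via the t transform) and least-squares
#' line between per-embryo S-phase length and recruitment peak centre, with
#' the strength bands used for this analysis (0.40 < r < 0.60 moderate;
#' r > 0.60 strong).
#'
#' @param metrics Data frame with one row per embryo containing
#'   `sphase_length` and `peak_centre` columns (e.g. from [fit_embryos()]).
#' @return An `sphase_cor` object: `r`, `p_value`, `slope`, `intercept`,
#'   `strength_label`, `n`, and the input pairs. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(sphase_length = c(400, 500, 600, 700),
#'                     peak_centre = c(210, 240, 310, 350))
#' correlate_peak_with_sphase(d)
#' @export
correlate_peak_with_sphase <- function(metrics) {
  check_columns(metrics, c("sphase_length", "peak_centre"), "metrics")
  x <- metrics$sphase_length
  y <- metrics$peak_centre
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 embryos for the correlation.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in peak time or S-phase length.")
  }
  ct <- cor.test(x, y, method = "pearson")
  line <- coef(lm(y ~ x))
  structure(
    list(r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(line[2]), intercept = unname(line[1]),
         strength_label = strength_label(unname(ct$estimate)),
         n = length(x),
         data = tibble::tibble(sphase_length = x, peak_centre = y)),
    class = "sphase_cor"
  )
}

#' @export
print.sphase_cor <- function(x, ...) {
  cat(sprintf(
    "<sphase_cor> r = %.3f (%s), p = %.3g, n = %d\n",
    x$r, x$strength_label, x$p_value, x$n))
  cat(sprintf("  peak_centre = %.3g + %.3g * sphase_length\n",
              x$intercept, x$slope))
  invisible(x)
}
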