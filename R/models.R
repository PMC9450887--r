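# Temporal models for centriolar recruitment dynamics.
#
# The candidate repertoire for S-phase recruitment curves is: Lorentzian,
# Gaussian, increase-constant-decrease and increase-decrease. A fifth model,
# the linear-rise-then-plateau used for cartwheel growth, shares the same
# machinery. All fits are ordinary least squares on the per-embryo mean curve;
# candidate models are compared with the Bayesian Information Criterion
# BIC = n*ln(RSS/n) + k*ln(n).

RECRUIT_MODELS <- c("lorentzian", "gaussian", "inc_const_dec", "inc_dec")

model_par_names <- function(model) {
  switch(model,
    lorentzian    = c("B", "A", "t0", "gamma"),
    gaussian      = c("B", "A", "t0", "sigma"),
    inc_dec       = c("y0", "m1", "m2", "t_b"),
    inc_const_dec = c("y0", "m1", "m2", "t1", "t2"),
    rise_plateau  = c("y0", "rate", "period"),
    abort(sprintf("unknown model '%s'", model))
  )
}

#' Evaluate a recruitment/growth model curve
#'
#' Computes the noise-free intensity of one of the five temporal models used
#' throughout the package on a vector of time points.
#'
#' Parameterizations (time `t` in seconds from centrosome separation):
#' * `lorentzian`: `B + A / (1 + ((t - t0)/gamma)^2)` (`gamma` = half-width
#'   at half-maximum).
#' * `gaussian`: `B + A * exp(-(t - t0)^2 / (2 sigma^2))`.
#' * `inc_dec`: continuous piecewise line `y0 + m1*min(t, t_b) +
#'   m2*max(t - t_b, 0)` rising with slope `m1` to a breakpoint `t_b`, then
#'   changing to slope `m2`.
#' * `inc_const_dec`: `y0 + m1*min(t, t1) + m2*max(t - t2, 0)`; rise, plateau
#'   on `[t1, t2]`, then fall.
#' * `rise_plateau`: `y0 + rate*min(t, period)`, the cartwheel-growth model.
#'
#' @param model Model name, one of `"lorentzian"`, `"gaussian"`,
#'   `"inc_const_dec"`, `"inc_dec"`, `"rise_plateau"`.
#' @param par Named numeric vector of model parameters (see Details).
#' @param t Numeric vector of times (s).
#' @return Numeric vector of model intensities (a.u.), same length as `t`.
#' @examples
#' t <- seq(0, 600, by = 30)
#' model_curve("lorentzian", c(B = 0.1, A = 1, t0 = 300, gamma = 120), t)
#' @export
model_curve <- function(model, par, t) {
  model <- match.arg(model, c(RECRUIT_MODELS, "rise_plateau"))
  need <- model_par_names(model)
  if (!all(need %in% names(par))) {
    abort(sprintf("model '%s' needs parameters: %s", model,
                  paste(need, collapse = ", ")))
  }
  p <- as.list(par[need])
  switch(model,
    lorentzian = p$B + p$A / (1 + ((t - p$t0) / p$gamma)^2),
    gaussian   = p$B + p$A * exp(-(t - p$t0)^2 / (2 * p$sigma^2)),
    inc_dec    = p$y0 + p$m1 * pmin(t, p$t_b) + p$m2 * pmax(t - p$t_b, 0),
    inc_const_dec =
      p$y0 + p$m1 * pmin(t, p$t1) + p$m2 * pmax(t - p$t2, 0),
    rise_plateau = p$y0 + p$rate * pmin(t, p$period)
  )
}

# Gaussian-likelihood BIC; RSS floored so an exact fit on noise-free data
# yields a large negative but finite criterion.
bic_from_rss <- function(rss, n, k) {
  n * log(max(rss, 1e-300) / n) + k * log(n)
}

new_recruit_fit <- function(model, par, rss, n, converged,
                            t, y, window, boundary = FALSE,
                            candidates = NULL) {
  k <- length(model_par_names(model))
  structure(
    list(
      model = model,
      par = par,
      rss = rss,
      n_points = n,
      k_params = k,
      bic = bic_from_rss(rss, n, k),
      converged = converged,
      boundary = boundary,
      window = window,
      data = tibble::tibble(time_s = t, intensity = y),
      candidates = candidates
    ),
    class = "recruit_fit"
  )
}

#' @export
print.recruit_fit <- function(x, ...) {
  cat(sprintf("<recruit_fit> model = %s (k = %d, n = %d)\n",
              x$model, x$k_params, x$n_points))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  rss = %.4g, BIC = %.2f, converged = %s\n",
              x$rss, x$bic, x$converged))
  if (!is.null(x$candidates)) {
    cat("  candidates (BIC):",
        paste(sprintf("%s %.1f", x$candidates$model, x$candidates$bic),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- smooth-model fitting (Lorentzian / Gaussian) ---------------------------

fit_smooth_model <- function(t, y, model, weights) {
  span <- diff(range(t))
  b0 <- min(y)
  a0 <- max(y) - b0
  if (a0 <= 0) a0 <- max(abs(y), 1e-6)
  t0_0 <- t[which.max(y)]
  wid0 <- span / 6
  start <- c(b0, a0, t0_0, wid0)
  lower <- c(-Inf, 1e-12, min(t) - 0.5 * span, span / 1e4)
  upper <- c(Inf, Inf, max(t) + 0.5 * span, Inf)
  sw <- sqrt(weights)
  nm <- model_par_names(model)
  resid_fun <- function(p) {
    names(p) <- nm
    (y - model_curve(model, p, t)) * sw
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(par = setNames(start, nm), rss = Inf, converged = FALSE))
  }
  par <- setNames(fit$par, nm)
  # widths are symmetric in sign under the model; canonicalize to positive
  par[4] <- abs(par[4])
  at_bound <- (par["t0"] <= lower[3] + 1e-9) || (par["t0"] >= upper[3] - 1e-9)
  converged <- fit$info %in% 1:4 && !at_bound
  list(par = par, rss = sum(((y - model_curve(model, par, t)) * sw)^2),
       converged = converged)
}

# ---- piecewise-linear fitting ----------------------------------------------

# Given fixed breakpoints, the piecewise models are linear in the remaining
# parameters; solve by least squares (rank-deficient designs fall back to the
# pivoted solution with dropped columns treated as zero).
pw_ls <- function(X, y, weights) {
  sw <- sqrt(weights)
  fit <- stats::lm.fit(X * sw, y * sw)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta, rss = sum(fit$residuals^2))
}

pw_design <- function(model, t, brk) {
  if (model == "inc_dec") {
    cbind(1, pmin(t, brk[1]), pmax(t - brk[1], 0))
  } else if (model == "inc_const_dec") {
    cbind(1, pmin(t, brk[1]), pmax(t - brk[2], 0))
  } else { # rise_plateau
    cbind(1, pmin(t, brk[1]))
  }
}

pw_rss_at <- function(model, t, y, weights, brk) {
  pw_ls(pw_design(model, t, brk), y, weights)$rss
}

fit_piecewise_model <- function(t, y, model, weights) {
  n <- length(t)
  # breakpoints at data times, keeping >= 2 points in each segment
  idx <- seq_len(n)
  cand <- t[idx >= 2 & idx <= n - 1]
  boundary <- FALSE
  if (model == "inc_dec" || model == "rise_plateau") {
    rss_grid <- vapply(cand, function(b) pw_rss_at(model, t, y, weights, b),
                       numeric(1))
    i <- which.min(rss_grid)
    lo <- if (i > 1) cand[i - 1] else cand[1]
    hi <- if (i < length(cand)) cand[i + 1] else cand[length(cand)]
    brk <- cand[i]
    if (hi > lo) {
      op <- optimize(function(b) pw_rss_at(model, t, y, weights, b),
                     interval = c(lo, hi), tol = 1e-10 * diff(range(t)))
      if (op$objective <= rss_grid[i]) brk <- op$minimum
    }
    if (model == "rise_plateau" && i == length(cand)) {
      # no plateau reached inside the window: pin at the window end
      grow_end <- pw_rss_at(model, t, y, weights, max(t))
      if (grow_end <= pw_rss_at(model, t, y, weights, brk) + 1e-12) {
        brk <- max(t)
        boundary <- TRUE
      }
    }
    sol <- pw_ls(pw_design(model, t, brk), y, weights)
    if (model == "inc_dec") {
      par <- c(y0 = unname(sol$beta[1]), m1 = unname(sol$beta[2]),
               m2 = unname(sol$beta[3]), t_b = brk)
    } else {
      par <- c(y0 = unname(sol$beta[1]), rate = unname(sol$beta[2]),
               period = brk)
    }
    return(list(par = par, rss = sol$rss, converged = TRUE,
                boundary = boundary))
  }
  # inc_const_dec: grid over ordered breakpoint pairs, then local refinement
  pairs <- expand.grid(i = seq_along(cand), j = seq_along(cand))
  pairs <- pairs[pairs$j > pairs$i, , drop = FALSE]
  rss_grid <- mapply(function(i, j) {
    pw_rss_at(model, t, y, weights, c(cand[i], cand[j]))
  }, pairs$i, pairs$j)
  best <- which.min(rss_grid)
  b1 <- cand[pairs$i[best]]
  b2 <- cand[pairs$j[best]]
  tmin <- t[2]; tmax <- t[n - 1]
  obj <- function(b) {
    if (b[1] < tmin || b[2] > tmax || b[2] <= b[1]) return(Inf)
    pw_rss_at(model, t, y, weights, b)
  }
  op <- tryCatch(
    optim(c(b1, b2), obj, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 500)),
    error = function(e) NULL
  )
  brk <- c(b1, b2)
  rss <- rss_grid[best]
  if (!is.null(op) && is.finite(op$value) && op$value <= rss) {
    brk <- op$par
    rss <- op$value
  }
  sol <- pw_ls(pw_design(model, t, brk), y, weights)
  par <- c(y0 = unname(sol$beta[1]), m1 = unname(sol$beta[2]),
           m2 = unname(sol$beta[3]), t1 = brk[1], t2 = brk[2])
  list(par = par, rss = sol$rss, converged = TRUE, boundary = FALSE)
}

# ---- public fitting surface -------------------------------------------------

#' Fit a temporal model to a recruitment profile
#'
#' Least-squares fit of one of the four candidate recruitment models (or the
#' rise-then-plateau growth model) to a per-embryo mean intensity profile.
#' With `model = "auto"` all four recruitment models are fitted and the one
#' with the lowest BIC is returned (ties broken toward fewer parameters, then
#' the fixed repertoire order Lorentzian, Gaussian, increase-constant-decrease,
#' increase-decrease).
#'
#' @param profile Data frame with columns `time_s` and `intensity` (a.u.), or
#'   the `mean` column of [preprocess_tracks()] output (`mean` is used when
#'   `intensity` is absent). One embryo's profile.
#' @param model `"auto"` or a specific model name.
#' @param weights Optional per-point weights for weighted least squares;
#'   default is unweighted (the profile is a mean curve).
#' @return A `recruit_fit` object: model name, named parameter vector, `rss`,
#'   `n_points`, `k_params`, `bic`, `converged` flag, and (for `"auto"`) a
#'   `candidates` tibble with the BIC of every model tried. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @seealso [select_best_model()], [peak_metrics()], [model_curve()]
#' @examples
#' prof <- sim_profile("lorentzian", c(B = 0.1, A = 1, t0 = 300, gamma = 120),
#'                     times = seq(0, 600, 30))
#' fit <- fit_recruitment(prof, model = "lorentzian")
#' fit$par
#' @export
fit_recruitment <- function(profile, model = "auto", weights = NULL) {
  check_columns(profile, "time_s", "profile")
  ycol <- if ("intensity" %in% names(profile)) "intensity" else "mean"
  check_columns(profile, ycol, "profile")
  t <- as.numeric(profile$time_s)
  y <- as.numeric(profile[[ycol]])
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (is.unsorted(t, strictly = FALSE)) {
    o <- order(t); t <- t[o]; y <- y[o]
  }
  n <- length(t)
  models <- if (identical(model, "auto")) RECRUIT_MODELS else {
    match.arg(model, c(RECRUIT_MODELS, "rise_plateau"))
  }
  for (m in models) {
    if (n <= length(model_par_names(m))) {
      abort(sprintf(
        "profile has %d points; model '%s' needs more points than parameters (%d).",
        n, m, length(model_par_names(m))))
    }
  }
  w <- weights %||% rep(1, n)
  if (length(w) != n) abort("`weights` must match the number of points.")
  window <- range(t)

  fit_one <- function(m) {
    res <- if (m %in% c("lorentzian", "gaussian")) {
      c(fit_smooth_model(t, y, m, w), boundary = FALSE)
    } else {
      fit_piecewise_model(t, y, m, w)
    }
    new_recruit_fit(m, res$par, if (res$converged) res$rss else Inf, n,
                    res$converged, t, y, window,
                    boundary = isTRUE(res$boundary))
  }

  if (length(models) == 1L) return(fit_one(models))

  fits <- lapply(models, fit_one)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  ks <- vapply(fits, function(f) f$k_params, numeric(1))
  ok <- vapply(fits, function(f) f$converged && is.finite(f$bic), logical(1))
  if (sum(ok) < 2L) {
    if (!any(ok)) abort("all candidate model fits failed to converge.")
    warn("only one candidate model converged; selection is trivial.")
  }
  ord <- order(!ok, bics, ks, seq_along(models))
  best <- fits[[ord[1]]]
  best$candidates <- tibble::tibble(
    model = vapply(fits, function(f) f$model, character(1)),
    k_params = ks,
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    bic = bics,
    converged = !vapply(fits, function(f) !f$converged, logical(1)),
    selected = seq_along(fits) == ord[1]
  )
  best
}

#' Select the best recruitment model by BIC
#'
#' Convenience wrapper for [fit_recruitment()] with `model = "auto"`: fits the
#' full four-model repertoire and returns the lowest-BIC fit.
#'
#' @inheritParams fit_recruitment
#' @return A `recruit_fit` with a `candidates` tibble recording every model's
#'   BIC.
#' @examples
#' prof <- sim_profile("gaussian", c(B = 0, A = 1, t0 = 250, sigma = 90),
#'                     times = seq(0, 600, 15))
#' select_best_model(prof)$model
#' @export
select_best_model <- function(profile, weights = NULL) {
  fit_recruitment(profile, model = "auto", weights = weights)
}

# Predict from a recruit_fit on new times.
#' @export
predict.recruit_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s else {
    if (is.data.frame(newdata)) newdata$time_s else as.numeric(newdata)
  }
  model_curve(object$model, object$par, t)
}
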