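# Preprocessing of per-centriole intensity tracks into per-embryo profiles.

#' Preprocess centriole tracks into per-embryo recruitment profiles
#'
#' Turns raw per-centriole intensity tracks into per-embryo mean +/- s.d.
#' time courses over the S-phase window, the representation that all model
#' fitting works on. Steps, per embryo:
#'
#' 1. Rows with non-finite intensity are dropped (count recorded).
#' 2. Time is shifted so centrosome separation (CS) is 0 and only the S-phase
#'    window `[CS, NEB]` is kept (mitotic frames are excluded).
#' 3. Background subtraction: a supplied constant, or by default the 5th
#'    percentile of the embryo's intensities.
#' 4. Photobleaching correction: if a whole-field reference series is
#'    supplied, an exponential `exp(-t/tau)` is fitted to it (log-linear
#'    least squares) and intensities are divided by it; otherwise identity.
#' 5. Aggregation across centrioles per time point to mean, s.d. and n.
#' 6. Optional per-embryo scaling so the cycle maximum of the mean is 1.
#'
#' @param tracks Data frame with columns `embryo_id`, `centriole_id`,
#'   `time_s`, `intensity`.
#' @param landmarks Data frame with columns `embryo_id`, `cs_s`, `neb_s`
#'   (one row per embryo; `cs_s < neb_s`).
#' @param background `NULL` (estimate as the 5th percentile per embryo) or a
#'   single constant background value (a.u.).
#' @param bleach_ref Optional whole-field reference series: data frame with
#'   `time_s` and `intensity`, on the same time base as `tracks`.
#' @param scale_max1 If `TRUE`, scale each embryo's mean profile (and s.d.)
#'   so its maximum mean intensity is exactly 1.
#' @return A tibble (class `embryo_profiles`) with columns `embryo_id`,
#'   `time_s` (s from CS), `mean`, `sd`, `n`. Attributes: `landmarks`
#'   (with `sphase_length`), `preprocessing` (background values, bleach tau,
#'   scale factors, dropped-row count).
#' @examples
#' coh <- sim_embryo_cohort(cohort_spec(n_embryos = 2), seed = 1)
#' prof <- preprocess_tracks(coh$tracks, coh$landmarks, scale_max1 = TRUE)
#' head(prof)
#' @export
preprocess_tracks <- function(tracks, landmarks, background = NULL,
                              bleach_ref = NULL, scale_max1 = FALSE) {
  check_columns(tracks, c("embryo_id", "centriole_id", "time_s", "intensity"),
                "tracks")
  check_columns(landmarks, c("embryo_id", "cs_s", "neb_s"), "landmarks")
  if (any(landmarks$cs_s >= landmarks$neb_s)) {
    abort("landmarks must satisfy cs_s < neb_s for every embryo.")
  }
  bad <- !is.finite(tracks$intensity)
  dropped <- sum(bad)
  tracks <- tracks[!bad, , drop = FALSE]

  bleach_tau <- NULL
  if (!is.null(bleach_ref)) {
    check_columns(bleach_ref, c("time_s", "intensity"), "bleach_ref")
    pos <- bleach_ref$intensity > 0
    if (sum(pos) < 3) abort("`bleach_ref` needs >= 3 positive intensities.")
    sl <- coef(lm(log(bleach_ref$intensity[pos]) ~ bleach_ref$time_s[pos]))[2]
    bleach_tau <- if (sl < 0) -1 / sl else Inf
  }

  out <- dplyr::left_join(tracks, landmarks, by = "embryo_id")
  if (any(is.na(out$cs_s))) {
    abort("every embryo in `tracks` needs a row in `landmarks`.")
  }
  out <- dplyr::filter(out, .data$time_s >= .data$cs_s,
                       .data$time_s <= .data$neb_s)
  if (nrow(out) == 0) abort("no track points inside the [CS, NEB] window.")

  bg_tbl <- out |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(
      background = if (is.null(background)) {
        quantile(.data$intensity, 0.05, names = FALSE)
      } else background,
      .groups = "drop")

  out <- out |>
    dplyr::left_join(bg_tbl, by = "embryo_id") |>
    dplyr::mutate(intensity = .data$intensity - .data$background)
  if (!is.null(bleach_tau) && is.finite(bleach_tau)) {
    out <- dplyr::mutate(out,
      intensity = .data$intensity / exp(-.data$time_s / bleach_tau))
  }

  prof <- out |>
    dplyr::mutate(time_s = .data$time_s - .data$cs_s) |>
    dplyr::group_by(.data$embryo_id, .data$time_s) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     sd = ifelse(dplyr::n() > 1, sd(.data$intensity), 0),
                     n = dplyr::n(), .groups = "drop")

  scale_tbl <- prof |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(scale = max(.data$mean), .groups = "drop")
  if (scale_max1) {
    if (any(scale_tbl$scale <= 0)) {
      abort("cannot scale to 1: an embryo's maximum mean intensity is <= 0.")
    }
    prof <- prof |>
      dplyr::left_join(scale_tbl, by = "embryo_id") |>
      dplyr::mutate(mean = .data$mean / .data$scale,
                    sd = .data$sd / .data$scale) |>
      dplyr::select(-"scale")
  }

  lmk <- dplyr::mutate(tibble::as_tibble(landmarks),
                       sphase_length = .data$neb_s - .data$cs_s)
  structure(
    tibble::as_tibble(prof),
    landmarks = lmk,
    preprocessing = list(
      background = bg_tbl,
      bleach_tau = bleach_tau,
      scaled = scale_max1,
      scale = if (scale_max1) scale_tbl else NULL,
      dropped_rows = dropped),
    class = c("embryo_profiles", class(tibble::tibble()))
  )
}

#' Extract one embryo's profile
#'
#' @param profiles Output of [preprocess_tracks()].
#' @param embryo Embryo id.
#' @return Tibble with `time_s`, `mean`, `sd`, `n` for that embryo.
#' @export
embryo_profile <- function(profiles, embryo) {
  p <- dplyr::filter(profiles, .data$embryo_id == embryo)
  if (nrow(p) == 0) abort(sprintf("no profile for embryo '%s'.", embryo))
  tibble::as_tibble(p)
}
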