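# Peak counting spectroscopy: background threshold calibration from control
# traces, supra-threshold peak counting, and the ROUT robust outlier screen.

# Coerce the accepted trace representations to a list of count vectors.
as_trace_list <- function(traces) {
  if (inherits(traces, "pecos_traces")) return(traces$counts)
  if (is.numeric(traces)) return(list(traces))
  if (is.list(traces) && all(vapply(traces, is.numeric, logical(1)))) {
    return(traces)
  }
  abort("`traces` must be a pecos_traces object, a numeric vector, or a list of numeric vectors.")
}

#' Calibrate the PeCoS background threshold from control traces
#'
#' Pools the photon counts of all control bins and sets the background
#' threshold to Mean + 7 x s.d. A calibration is valid when the controls
#' average fewer than five counted peaks per 180 s recording at that
#' threshold.
#'
#' @param controls Control traces: a `pecos_traces` object (see
#'   [sim_pecos_traces()]), a list of count vectors, or a single vector.
#' @return A `pecos_threshold`: `mean`, `sd` (pooled over all control bins),
#'   `threshold = mean + 7*sd`, `control_mean_peaks` (average
#'   [count_peaks()] over the controls at that threshold) and `valid`
#'   (`control_mean_peaks < 5`). Constant controls (sd = 0) give
#'   `threshold = mean` with a degenerate-control warning.
#' @examples
#' compute_threshold(list(c(100, 101, 99, 100), c(100, 100, 98, 102)))
#' @export
compute_threshold <- function(controls) {
  traces <- as_trace_list(controls)
  if (length(traces) < 1) abort("need >= 1 control trace.")
  pooled <- unlist(traces, use.names = FALSE)
  m <- mean(pooled)
  s <- sd(pooled)
  if (is.na(s)) s <- 0
  if (s == 0) {
    warn("degenerate controls: pooled s.d. is 0, threshold equals the mean.")
  }
  thr <- m + 7 * s
  mean_peaks <- mean(vapply(traces, count_peaks, numeric(1), threshold = thr))
  structure(
    list(mean = m, sd = s, threshold = thr,
         control_mean_peaks = mean_peaks,
         valid = mean_peaks < 5,
         n_controls = length(traces)),
    class = "pecos_threshold"
  )
}

#' @export
print.pecos_threshold <- function(x, ...) {
  cat(sprintf(
    "<pecos_threshold> mean = %.2f, sd = %.2f, threshold = %.2f counts\n",
    x$mean, x$sd, x$threshold))
  cat(sprintf("  control peaks/trace = %.2f (valid: %s, requires < 5)\n",
              x$control_mean_peaks, x$valid))
  invisible(x)
}

#' Count supra-threshold peaks in a photon trace
#'
#' A peak is one maximal contiguous run of bins whose counts exceed the
#' threshold (runs separated by at least one sub-threshold bin are distinct
#' peaks).
#'
#' @param counts Numeric vector of per-bin photon counts.
#' @param threshold Threshold (counts); bins with `counts > threshold` are
#'   supra-threshold.
#' @return Integer peak count.
#' @examples
#' count_peaks(c(0, 9, 9, 0, 9, 0), threshold = 5) # 2 runs
#' @export
count_peaks <- function(counts, threshold) {
  if (!is.numeric(counts)) abort("`counts` must be numeric.")
  check_number(threshold, "threshold")
  if (length(counts) == 0) return(0L)
  r <- rle(counts > threshold)
  sum(r$values)
}

#' Count peaks in every trace of a set
#'
#' @param traces A `pecos_traces` object or list of count vectors.
#' @param threshold Threshold (counts), e.g. from [compute_threshold()].
#' @return Tibble with `trace_id` and `n_peaks`.
#' @export
count_peaks_all <- function(traces, threshold) {
  lst <- as_trace_list(traces)
  tibble::tibble(
    trace_id = seq_along(lst),
    n_peaks = vapply(lst, count_peaks, numeric(1), threshold = threshold)
  )
}

#' ROUT robust outlier screen (one-sample)
#'
#' Robust outlier detection controlling a false discovery rate Q among the
#' removed points, applied to a single sample of measurements. The robust
#' centre is the median; the robust scale (RSDR) is the 68.27th percentile of
#' the absolute residuals scaled by `sqrt(n/(n-1))`; each point gets a
#' two-sided p-value from the t distribution (df = n - 1) of
#' `|residual| / RSDR`; outliers are declared by a step-down FDR sweep at
#' rate `Q` from the most extreme residual inward, stopping at the first
#' non-significant point.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param Q Target false discovery rate among removed points (default 0.01,
#'   i.e. Q = 1%).
#' @return A list: `kept` and `outliers` (numeric vectors), `detail` (tibble
#'   with `value`, `residual`, `p`, `outlier` in input order), and `Q`.
#' @examples
#' rout_filter(c(10.0, 10.1, 9.9, 10.05, 9.95, 50.0))$outliers
#' @export
rout_filter <- function(values, Q = 0.01) {
  if (!is.numeric(values)) abort("`values` must be numeric.")
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) abort("ROUT needs at least 3 finite values.")
  check_number(Q, "Q", lower = 0, upper = 1, strict_lower = TRUE)
  resid <- values - median(values)
  ar <- abs(resid)
  rsdr <- quantile(ar, 0.6827, names = FALSE) * sqrt(n / (n - 1))
  outlier <- rep(FALSE, n)
  if (rsdr == 0) {
    # degenerate scale: any point off the median is unambiguously an outlier
    outlier <- ar > 0
    p <- ifelse(ar > 0, 0, 1)
  } else {
    p <- 2 * pt(ar / rsdr, df = n - 1, lower.tail = FALSE)
    ord <- order(ar, decreasing = TRUE)
    for (i in seq_len(n)) {
      if (p[ord[i]] < Q * i / n) outlier[ord[i]] <- TRUE else break
    }
  }
  list(
    kept = values[!outlier],
    outliers = values[outlier],
    detail = tibble::tibble(value = values, residual = resid, p = p,
                            outlier = outlier),
    Q = Q
  )
}

#' Summarize PeCoS peak counts for a sample group
#'
#' Counts peaks per trace at a calibrated threshold and reports the group
#' mean +/- s.d. after ROUT screening of the per-trace counts.
#'
#' @param traces Sample traces (`pecos_traces` or list of count vectors).
#' @param threshold A `pecos_threshold` or a numeric threshold.
#' @param Q ROUT false discovery rate (default 0.01).
#' @return A list: `counts` (per-trace tibble with `outlier` flag),
#'   `mean`, `sd`, `n_kept`, `n_outliers`, `threshold`.
#' @export
pecos_summary <- function(traces, threshold, Q = 0.01) {
  thr <- if (inherits(threshold, "pecos_threshold")) {
    threshold$threshold
  } else {
    check_number(threshold, "threshold")
  }
  counts <- count_peaks_all(traces, thr)
  scr <- rout_filter(counts$n_peaks, Q = Q)
  counts$outlier <- scr$detail$outlier
  list(counts = counts, mean = mean(scr$kept),
       sd = if (length(scr$kept) > 1) sd(scr$kept) else 0,
       n_kept = length(scr$kept), n_outliers = length(scr$outliers),
       threshold = thr)
}
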