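# Synthetic generator for peak counting spectroscopy (PeCoS) photon traces.
#
# A trace is a fixed-duration (default 180 s) sequence of photon counts per
# bin: Poisson background plus fluorophore transit bursts. Burst start times
# follow a Poisson process whose rate is proportional to the cytoplasmic
# concentration; each burst adds Poisson-distributed counts around an
# exponentially decaying envelope. The true number of burst events per trace
# is stored so counting performance can be scored.

#' Specify synthetic PeCoS traces
#'
#' @param duration Recording length (s); 180 s as in the measurements.
#' @param bin_width Bin width (s). The acquisition binning is configurable;
#'   the default is 1 ms, a typical photon-counting binning.
#' @param background_rate Poisson mean of the background (counts/bin).
#' @param transit_rate Burst (molecule transit) rate (events/s), proportional
#'   to concentration; 0 gives pure background.
#' @param burst_amplitude Initial burst intensity (counts/bin above
#'   background).
#' @param burst_tau Exponential decay time (s) of the burst envelope.
#' @return A `pecos_spec` list.
#' @export
pecos_spec <- function(duration = 180, bin_width = 0.001,
                       background_rate = 50, transit_rate = 0.2,
                       burst_amplitude = 200, burst_tau = 0.005) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  n_bins <- duration / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("`duration` must be a whole number of bins.")
  }
  check_number(background_rate, "background_rate", lower = 0)
  check_number(transit_rate, "transit_rate", lower = 0)
  check_number(burst_amplitude, "burst_amplitude", lower = 0)
  check_number(burst_tau, "burst_tau", lower = 0, strict_lower = TRUE)
  structure(
    list(duration = duration, bin_width = bin_width,
         background_rate = background_rate, transit_rate = transit_rate,
         burst_amplitude = burst_amplitude, burst_tau = burst_tau,
         n_bins = as.integer(round(n_bins))),
    class = "pecos_spec"
  )
}

sim_one_trace <- function(spec) {
  counts <- if (spec$background_rate > 0) {
    rpois(spec$n_bins, spec$background_rate)
  } else {
    integer(spec$n_bins)
  }
  n_events <- rpois(1, spec$transit_rate * spec$duration)
  if (n_events > 0) {
    starts <- runif(n_events, 0, spec$duration)
    span <- ceiling(10 * spec$burst_tau / spec$bin_width) # envelope support
    centers <- (seq_len(spec$n_bins) - 0.5) * spec$bin_width
    for (t0 in starts) {
      j0 <- max(1L, ceiling(t0 / spec$bin_width))
      j1 <- min(spec$n_bins, j0 + span)
      idx <- j0:j1
      lam <- spec$burst_amplitude *
        exp(-pmax(centers[idx] - t0, 0) / spec$burst_tau)
      counts[idx] <- counts[idx] + rpois(length(idx), lam)
    }
  }
  list(counts = counts, n_events = n_events)
}

#' Simulate PeCoS photon traces
#'
#' @param spec A [pecos_spec()].
#' @param n Number of traces.
#' @param seed Integer seed; each trace gets a derived child seed.
#' @return A `pecos_traces` object: list with `counts` (list of integer
#'   vectors, one per trace), `bin_width`, `duration`, and `truth` (tibble
#'   `trace_id`, `n_events` with the true burst-event count per trace).
#' @examples
#' tr <- sim_pecos_traces(pecos_spec(duration = 1, transit_rate = 5), 2, seed = 1)
#' tr$truth
#' @export
sim_pecos_traces <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "pecos_spec"))
  n <- check_count(n, "n")
  sims <- lapply(seq_len(n), function(i) {
    with_seed(child_seed(seed, i), sim_one_trace(spec))
  })
  structure(
    list(counts = lapply(sims, `[[`, "counts"),
         bin_width = spec$bin_width,
         duration = spec$duration,
         truth = tibble::tibble(
           trace_id = seq_len(n),
           n_events = vapply(sims, `[[`, numeric(1), "n_events")),
         spec = spec, seed = seed),
    class = "pecos_traces"
  )
}

#' @export
print.pecos_traces <- function(x, ...) {
  cat(sprintf(
    "<pecos_traces> %d traces, %g s at %g s bins (%d bins each)\n",
    length(x$counts), x$duration, x$bin_width, length(x$counts[[1]])))
  invisible(x)
}
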