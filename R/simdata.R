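#' Simulation condition for the synthetic benchmark
#'
#' Bundles the parameters of one simulated condition: cycle count, period,
#' sampling interval, Gaussian noise level, amplitude decay, dataset sizes
#' and seed.  The emulated conditions follow typical omics time-course
#' designs: one or two 24-h cycles sampled every 1-8 h, unit-amplitude sine
#' signals with additive Gaussian noise of SD up to ~0.6 (relative to
#' amplitude), optionally decaying so the second-cycle peak is one third of
#' the first, and non-oscillating series of i.i.d. uniform random values.
#'
#' @param n_cycles 1 or 2 full periods.
#' @param period Period in hours (default 24).
#' @param interval Sampling interval in hours; `n_cycles * period / interval`
#'   must be an integer >= 4.
#' @param noise_sd Standard deviation of additive Gaussian noise on the unit
#'   sine (>= 0).
#' @param decaying Attenuate the oscillation so the second-cycle peak equals
#'   `decay_ratio` times the first (two-cycle designs only).
#' @param decay_ratio Peak ratio between consecutive cycles (default 1/3).
#' @param n_oscillating,n_nonoscillating Numbers of labelled positive and
#'   negative series.
#' @param seed RNG seed; the dataset is fully determined by the spec.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_cycles = 2, period = 24, interval = 4, noise_sd = 0,
                     decaying = FALSE, decay_ratio = 1 / 3,
                     n_oscillating = 100, n_nonoscillating = 100, seed = 1) {
    if (!n_cycles %in% c(1, 2)) stop("'n_cycles' must be 1 or 2")
    if (period <= 0 || interval <= 0)
        stop("'period' and 'interval' must be positive")
    npts <- n_cycles * period / interval
    if (abs(npts - round(npts)) > 1e-9)
        stop("n_cycles * period / interval must be an integer number of points")
    if (round(npts) < 4) stop("fewer than 4 points per series")
    if (noise_sd < 0) stop("'noise_sd' must be >= 0")
    if (decaying && n_cycles != 2)
        stop("decaying series require a two-cycle design")
    if (decay_ratio <= 0 || decay_ratio > 1)
        stop("'decay_ratio' must be in (0, 1]")
    if (n_oscillating < 0 || n_nonoscillating < 0) stop("negative dataset size")
    structure(list(n_cycles = as.integer(n_cycles), period = period,
                   interval = interval, noise_sd = noise_sd,
                   decaying = isTRUE(decaying), decay_ratio = decay_ratio,
                   n_oscillating = as.integer(n_oscillating),
                   n_nonoscillating = as.integer(n_nonoscillating),
                   seed = as.integer(seed)),
              class = "sim_spec")
}

#' Sampling-time grid of a simulation condition
#'
#' Half-open convention: times run from 0 in steps of `interval` up to but
#' excluding `n_cycles * period` (the endpoint coincides with t = 0 of the
#' next cycle), so a 4-h interval over two 24-h cycles yields 12 points
#' 0..44 h.
#'
#' @param spec A [sim_spec()].
#' @return Numeric vector of sampling times in hours.
#' @export
make_grid <- function(spec) {
    stopifnot(inherits(spec, "sim_spec"))
    seq(0, spec$n_cycles * spec$period - spec$interval, by = spec$interval)
}

#' One oscillating series on a time grid
#'
#' Unit-amplitude sine \eqn{\sin(2\pi t / T)} around mesor 0 with additive
#' i.i.d. Gaussian noise of SD `noise_sd` per point.  If `decaying`, the
#' noisy series is multiplied by the exponential envelope
#' \eqn{e^{-\lambda t}} with \eqn{\lambda = -\ln(r) / T}: amplitude decay
#' attenuates the measured trace as a whole, so the realized peak value one
#' period apart is exactly `r = decay_ratio` times the previous cycle's
#' (second-cycle peak a third of the first at the default).  Uses the
#' current RNG state.
#'
#' @param times Sampling times in hours.
#' @param period Period in hours.
#' @inheritParams sim_spec
#' @param decay_mode `"exponential"` (default) for the continuous envelope;
#'   `"piecewise"` scales each whole cycle by `decay_ratio^cycle` instead.
#' @return Numeric vector of simulated values.
#' @export
oscillating_series <- function(times, period = 24, noise_sd = 0,
                               decaying = FALSE, decay_ratio = 1 / 3,
                               decay_mode = c("exponential", "piecewise")) {
    decay_mode <- match.arg(decay_mode)
    out <- sin(2 * pi * times / period) +
        rnorm(length(times), mean = 0, sd = noise_sd)
    if (decaying) {
        env <- switch(decay_mode,
                      exponential = exp(log(decay_ratio) * times / period),
                      piecewise = decay_ratio^floor(times / period))
        out <- out * env
    }
    out
}

#' One non-oscillating series on a time grid
#'
#' I.i.d. uniform random values, one per timepoint; MIC's invariance under
#' strictly increasing transforms makes the support immaterial.  Uses the
#' current RNG state.
#'
#' @param times Sampling times in hours.
#' @return Numeric vector of uniform(0, 1) values.
#' @export
nonoscillating_series <- function(times) {
    runif(length(times))
}

#' Labelled synthetic dataset for one condition
#'
#' Generates `n_oscillating` positive series followed by `n_nonoscillating`
#' negative series on the condition's grid, fully determined by the spec's
#' seed (the caller's RNG state is untouched).
#'
#' @param spec A [sim_spec()].
#' @return A `sim_dataset`: list with matrix `x` (rows `osc_*`, `ran_*`),
#'   `times`, logical `labels` (`TRUE` = oscillating) and the `spec`.
#' @export
make_dataset <- function(spec) {
    stopifnot(inherits(spec, "sim_spec"))
    times <- make_grid(spec)
    x <- with_seed(spec$seed, {
        pos <- t(vapply(seq_len(spec$n_oscillating), function(i)
            oscillating_series(times, period = spec$period,
                               noise_sd = spec$noise_sd,
                               decaying = spec$decaying,
                               decay_ratio = spec$decay_ratio),
            numeric(length(times))))
        neg <- t(vapply(seq_len(spec$n_nonoscillating),
                        function(i) nonoscillating_series(times),
                        numeric(length(times))))
        rbind(if (spec$n_oscillating) pos else NULL,
              if (spec$n_nonoscillating) neg else NULL)
    })
    labels <- rep(c(TRUE, FALSE),
                  c(spec$n_oscillating, spec$n_nonoscillating))
    rownames(x) <- c(sprintf("osc_%03d", seq_len(spec$n_oscillating)),
                     sprintf("ran_%03d", seq_len(spec$n_nonoscillating)))
    colnames(x) <- times
    structure(list(x = x, times = times, labels = labels, spec = spec),
              class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
    s <- x$spec
    cat(sprintf(
        "simulated dataset: %d oscillating + %d non-oscillating series, %d cycle(s) of %g h sampled every %g h (%d points), noise SD %g%s, seed %d\n",
        s$n_oscillating, s$n_nonoscillating, s$n_cycles, s$period,
        s$interval, length(x$times), s$noise_sd,
        if (s$decaying) sprintf(", decaying (peak ratio %.3g)", s$decay_ratio)
        else "", s$seed))
    invisible(x)
}
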