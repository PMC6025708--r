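#' Reference sine curve on a sampling grid
#'
#' Evaluates the fixed sine template \eqn{\sin(2\pi (t - \phi) / T)} on the
#' sampling times.  The same curve is used for every series of a matrix; each
#' series' MIC is computed against it.  Values are the plain floating-point
#' sine evaluation; the rank-based partition search downstream orders them
#' deterministically, and a noise-free series generated by the same
#' expression is numerically identical to the reference, so it scores
#' MIC = 1.
#'
#' @param times Strictly increasing sampling times in hours, length >= 4.
#' @param period Oscillation period in hours (default 24).
#' @param phase Phase offset in hours (default 0); `phase = period` is
#'   identical to `phase = 0`.
#' @return A `micop_reference`: list with `times`, `values`, `period`,
#'   `phase`.
#' @examples
#' build_reference(c(0, 6, 12, 18))$values  # 0, 1, 0, -1
#' @export
build_reference <- function(times, period = 24, phase = 0) {
    check_times(times)
    if (!is.numeric(period) || length(period) != 1 || period <= 0)
        stop("'period' must be a positive number of hours")
    if (!is.numeric(phase) || length(phase) != 1 || !is.finite(phase))
        stop("'phase' must be a finite number of hours")
    values <- sin(2 * pi * (times - phase) / period)
    if (diff(range(values)) < 1e-9)
        warning("degenerate reference: the sampling grid aliases the sine ",
                "curve to a constant (sampling at multiples of half the ",
                "period)")
    structure(list(times = as.numeric(times), values = values,
                   period = period, phase = phase),
              class = "micop_reference")
}

check_times <- function(times) {
    if (!is.numeric(times) || length(times) < 4)
        stop("'times' must be a numeric vector of at least 4 sampling times")
    if (anyNA(times) || any(!is.finite(times)))
        stop("'times' must be finite")
    if (any(diff(times) <= 0))
        stop("'times' must be strictly increasing")
    invisible(times)
}

#' @export
print.micop_reference <- function(x, ...) {
    cat(sprintf("reference sine: period %g h, phase %g h, %d timepoints (%g..%g h)\n",
                x$period, x$phase, length(x$times), min(x$times),
                max(x$times)))
    invisible(x)
}
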