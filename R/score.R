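#' Score one expression series against the reference curve
#'
#' Pairwise-deletes missing points from the series and the reference, then
#' computes the MIC of the remainder.  A series with fewer than 4 usable
#' points is unscoreable and is reported as such rather than raising.
#'
#' @param values Numeric vector of expression values on the reference's time
#'   grid; `NA` marks missing timepoints.
#' @param ref A [build_reference()] curve.
#' @inheritParams mic
#' @return A `mic_score` with an `n_used` field, or `NULL` when fewer than 4
#'   points are usable.
#' @export
score_series <- function(values, ref, alpha = 0.6, clumps = 15,
                         bound = "product") {
    stopifnot(inherits(ref, "micop_reference"))
    if (length(values) != length(ref$times))
        stop("series length does not match the reference time grid")
    usable <- which(is.finite(values))
    if (length(usable) < 4) return(NULL)
    s <- mic(ref$values[usable], values[usable], alpha = alpha,
             clumps = clumps, bound = bound)
    s$n_used <- length(usable)
    s$usable <- usable
    s
}

null_key <- function(idx, ref, n_draws, seed, alpha, clumps, bound) {
    paste(paste(idx, collapse = ","),
          paste(format(ref$values[idx], digits = 17), collapse = ","),
          n_draws, seed, alpha, clumps, bound, sep = "|")
}

#' Monte-Carlo null distribution of MIC scores
#'
#' Draws `n_draws` non-oscillating series of i.i.d. uniform random values on
#' the (sub)grid and scores each against the reference curve.  The resulting
#' distribution depends only on the usable timepoints and the reference, so
#' it is computed once and reused for every series sharing them.  MIC is
#' invariant under strictly increasing transforms of either variable, so the
#' support of the uniform draw is immaterial.
#'
#' @param ref A [build_reference()] curve.
#' @param n_draws Number of null series (default 1000, giving p-value
#'   resolution 1/1000).
#' @param seed RNG seed; the same seed reproduces the distribution exactly.
#' @param idx Indices of usable timepoints (default: all).
#' @inheritParams mic
#' @return A `micop_null`: list with sorted `mics`, `n_points`, `n_draws`,
#'   `seed`.
#' @export
sample_null <- function(ref, n_draws = 1000, seed = 1, alpha = 0.6,
                        clumps = 15, bound = "product", idx = NULL) {
    stopifnot(inherits(ref, "micop_reference"))
    if (n_draws < 1) stop("'n_draws' must be >= 1")
    if (is.null(idx)) idx <- seq_along(ref$values)
    rv <- ref$values[idx]
    n <- length(idx)
    if (n < 4) stop("fewer than 4 usable timepoints")
    draws <- with_seed(seed, matrix(runif(n_draws * n), nrow = n))
    mics <- vapply(seq_len(n_draws),
                   function(i) cpp_mic(rv, draws[, i], alpha,
                                       as.integer(clumps), FALSE,
                                       bound == "axis")$mic,
                   numeric(1))
    structure(list(mics = sort(mics), n_points = n,
                   n_draws = as.integer(n_draws), seed = as.integer(seed)),
              class = "micop_null")
}

#' @export
print.micop_null <- function(x, ...) {
    cat(sprintf("MIC null: %d draws at n = %d (median %.3f, 95th pct %.3f)\n",
                x$n_draws, x$n_points, stats::median(x$mics),
                stats::quantile(x$mics, 0.95)))
    invisible(x)
}

#' Monte-Carlo p-value of an observed MIC
#'
#' The fraction of null MIC scores strictly exceeding the observed score,
#' \eqn{p = k / n_{draws}}.  With the strict inequality the smallest
#' attainable p-value is exactly 0 and the resolution is
#' \eqn{1/n_{draws}}.
#'
#' @param score A `mic_score` (from [mic()] or [score_series()]) or a bare
#'   MIC value; if a `mic_score`, its sample size must match the null's.
#' @param null A [sample_null()] distribution.
#' @return p-value in \eqn{[0, 1]}.
#' @export
p_value <- function(score, null) {
    stopifnot(inherits(null, "micop_null"))
    if (inherits(score, "mic_score")) {
        n_obs <- if (!is.null(score$n_used)) score$n_used else score$n
        if (n_obs != null$n_points)
            stop("null was sampled at n = ", null$n_points,
                 " but the series has ", n_obs,
                 " usable points; re-sample the null at the matching length")
        score <- score$mic
    }
    if (!is.numeric(score) || length(score) != 1 || is.na(score))
        stop("'score' must be a single MIC value")
    sum(null$mics > score) / null$n_draws
}

#' Score a whole expression matrix and call oscillating molecules
#'
#' Scores every row of a molecules-by-timepoints matrix against one
#' reference sine curve, attaches Monte-Carlo p-values, applies
#' Benjamini-Hochberg correction across all scoreable rows, and calls a
#' molecule oscillating when its adjusted p-value falls below `alpha_level`.
#' Null distributions are sampled once per distinct usable-timepoint pattern
#' and reused.
#'
#' @param x Numeric matrix (or data frame), rows = molecules, columns =
#'   timepoints; `NA` marks missing values.  Row names are molecule ids.
#' @param times Sampling times in hours; taken from numeric column names
#'   when omitted.
#' @param period,phase Reference sine parameters in hours.
#' @param alpha MIC grid-bound exponent (default 0.6).
#' @param clumps MIC search cap (default 15).
#' @param n_draws Null draws per distinct pattern (default 1000).
#' @param seed Seed for the null sampler.
#' @param alpha_level Call threshold on the (adjusted) p-value, default 0.05.
#' @param p_mode `"bh"` (default) calls on the BH-adjusted p-value `q`;
#'   `"raw"` calls on the uncorrected p-value.
#' @param null_mode `"uniform"` (default) draws i.i.d. uniform null series;
#'   `"permutation"` instead permutes each observed series' own values
#'   (`n_draws` permutations per row, seeded per row as `seed` + row index).
#' @param bound MIC shape-admissibility rule, `"product"` (default) or
#'   `"axis"`; see [mic()].
#' @param null_cache Optional environment in which null distributions are
#'   memoised; pass the same environment across calls to share nulls.
#' @return A data frame of class `micop_result` with columns `id`, `n_used`,
#'   `mic`, `p`, `q`, `called`.  Unscoreable rows (fewer than 4 usable
#'   points) carry `NA` and no call.
#' @examples
#' tm <- seq(0, 44, by = 4)
#' mat <- rbind(osc = sin(2 * pi * tm / 24), flat = rep(1, 12))
#' micop_call(mat, tm, n_draws = 50)
#' @export
micop_call <- function(x, times = NULL, period = 24, phase = 0, alpha = 0.6,
                       clumps = 15, n_draws = 1000, seed = 1,
                       alpha_level = 0.05, p_mode = c("bh", "raw"),
                       null_mode = c("uniform", "permutation"),
                       bound = "product", null_cache = NULL) {
    p_mode <- match.arg(p_mode)
    null_mode <- match.arg(null_mode)
    x <- as.matrix(x)
    if (is.null(times)) {
        times <- suppressWarnings(as.numeric(colnames(x)))
        if (anyNA(times))
            stop("'times' not given and column names are not numeric")
    }
    if (length(times) != ncol(x))
        stop("length of 'times' must equal the number of columns")
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(x)))
    if (nrow(x) == 0)
        return(empty_result())
    ref <- build_reference(times, period = period, phase = phase)
    if (is.null(null_cache)) null_cache <- new.env(parent = emptyenv())

    n_used <- integer(nrow(x))
    mics <- rep(NA_real_, nrow(x))
    ps <- rep(NA_real_, nrow(x))
    for (i in seq_len(nrow(x))) {
        s <- score_series(x[i, ], ref, alpha = alpha, clumps = clumps,
                          bound = bound)
        if (is.null(s)) {
            n_used[i] <- sum(is.finite(x[i, ]))
            next
        }
        n_used[i] <- s$n_used
        mics[i] <- s$mic
        if (null_mode == "uniform") {
            key <- null_key(s$usable, ref, n_draws, seed, alpha, clumps,
                            bound)
            nl <- null_cache[[key]]
            if (is.null(nl)) {
                nl <- sample_null(ref, n_draws = n_draws, seed = seed,
                                  alpha = alpha, clumps = clumps,
                                  bound = bound, idx = s$usable)
                null_cache[[key]] <- nl
            }
        } else {
            nl <- permutation_null(x[i, s$usable], ref$values[s$usable],
                                   n_draws, seed + i, alpha, clumps, bound)
        }
        ps[i] <- p_value(s, nl)
    }
    qs <- rep(NA_real_, nrow(x))
    ok <- !is.na(ps)
    qs[ok] <- p.adjust(ps[ok], method = "BH")
    called <- rep(NA, nrow(x))
    called[ok] <- (if (p_mode == "bh") qs[ok] else ps[ok]) < alpha_level
    structure(data.frame(id = ids, n_used = n_used, mic = mics, p = ps,
                         q = qs, called = called, stringsAsFactors = FALSE),
              class = c("micop_result", "data.frame"))
}

empty_result <- function() {
    structure(data.frame(id = character(), n_used = integer(),
                         mic = numeric(), p = numeric(), q = numeric(),
                         called = logical(), stringsAsFactors = FALSE),
              class = c("micop_result", "data.frame"))
}

permutation_null <- function(values, ref_values, n_draws, seed, alpha,
                             clumps, bound = "product") {
    n <- length(values)
    perms <- with_seed(seed, replicate(n_draws, sample(values)))
    mics <- vapply(seq_len(n_draws),
                   function(i) cpp_mic(ref_values, perms[, i], alpha,
                                       as.integer(clumps), FALSE,
                                       bound == "axis")$mic,
                   numeric(1))
    structure(list(mics = sort(mics), n_points = n,
                   n_draws = as.integer(n_draws), seed = as.integer(seed)),
              class = "micop_null")
}
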