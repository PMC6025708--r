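#' Matthews correlation coefficient
#'
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' the balanced binary-classification quality in \eqn{[-1, 1]}.  When any of
#' the four parenthesised sums is zero the denominator vanishes and 0 is
#' returned (the standard convention).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.  `tp` may instead be a
#'   named vector or list carrying all four.
#' @return MCC in \eqn{[-1, 1]}.
#' @examples
#' mcc(100, 0, 100, 0)  # perfect: 1
#' mcc(50, 50, 50, 50)  # random: 0
#' @export
mcc <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
    if (is.null(fp) && (is.list(tp) || !is.null(names(tp)))) {
        cc <- tp
        tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
    }
    cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    if (any(is.na(cnt)) || any(cnt < 0))
        stop("confusion counts must be non-negative")
    s <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (any(s == 0)) return(0)
    # products can overflow integer range; work in doubles
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(prod(as.numeric(s)))
}

#' Confusion counts of oscillation calls against known labels
#'
#' Rows without a call (unscoreable series) are excluded, so the four counts
#' sum to the number of scoreable rows.
#'
#' @param called Logical calls (`NA` = no call).
#' @param labels Logical ground truth (`TRUE` = oscillating).
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(called, labels) {
    if (length(called) != length(labels))
        stop("'called' and 'labels' must have the same length")
    ok <- !is.na(called)
    called <- called[ok]
    labels <- labels[ok]
    c(tp = sum(called & labels), fp = sum(called & !labels),
      tn = sum(!called & !labels), fn = sum(!called & labels))
}

#' Run one benchmark cell
#'
#' Generates the condition's labelled dataset, scores it with the full MICOP
#' pipeline (one reference sine, cached Monte-Carlo null, BH calls), and
#' tallies confusion counts and MCC against the known labels.  The null
#' sampler is seeded at `spec$seed + 500000` so its random stream is disjoint
#' from the data generator's.
#'
#' @param spec A [sim_spec()]; its `seed` drives the data.
#' @inheritParams micop_call
#' @return A `benchmark_cell`: list with the `spec`, confusion `counts`,
#'   `mcc` and the per-series `result` table.
#' @export
run_cell <- function(spec, alpha = 0.6, clumps = 15, n_draws = 1000,
                     alpha_level = 0.05, p_mode = "bh", null_cache = NULL) {
    stopifnot(inherits(spec, "sim_spec"))
    ds <- make_dataset(spec)
    res <- micop_call(ds$x, ds$times, period = spec$period, alpha = alpha,
                      clumps = clumps, n_draws = n_draws,
                      seed = spec$seed + 500000L, alpha_level = alpha_level,
                      p_mode = p_mode, null_cache = null_cache)
    counts <- confusion_counts(res$called, ds$labels)
    structure(list(spec = spec, counts = counts, mcc = mcc(counts),
                   result = res),
              class = "benchmark_cell")
}

#' @export
print.benchmark_cell <- function(x, ...) {
    cat(sprintf("benchmark cell (interval %g h, noise %g%s, seed %d): MCC = %.3f  [tp %d fp %d tn %d fn %d]\n",
                x$spec$interval, x$spec$noise_sd,
                if (x$spec$decaying) ", decaying" else "", x$spec$seed,
                x$mcc, x$counts["tp"], x$counts["fp"], x$counts["tn"],
                x$counts["fn"]))
    invisible(x)
}

#' Sweep benchmark conditions
#'
#' Runs [run_cell()] over the cross of sampling intervals and noise levels,
#' repeated over seeds, sharing one null cache across all cells (the null
#' depends only on the usable grid and the reference, so cells with the same
#' grid and seed reuse it).
#'
#' @param intervals Sampling intervals in hours.
#' @param noise_sds Gaussian noise SDs.
#' @param seeds Seeds, one dataset per seed per condition (default 1:3).
#' @inheritParams sim_spec
#' @inheritParams micop_call
#' @return A `benchmark_result` data frame in long format: one row per
#'   condition x seed with columns `n_cycles`, `interval`, `noise_sd`,
#'   `decaying`, `seed`, `tp`, `fp`, `tn`, `fn`, `mcc`.
#' @seealso [summarize_benchmark()] for per-condition mean and SD.
#' @export
benchmark_sweep <- function(intervals, noise_sds, n_cycles = 2,
                            decaying = FALSE, period = 24,
                            n_oscillating = 100, n_nonoscillating = 100,
                            seeds = 1:3, alpha = 0.6, clumps = 15,
                            n_draws = 1000, alpha_level = 0.05,
                            p_mode = "bh", null_cache = NULL) {
    if (is.null(null_cache)) null_cache <- new.env(parent = emptyenv())
    grid <- expand.grid(interval = intervals, noise_sd = noise_sds,
                        seed = seeds, KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        spec <- sim_spec(n_cycles = n_cycles, period = period,
                         interval = grid$interval[i],
                         noise_sd = grid$noise_sd[i], decaying = decaying,
                         n_oscillating = n_oscillating,
                         n_nonoscillating = n_nonoscillating,
                         seed = grid$seed[i])
        cell <- run_cell(spec, alpha = alpha, clumps = clumps,
                         n_draws = n_draws, alpha_level = alpha_level,
                         p_mode = p_mode, null_cache = null_cache)
        data.frame(n_cycles = n_cycles, interval = spec$interval,
                   noise_sd = spec$noise_sd, decaying = decaying,
                   seed = spec$seed, tp = cell$counts[["tp"]],
                   fp = cell$counts[["fp"]], tn = cell$counts[["tn"]],
                   fn = cell$counts[["fn"]], mcc = cell$mcc)
    })
    structure(do.call(rbind, rows),
              class = c("benchmark_result", "data.frame"))
}

#' Summarise a benchmark sweep across seeds
#'
#' @param cells A [benchmark_sweep()] result.
#' @return Data frame with one row per condition: `mean_mcc`, `sd_mcc`,
#'   `n_seeds`.
#' @export
summarize_benchmark <- function(cells) {
    agg <- stats::aggregate(
        mcc ~ n_cycles + interval + noise_sd + decaying, data = cells,
        FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
    out <- agg[setdiff(names(agg), "mcc")]
    out$mean_mcc <- agg$mcc[, "mean"]
    out$sd_mcc <- agg$mcc[, "sd"]
    out$n_seeds <- as.integer(agg$mcc[, "n"])
    out[order(out$n_cycles, out$interval, out$noise_sd), , drop = FALSE]
}
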