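#' Mutual information of a grid partition
#'
#' Computes the mutual information, in bits, of the empirical joint
#' distribution held by a 2-D contingency grid: \eqn{I(X;Y) = \sum p(x,y)
#' \log_2 [p(x,y) / (p(x)p(y))]} over cells with positive count, where the
#' marginals are the row and column sums.
#'
#' @param counts Non-negative integer matrix of cell counts (rows partition
#'   one variable, columns the other).
#' @return Mutual information in bits, a non-negative scalar bounded by
#'   \eqn{\log_2} of the smaller grid dimension.
#' @examples
#' mutual_information(matrix(c(5, 0, 0, 5), 2))  # perfect association: 1 bit
#' mutual_information(matrix(25, 2, 2))          # independence: 0 bits
#' @export
mutual_information <- function(counts) {
    counts <- as.matrix(counts)
    if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts)))
        stop("'counts' must be a matrix of finite non-negative counts")
    n <- sum(counts)
    if (n == 0) stop("empty grid: total count is zero")
    p <- counts / n
    px <- rowSums(p)
    py <- colSums(p)
    e <- outer(px, py)
    pos <- p > 0
    sum(p[pos] * log2(p[pos] / e[pos]))
}

#' Normalized mutual information of a grid partition
#'
#' Mutual information divided by \eqn{\log_2} of the smaller number of bins,
#' mapping the statistic to \eqn{[0, 1]} so grids of different shapes are
#' comparable.
#'
#' @inheritParams mutual_information
#' @return Normalized mutual information in \eqn{[0, 1]}.
#' @export
normalized_mi <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2 || ncol(counts) < 2)
        stop("grid must have at least 2 bins on each axis (normalizer log2(min) would be 0)")
    mutual_information(counts) / log2(min(dim(counts)))
}

check_pair <- function(x, y) {
    if (!is.numeric(x) || !is.numeric(y)) stop("'x' and 'y' must be numeric")
    if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
    if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
        stop("missing or non-finite values: pairwise-delete before computing MIC")
    if (length(x) < 4) stop("need at least 4 paired observations")
    invisible(length(x))
}

new_mic_score <- function(mic, best_cx, best_cy, n, degenerate,
                          char_matrix = NULL) {
    structure(list(mic = mic, best_cx = best_cx, best_cy = best_cy, n = n,
                   degenerate = degenerate, char_matrix = char_matrix),
              class = "mic_score")
}

#' Maximal information coefficient of two paired vectors
#'
#' The MIC is the maximum, over all admissible grid shapes \eqn{(c_x, c_y)}
#' with \eqn{c_x, c_y \ge 2}, of the grid's mutual information normalized by
#' \eqn{\log_2 \min(c_x, c_y)}, each shape maximized over cut placements.
#' The admissible shapes are bounded by \eqn{B(n) = n^\alpha}: the default
#' `bound = "product"` restricts the product (\eqn{c_x c_y < n^\alpha},
#' strict), as the MINE reference implementations do; `bound = "axis"`
#' instead bounds each axis' bin count (\eqn{c_x < n^\alpha} and
#' \eqn{c_y < n^\alpha}), a laxer rule that admits much finer grids on short
#' series and lets the null distribution saturate — offered for comparison
#' only.
#'
#' The placement search uses the standard approximation: one axis is
#' equipartitioned by rank, the other axis is optimized exactly by dynamic
#' programming over clump boundaries, and both axis orientations are
#' searched.  The number of cut candidates on the optimized axis is capped
#' at `clumps` times the number of bins.  Points are ranked with ties broken
#' by original index, so tied values have a deterministic order and grid
#' lines may fall between them; all partition logic is rank-based, making
#' the statistic exactly invariant under strictly increasing transforms of
#' either variable.
#'
#' @param x,y Numeric vectors of equal length \eqn{n \ge 4}, no missing
#'   values.
#' @param alpha Exponent of the grid-size bound \eqn{B(n) = n^\alpha};
#'   default 0.6.
#' @param clumps Superclump multiplier capping the dynamic-program search;
#'   default 15.  Values of at least \eqn{n} leave the cut search
#'   unrestricted.
#' @param bound Shape-admissibility rule, `"product"` (default) or
#'   `"axis"`; see Description.
#' @param keep_matrix Retain the characteristic matrix of per-shape
#'   normalized MI values.
#' @return A `mic_score`: list with `mic` in \eqn{[0,1]}, the best grid shape
#'   `best_cx`, `best_cy`, the sample size `n`, a `degenerate` flag (set for
#'   constant input, which scores 0), and optionally `char_matrix`.
#' @details If no grid shape is admissible (\eqn{n^\alpha \le 2} under the
#'   axis bound, \eqn{n^\alpha \le 4} under the product bound) the series is
#'   too short to score at this `alpha` and an error is raised rather than
#'   silently returning 0.
#' @examples
#' x <- seq_len(12)
#' mic(x, x^3)$mic  # 1: strictly monotone, noiseless
#' @seealso [brute_force_mic()] for the exhaustive small-sample oracle.
#' @export
mic <- function(x, y, alpha = 0.6, clumps = 15,
                bound = c("product", "axis"), keep_matrix = FALSE) {
    n <- check_pair(x, y)
    bound <- match.arg(bound)
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must be in (0, 1)")
    if (clumps < 1) stop("'clumps' must be >= 1")
    res <- cpp_mic(as.numeric(x), as.numeric(y), alpha, as.integer(clumps),
                   keep_matrix, bound == "axis")
    if (isTRUE(res$no_grid))
        stop("no admissible grid: n^alpha = ", format(n^alpha),
             " admits no shape with at least 2 bins per axis; the series ",
             "is too short to score at alpha = ", alpha)
    cm <- NULL
    if (keep_matrix && !isTRUE(res$degenerate) && length(res$char_matrix)) {
        cm <- res$char_matrix
        dimnames(cm) <- list(cx = seq_len(nrow(cm)) + 1L,
                             cy = seq_len(ncol(cm)) + 1L)
    }
    new_mic_score(res$mic, res$best_cx, res$best_cy, n,
                  isTRUE(res$degenerate), cm)
}

#' @export
print.mic_score <- function(x, ...) {
    cat(sprintf("MIC = %.4f  (n = %d, best grid %s x %s%s)\n", x$mic, x$n,
                x$best_cx, x$best_cy,
                if (x$degenerate) ", degenerate input" else ""))
    invisible(x)
}

#' Exhaustive maximal information coefficient (testing oracle)
#'
#' Enumerates every admissible grid — all admissible shapes and all
#' placements of cut positions between consecutive rank positions on both
#' axes (the same rank order, ties broken by original index, that [mic()]
#' uses) — and returns the true maximum of normalized mutual information.
#' Combinatorial, so restricted to \eqn{n \le 12}; it serves as an
#' upper-bound oracle for [mic()], whose equipartition-based search can
#' never exceed it.
#'
#' @inheritParams mic
#' @return A `mic_score` (without characteristic matrix).
#' @export
brute_force_mic <- function(x, y, alpha = 0.6, bound = c("product", "axis")) {
    n <- check_pair(x, y)
    bound <- match.arg(bound)
    if (n > 12) stop("exhaustive search is limited to n <= 12")
    B <- n^alpha
    admissible <- function(cx, cy) {
        if (bound == "axis") cx < B - 1e-9 && cy < B - 1e-9
        else cx * cy < B - 1e-9
    }
    if (!admissible(2, 2))
        stop("no admissible grid: n^alpha = ", format(B),
             " admits no shape with at least 2 bins per axis")
    if (length(unique(x)) < 2 || length(unique(y)) < 2)
        return(new_mic_score(0, NA_integer_, NA_integer_, n, TRUE))
    # rank position (ties stable by original index) of each point, per axis
    xpos <- integer(n)
    xpos[order(x)] <- seq_len(n)
    ypos <- integer(n)
    ypos[order(y)] <- seq_len(n)
    maxax <- 2L
    while (admissible(maxax + 1L, 2L)) maxax <- maxax + 1L
    best <- 0
    bcx <- 2L
    bcy <- 2L
    for (cx in 2:maxax) {
        for (cy in 2:maxax) {
            if (!admissible(cx, cy)) next
            xsets <- combn(n - 1L, cx - 1L, simplify = FALSE)
            ysets <- combn(n - 1L, cy - 1L, simplify = FALSE)
            norm <- log2(min(cx, cy))
            for (xs in xsets) {
                xi <- findInterval(xpos, xs + 0.5) + 1L
                for (ys in ysets) {
                    yi <- findInterval(ypos, ys + 0.5) + 1L
                    cnt <- matrix(tabulate((yi - 1L) * cx + xi, cx * cy),
                                  cx, cy)
                    v <- mutual_information(cnt) / norm
                    if (v > best + 1e-12) {
                        best <- v
                        bcx <- cx
                        bcy <- cy
                    }
                }
            }
        }
    }
    new_mic_score(min(best, 1), bcx, bcy, n, FALSE)
}
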