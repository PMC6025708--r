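test_that("mutual information matches the cell-sum formula", {
    # perfect 2x2 association carries exactly one bit
    expect_equal(mutual_information(matrix(c(5, 0, 0, 5), 2)), 1)
    # independence carries none
    expect_equal(mutual_information(matrix(25, 2, 2)), 0)
    # 2x3 grid [[4,1,0],[0,1,4]]: direct term-by-term evaluation gives
    # 2 * 0.4*log2(0.4/(0.5*0.4)) + 2 * 0.1*log2(0.1/(0.5*0.2)) = 0.8 bits
    cnt <- matrix(c(4, 0, 1, 1, 0, 4), 2, 3)
    expect_equal(mutual_information(cnt), 0.8)
    expect_error(mutual_information(matrix(0, 2, 2)), "empty grid")
    expect_error(mutual_information(matrix(c(-1, 2, 2, 2), 2)), "non-negative")
})

test_that("mutual information never exceeds either marginal entropy", {
    set.seed(401)
    for (i in 1:200) {
        cnt <- matrix(rpois(6, 3), sample(2:3, 1))
        if (sum(cnt) == 0) next
        px <- rowSums(cnt) / sum(cnt)
        py <- colSums(cnt) / sum(cnt)
        h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
        expect_lte(mutual_information(cnt), min(h(px), h(py)) + 1e-12)
        expect_gte(mutual_information(cnt), -1e-12)
    }
})

test_that("normalized MI rescales by the smaller bin count", {
    expect_equal(normalized_mi(matrix(c(5, 0, 0, 5), 2)), 1)
    expect_equal(normalized_mi(matrix(10, 2, 3)), 0)
    expect_equal(normalized_mi(matrix(c(4, 0, 1, 1, 0, 4), 2, 3)), 0.8)
    expect_error(normalized_mi(matrix(1:4, 1)), "at least 2 bins")
})

test_that("MIC is 1 for noiseless monotone relationships", {
    set.seed(400)
    for (n in c(12, 16, 24, 48)) {
        x <- sort(runif(n))
        expect_equal(mic(x, x)$mic, 1)
        expect_equal(mic(x, exp(x))$mic, 1)
        expect_equal(mic(x, -x^3)$mic, 1)  # decreasing is association too
    }
})

test_that("MIC stays in [0,1] and shrinks for independent noise", {
    set.seed(402)
    small_n <- replicate(80, mic(runif(12), runif(12))$mic)
    large_n <- replicate(80, mic(runif(16), runif(16))$mic)
    expect_true(all(small_n >= 0 & small_n <= 1))
    expect_true(all(large_n >= 0 & large_n <= 1))
    # with the admissible shapes fixed (2x2 at both sizes), more points
    # mean less overfitting and a smaller chance association
    expect_lt(mean(large_n), mean(small_n))
})

test_that("MIC is symmetric and invariant under monotone transforms", {
    set.seed(403)
    for (i in 1:25) {
        n <- sample(c(12, 16, 24), 1)
        x <- runif(n)
        y <- sin(2 * pi * x) + rnorm(n, sd = 0.3)
        m <- mic(x, y)$mic
        expect_equal(mic(y, x)$mic, m)
        f <- random_monotone(i)
        g <- random_monotone(i + 1)
        expect_equal(mic(f(x), g(y))$mic, m)
    }
})

test_that("degenerate and too-short inputs are handled as contracts say", {
    s <- mic(rep(1, 12), runif(12))
    expect_equal(s$mic, 0)
    expect_true(s$degenerate)
    expect_error(mic(runif(6), runif(6)), "no admissible grid")
    expect_error(mic(runif(3), runif(3)), "at least 4")
    expect_error(mic(c(NA, runif(11)), runif(12)), "pairwise-delete")
    expect_error(mic(runif(12), runif(11)), "same length")
})

test_that("MIC equals the maximum characteristic-matrix entry", {
    set.seed(404)
    for (n in c(16, 24, 48)) {
        x <- runif(n)
        y <- x + rnorm(n, sd = 0.5)
        s <- mic(x, y, keep_matrix = TRUE)
        expect_equal(s$mic, max(s$char_matrix, na.rm = TRUE))
        # best shape respects the product bound, strictly
        expect_lt(s$best_cx * s$best_cy, n^0.6)
    }
})

test_that("dynamic-program search never exceeds the exhaustive oracle", {
    set.seed(405)
    for (i in 1:30) {
        n <- sample(8:12, 1)
        x <- runif(n)
        y <- runif(n)
        for (a in c(0.75, 0.95)) {
            expect_lte(mic(x, y, alpha = a, clumps = n)$mic,
                       brute_force_mic(x, y, alpha = a)$mic + 1e-12)
        }
    }
})

test_that("the exhaustive oracle honours its own contracts", {
    x <- sort(runif(8))
    expect_equal(brute_force_mic(x, x, alpha = 0.95)$mic, 1)
    expect_error(brute_force_mic(runif(13), runif(13)), "n <= 12")
    expect_error(brute_force_mic(runif(6), runif(6)), "no admissible grid")
    s <- brute_force_mic(rep(2, 12), runif(12))
    expect_equal(s$mic, 0)
    expect_true(s$degenerate)
})
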