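test_that("the reference sine is evaluated exactly on the grid", {
    r <- build_reference(c(0, 6, 12, 18))
    expect_equal(r$values, c(0, 1, 0, -1))
    # phase is periodic
    tm <- grid_2cyc(4)
    expect_equal(build_reference(tm, phase = 24)$values,
                 build_reference(tm, phase = 0)$values)
    # sampling at half-period multiples aliases the sine to ~0 everywhere
    expect_warning(build_reference(c(0, 12, 24, 36)), "degenerate reference")
    expect_error(build_reference(c(0, 6, 6, 18)), "strictly increasing")
    expect_error(build_reference(c(0, 6, 12, 18), period = -1), "positive")
})

test_that("scoring pairwise-deletes missing points", {
    tm <- grid_2cyc(3)
    ref <- build_reference(tm)
    clean <- sin(2 * pi * tm / 24)
    expect_equal(score_series(clean, ref)$mic, 1)
    # scoring with NAs equals scoring the truncated series directly
    set.seed(21)
    for (i in 1:10) {
        y <- clean + rnorm(16, sd = 0.4)
        drop <- sample(16, 3)
        y_na <- replace(y, drop, NA)
        s <- score_series(y_na, ref)
        expect_equal(s$n_used, 13)
        expect_equal(s$mic,
                     mic(ref$values[-drop], y[-drop])$mic)
    }
    # fewer than 4 usable points is unscoreable, not an error
    expect_null(score_series(replace(clean, 4:16, NA), ref))
    expect_error(score_series(clean[1:8], ref), "does not match")
})

test_that("the Monte-Carlo null is seeded, bounded and reusable", {
    ref <- build_reference(grid_2cyc(4))
    n1 <- sample_null(ref, n_draws = 150, seed = 9)
    n2 <- sample_null(ref, n_draws = 150, seed = 9)
    expect_identical(n1$mics, n2$mics)
    expect_true(all(n1$mics >= 0 & n1$mics <= 1))
    expect_false(identical(n1$mics, sample_null(ref, 150, seed = 10)$mics))
    # with the admissible grid shapes held fixed (2x2 at both lengths),
    # more timepoints mean less overfitting and a lower null
    ref16 <- build_reference(grid_2cyc(3))
    n16 <- sample_null(ref16, n_draws = 300, seed = 9)
    n12 <- sample_null(ref, n_draws = 300, seed = 9)
    expect_lt(mean(n16$mics), mean(n12$mics))
})

test_that("p-values count strict exceedances", {
    ref <- build_reference(grid_2cyc(4))
    nl <- sample_null(ref, n_draws = 200, seed = 4)
    expect_equal(p_value(1.0, nl), 0)            # nothing exceeds the max
    expect_equal(p_value(-0.1, nl), 1)           # everything exceeds
    med <- unname(stats::quantile(nl$mics, 0.5, type = 1))
    expect_equal(p_value(med, nl), sum(nl$mics > med) / 200)
    expect_lt(abs(p_value(med, nl) - 0.5), 0.2)  # median atom mass
    # monotone non-increasing in the observed MIC
    grid <- seq(0, 1, by = 0.05)
    ps <- vapply(grid, p_value, numeric(1), null = nl)
    expect_true(all(diff(ps) <= 0))
    # a score computed at another length is refused
    s <- score_series(sin(2 * pi * grid_2cyc(3) / 24),
                      build_reference(grid_2cyc(3)))
    expect_error(p_value(s, nl), "matching length")
})

test_that("matrix calls score, adjust and call per contract", {
    tm <- grid_2cyc(3)
    clean <- sin(2 * pi * tm / 24)
    x <- rbind(a = clean, b = clean, c = replace(clean, 1:13, NA),
               d = rep(1, 16))
    res <- micop_call(x, tm, n_draws = 200, seed = 2)
    expect_s3_class(res, "micop_result")
    expect_equal(res$id, c("a", "b", "c", "d"))
    expect_true(all(res$called[1:2]))
    expect_true(is.na(res$called[3]))  # 3 usable points: no call
    expect_false(res$called[4])        # flat row: degenerate, MIC 0
    expect_true(all(res$q >= res$p, na.rm = TRUE))
    expect_equal(nrow(micop_call(x[0, ], tm)), 0)
})

test_that("pure-noise matrices produce (almost) no BH calls", {
    tm <- grid_2cyc(3)
    set.seed(99)
    x <- matrix(runif(100 * 16), 100)
    res <- micop_call(x, tm, seed = 7)
    # discreteness of the MIC at short lengths lets the occasional null row
    # tie the null maximum (p = 0), so a stray call or two can survive BH
    expect_lte(sum(res$called), 3)
    expect_gt(mean(res$p), 0.3)  # raw p-values are far from enriched
})

test_that("null reuse gives identical results to per-row sampling", {
    tm <- grid_2cyc(4)
    set.seed(31)
    x <- matrix(runif(6 * 12), 6)
    shared <- new.env(parent = emptyenv())
    r1 <- micop_call(x, tm, n_draws = 100, seed = 5, null_cache = shared)
    r2 <- micop_call(x, tm, n_draws = 100, seed = 5)  # fresh cache
    expect_equal(r1, r2)
    # the shared cache holds exactly one null (all rows complete, same n)
    expect_length(ls(shared), 1)
    # per-row explicit computation agrees
    ref <- build_reference(tm)
    nl <- sample_null(ref, n_draws = 100, seed = 5)
    for (i in 1:6)
        expect_equal(r1$p[i], p_value(score_series(x[i, ], ref), nl))
})

test_that("permutation-mode nulls are a deterministic alternative", {
    tm <- grid_2cyc(4)
    set.seed(41)
    x <- matrix(runif(4 * 12), 4)
    r1 <- micop_call(x, tm, n_draws = 100, seed = 6,
                     null_mode = "permutation")
    r2 <- micop_call(x, tm, n_draws = 100, seed = 6,
                     null_mode = "permutation")
    expect_equal(r1, r2)
    expect_true(all(r1$p >= 0 & r1$p <= 1))
})

test_that("raw-p mode calls on the uncorrected p-value", {
    tm <- grid_2cyc(3)
    set.seed(51)
    x <- rbind(sin(2 * pi * tm / 24) + rnorm(16, sd = 0.2),
               runif(16))
    raw <- micop_call(x, tm, n_draws = 200, seed = 8, p_mode = "raw")
    expect_equal(raw$called, raw$p < 0.05)
})
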