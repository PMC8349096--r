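test_that("cubic fit recovers exact polynomials and their derivatives", {
    # exact linear data: gen = 2 * phys
    lin <- MareyMap(0:9, 2 * (0:9))
    fit <- fitPolynomial3(lin)
    expect_equal(unname(coef(fit)), c(0, 2, 0, 0), tolerance = 1e-9)
    expect_equal(recombinationRate(fit, c(1, 5, 9)), c(2, 2, 2),
                 tolerance = 1e-9)

    # exact cubic gen = x^3 - x (shifted into >= 0 territory)
    x <- seq(1, 5, by = 0.5)
    cub <- MareyMap(x, x^3 - x)
    fitc <- fitPolynomial3(cub)
    expect_equal(recombinationRate(fitc, x), 3 * x^2 - 1,
                 tolerance = 1e-8)

    # gen = x^2: derivative at 3 is 6
    sq <- MareyMap(0:6, (0:6)^2)
    expect_equal(recombinationRate(fitPolynomial3(sq), 3), 6,
                 tolerance = 1e-9)

    expect_error(fitPolynomial3(MareyMap(c(0, 1, 2), c(0, 1, 2))),
                 "at least 5")
    expect_error(recombinationRate(fit, 11), "extrapolation")
})

test_that("cubic coefficients match a normal-equations oracle on noisy data", {
    for (seed in c(7L, 21L, 99L)) {
        mm <- cubicFixture(n = 40, seed = seed, sd = 0.4)
        fit <- fitPolynomial3(mm)
        oracle <- normalEquationsCubic(physPos(mm), genPos(mm))
        expect_equal(unname(coef(fit)), oracle, tolerance = 1e-8)
    }
})

test_that("polynomial derivative equals the closed form, not a difference", {
    mm <- cubicFixture(n = 30, seed = 5L)
    fit <- fitPolynomial3(mm)
    cf <- coef(fit)
    xs <- seq(min(physPos(mm)), max(physPos(mm)), length.out = 17)
    expect_equal(recombinationRate(fit, xs),
                 unname(cf["a1"] + 2 * cf["a2"] * xs + 3 * cf["a3"] * xs^2),
                 tolerance = 1e-12)
})

test_that("loess reproduces linear data and approaches the cubic at span 1", {
    x <- seq(0, 20, by = 0.4)
    lin <- MareyMap(x, 2 * x)
    for (span in c(0.15, 0.5, 1.0)) {
        lfit <- fitLoess(lin, span = span)
        mid <- seq(1, 19, by = 0.7)
        expect_lt(max(abs(recombinationRate(lfit, mid) - 2)), 1e-3)
        expect_lt(max(abs(predictGen(lfit, mid) - 2 * mid)), 1e-6)
    }

    # on exact cubic data a moderate span tracks the global cubic closely
    # (the local fits are quadratic, so span 1 would leave a visible gap)
    x3 <- seq(0, 30, by = 0.5)
    cubm <- MareyMap(x3, 1 + 2.5 * x3 - 0.08 * x3^2 + 0.003 * x3^3)
    lf1 <- fitLoess(cubm, span = 0.3)
    pf <- fitPolynomial3(cubm)
    xs <- seq(1, 29, length.out = 25)
    expect_lt(max(abs(predictGen(lf1, xs) - predictGen(pf, xs))), 0.1)

    expect_error(fitLoess(lin, span = 0.03), "span")
    expect_error(fitLoess(MareyMap(1:10, (1:10) * 2), span = 0.1),
                 "minimum feasible span")
})

test_that("loess derivative peaks at the inflection of a sigmoid", {
    x <- seq(0, 20, by = 0.1)
    gen <- 50 * plogis(0.8 * (x - 10))
    mm <- MareyMap(x, gen)
    lfit <- fitLoess(mm, span = 0.3)
    grid <- seq(0.5, 19.5, by = 0.02)
    peak <- grid[which.max(recombinationRate(lfit, grid))]
    expect_lt(abs(peak - 10), 0.5)
})

test_that("cumulative R2 matches independent per-prefix refits", {
    mm <- cubicFixture(n = 20, seed = 33L, sd = 0.8)
    fwd <- r2Cumulative(mm, direction = "forward")
    bwd <- r2Cumulative(mm, direction = "backward")
    x <- physPos(mm); y <- genPos(mm)
    n <- length(x)
    for (k in 5:n) {
        expect_equal(fwd[k], bruteR2(x[1:k], y[1:k]), tolerance = 1e-9)
        expect_equal(bwd[n - k + 1], bruteR2(x[(n - k + 1):n],
                                             y[(n - k + 1):n]),
                     tolerance = 1e-9)
    }
    # short prefixes carry the first computable value
    expect_equal(fwd[1:4], rep(fwd[5], 4))
    # both full-data entries agree
    expect_equal(fwd[n], bwd[1], tolerance = 1e-9)

    curves <- r2Curves(mm)
    expect_s4_class(curves, "R2Curves")
    expect_equal(forwardR2(curves), fwd)
    expect_true(all(forwardR2(curves) <= 1 + 1e-12))
})

test_that("perfect cubic data give R2 identically one", {
    x <- seq(0, 10, by = 0.5)
    mm <- MareyMap(x, 1 + 0.5 * x + 0.02 * x^3)
    expect_equal(r2Cumulative(mm, direction = "forward"),
                 rep(1, length(x)), tolerance = 1e-9)
})

test_that("alternative cumulative statistics stay available", {
    mm <- cubicFixture(n = 25, seed = 3L, sd = 0.6)
    fit <- fitPolynomial3(mm)
    # raw cumulative RSS of the global fit is non-decreasing
    rss <- r2Cumulative(mm, fit, "forward", statistic = "rss")
    expect_true(all(diff(rss) >= -1e-12))
    expect_equal(rss[length(rss)],
                 sum((genPos(mm) - predictGen(fit, physPos(mm)))^2),
                 tolerance = 1e-9)
    # global-fit-per-prefix variant is bounded by 1 and ends at the
    # refitted value
    glob <- r2Cumulative(mm, fit, "forward", refit = FALSE)
    expect_true(all(glob <= 1 + 1e-12))
    expect_equal(glob[length(glob)],
                 r2Cumulative(mm, direction = "forward")[nMarkers(mm)],
                 tolerance = 1e-9)
})
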