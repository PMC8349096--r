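test_that("sliding-window size is the largest consecutive physical gap", {
    expect_equal(slidingWindowSize(MareyMap(c(0, 1, 3, 4), c(0, 1, 2, 3))),
                 2)
    expect_equal(slidingWindowSize(MareyMap(seq(0, 10, by = 0.5),
                                            seq(0, 20, by = 1))), 0.5)
    mm <- uniformFixture(n = 60, L = 30, seed = 14L)
    expect_equal(slidingWindowSize(mm), max(diff(sort(physPos(mm)))))
})

test_that("centromeric gaps are detected and can be overridden", {
    # uniform 2 markers/Mb: max gap is close to the median, no gap call
    mm <- MareyMap(seq(0, 40, by = 0.5), seq(0, 80, by = 1))
    expect_null(detectCentromericGap(mm))

    # markers on [0,18] and [26,44]: the 8-Mb hole is reported
    withr::with_seed(15, {
        p <- sort(c(runif(90, 0, 18), runif(90, 26, 44)))
    })
    gm <- MareyMap(p, seq(0, 100, length.out = 180))
    gap <- detectCentromericGap(gm)
    expect_false(is.null(gap))
    expect_equal(gap[1], max(p[p <= 18]))
    expect_equal(gap[2], min(p[p >= 26]))
    expect_null(detectCentromericGap(gm, forceNoGap = TRUE))
})

test_that("chromosome typing follows the rate-minimum position", {
    mm <- uniformFixture(n = 100, L = 40, seed = 16L)
    L1 <- min(physPos(mm)); L2 <- max(physPos(mm))
    at <- function(f) L1 + f * (L2 - L1)

    t1 <- identifyChromosomeType(mm, at(0.98), at(0.95))
    expect_equal(t1@form, "telocentric")
    expect_equal(t1@centromereSide, "right")

    t2 <- identifyChromosomeType(mm, at(0.03), at(0.05))
    expect_equal(t2@centromereSide, "left")

    # interior minimum at 50%: metacentric
    t3 <- identifyChromosomeType(mm, at(0.5), at(0.5))
    expect_equal(t3@form, "atelocentric")
    expect_equal(t3@subtype, "metacentric")

    # minimum at 30% of the span: not metacentric
    t4 <- identifyChromosomeType(mm, at(0.3), at(0.3))
    expect_equal(t4@subtype, "not_metacentric")

    # models disagreeing about the edge: undetermined, override honoured
    t5 <- identifyChromosomeType(mm, at(0.3), at(0.98))
    expect_equal(t5@subtype, "undetermined")
    t6 <- identifyChromosomeType(mm, at(0.3), at(0.98),
                                 override = "telocentric")
    expect_equal(t6@form, "telocentric")
})

test_that("centromere detection recovers simulated boundaries", {
    # metacentric, no gap
    sc <- mareyScenario(seed = 21L)
    sim <- simulateMap(sc)
    res <- mareyHCB(sim$map, force = TRUE,
                    chromosomeTypeOverride = "atelocentric")
    cen <- centromericBoundaries(res)
    w <- windowSize(res)
    expect_lt(abs(cen[1] - 20), 2 * w)
    expect_lt(abs(cen[2] - 24), 2 * w)

    # with a centromeric gap the flanks are recovered too
    scg <- mareyScenario(seed = 21L, hasGap = TRUE)
    simg <- simulateMap(scg)
    expect_false(any(physPos(simg$map) > 20 & physPos(simg$map) < 24))
    resg <- mareyHCB(simg$map, force = TRUE,
                     chromosomeTypeOverride = "atelocentric")
    expect_true(chromosomeType(resg)@hasCentromericGap)
    ceng <- centromericBoundaries(resg)
    wg <- windowSize(resg)
    expect_lt(abs(ceng[1] - 20), 2 * wg)
    expect_lt(abs(ceng[2] - 24), 2 * wg)

    # telocentric arm: a single interval ending at the chromosome end
    sct <- mareyScenario("telocentric", seed = 22L)
    simt <- simulateMap(sct)
    rest <- mareyHCB(simt$map, force = TRUE,
                     chromosomeTypeOverride = "telocentric")
    expect_equal(chromosomeType(rest)@form, "telocentric")
    cent <- centromericBoundaries(rest)
    p <- physPos(mapUsed(rest))
    expect_equal(cent[2], p[length(p)])   # distal limit is the arm end
    expect_lt(abs(cent[1] - 19), 2 * windowSize(rest))
})

test_that("telomere detection uses R2 depletion and degenerates safely", {
    # single realisations are noisy, so recovery of the planted 2-Mb /
    # 42-Mb inner edges is asserted on the median over seeds; the R2
    # depletion resolves a telomere to ~2 Mb at these densities, biased
    # into euchromatin
    leftErr <- rightErr <- numeric(10)
    for (s in 1:10) {
        sim <- simulateMap(mareyScenario(seed = 22L + s))
        res <- mareyHCB(sim$map, force = TRUE,
                        chromosomeTypeOverride = "atelocentric")
        tels <- telomericIntervals(res)
        expect_length(tels, 2L)
        leftErr[s] <- abs(tels$left[2] - 2)
        rightErr[s] <- abs(tels$right[1] - 42)
        # outer edges are the chromosome ends
        p <- physPos(mapUsed(res))
        expect_equal(tels$left[1], p[1])
        expect_equal(tels$right[2], p[length(p)])
    }
    expect_lt(median(leftErr), 3)
    expect_lt(median(rightErr), 3)

    # telocentric: exactly one telomeric interval
    rest <- mareyHCB(simulateMap(mareyScenario("telocentric",
                                               seed = 24L))$map,
                     force = TRUE, chromosomeTypeOverride = "telocentric")
    expect_length(telomericIntervals(rest), 1L)

    # perfect cubic data: R2 is 1 everywhere, telomeres collapse to ends
    x <- seq(0, 30, by = 0.25)
    perfect <- MareyMap(x, 0.5 * x + 0.001 * x^3)
    curves <- r2Curves(perfect)
    ct <- identifyChromosomeType(perfect, 15, 15)
    tel <- detectTelomeres(perfect, curves, ct, c(14, 16))
    expect_equal(tel$telomereLeft, c(0, 0))
})

test_that("rate extrapolation zeroes heterochromatin and floors negatives", {
    mm <- cubicFixture(n = 50, seed = 25L, sd = 0.2)
    fit <- fitPolynomial3(mm)
    h <- new("HCB", centromeric = c(10, 15), telomereLeft = c(2, 4),
             telomereRight = numeric(0), flags = character(0))
    grid <- seq(ceiling(min(physPos(mm))), floor(max(physPos(mm))),
                by = 0.5)
    out <- extrapolateRates(fit, h, grid)
    inside <- (grid >= 10 & grid <= 15) | (grid >= 2 & grid <= 4)
    expect_true(all(out$rate[inside] == 0))
    raw <- recombinationRate(fit, grid)
    expect_equal(out$rate[!inside], pmax(raw[!inside], 0))
    expect_true(all(out$rate >= 0))

    # a derivative that is negative outside heterochromatin is floored
    dec <- MareyMap(seq(0, 10, by = 0.5),
                    pmax(10 - seq(0, 10, by = 0.5), 0))
    fd <- fitPolynomial3(dec)
    o2 <- extrapolateRates(fd, new("HCB", centromeric = c(NA_real_, NA_real_),
                                   flags = character(0)),
                           seq(0, 10, by = 1))
    expect_true(all(o2$rate >= 0))
})

test_that("the full pipeline is deterministic and self-consistent", {
    sim <- simulateMap(mareyScenario(seed = 26L))
    r1 <- mareyHCB(sim$map, force = TRUE)
    r2 <- mareyHCB(sim$map, force = TRUE)
    expect_identical(rateGrid(r1), rateGrid(r2))
    expect_identical(hcb(r1)@centromeric, hcb(r2)@centromeric)
    expect_identical(internalBoundaries(r1), internalBoundaries(r2))

    # boundaries lie on the marker span; heterochromatin never overlaps
    p <- physPos(mapUsed(r1))
    ib <- internalBoundaries(r1)
    expect_true(all(ib >= p[1] & ib <= p[length(p)]))
    h <- hcb(r1)
    if (length(h@telomereLeft))
        expect_lte(h@telomereLeft[2], h@centromeric[1])
    if (length(h@telomereRight))
        expect_gte(h@telomereRight[1], h@centromeric[2])

    # final rates: zero inside heterochromatin, non-negative outside
    g <- rateGrid(r1)
    inHet <- (g$phys >= h@centromeric[1] & g$phys <= h@centromeric[2])
    if (length(h@telomereLeft))
        inHet <- inHet | (g$phys >= h@telomereLeft[1] &
                          g$phys <= h@telomereLeft[2])
    if (length(h@telomereRight))
        inHet <- inHet | (g$phys >= h@telomereRight[1] &
                          g$phys <= h@telomereRight[2])
    expect_true(all(g$rate[inHet] == 0))
    expect_true(all(g$rate >= 0))
})

test_that("DQC gate stops the pipeline unless cleaned or forced", {
    # dense but wildly non-uniform: distribution fails
    p <- c(withr::with_seed(2, runif(199, 0, 5)), 50)
    mm <- MareyMap(p, seq(0, 100, length.out = 200))
    expect_error(mareyHCB(mm), "quality control")
    expect_s4_class(mareyHCB(mm, force = TRUE), "HcbResult")
})
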