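test_that("global density is n over the largest physical position", {
    mm <- uniformFixture(n = 100, L = 50, seed = 3L)
    # force the exact endpoint so L is known
    m <- markers(mm); m$phys[100] <- 50
    mm <- MareyMap(m$phys, m$gen)
    expect_equal(globalDensity(mm), 100 / 50)

    # the published worked examples: 165 markers over 21.22 Mb, and the
    # genome-wide 618 over 114.59 Mb
    expect_equal(round(165 / 21.22, 2), 7.78)
    mmX <- MareyMap(c(seq(0, 21, length.out = 164), 21.22),
                    seq(0, 66, length.out = 165))
    expect_equal(round(globalDensity(mmX), 2), 7.78)
    expect_equal(round(618 / 114.59, 2), 5.39)

    expect_error(
        globalDensity(suppressWarnings(MareyMap(c(0, 0), c(0, 1)))),
        "degenerate")
})

test_that("local density profile matches brute-force bin assignment", {
    # worked example: L = 21.22 -> 22 one-Mb bins, mean 165/22 = 7.5
    mmX <- MareyMap(c(seq(0, 21, length.out = 164), 21.22),
                    seq(0, 66, length.out = 165))
    prof <- localDensityProfile(mmX, binWidth = 1)
    expect_length(prof$counts, 22L)
    expect_equal(round(prof$mean, 1), 7.5)
    expect_equal(sum(prof$counts), 165L)

    # single occupied bin
    mm <- MareyMap(c(seq(0, 0.9, length.out = 10), 5),
                   seq(0, 10, length.out = 11))
    prof2 <- localDensityProfile(mm, binWidth = 1)
    expect_equal(prof2$counts, c(10L, 0L, 0L, 0L, 1L))

    # random fixture vs per-marker brute-force assignment
    mm3 <- uniformFixture(n = 137, L = 33.7, seed = 8L)
    w <- 2.5
    prof3 <- localDensityProfile(mm3, binWidth = w)
    nb <- ceiling(max(physPos(mm3)) / w)
    brute <- integer(nb)
    for (p in physPos(mm3)) {
        k <- min(floor(p / w), nb - 1L) + 1L
        brute[k] <- brute[k] + 1L
    }
    expect_equal(prof3$counts, brute)
    expect_equal(sum(prof3$counts), nMarkers(mm3))
})

test_that("DQC flags density and distribution as specified", {
    mm <- uniformFixture(n = 200, L = 50, seed = 4L)
    q <- runDQC(mm)
    expect_true(densityPass(q))       # 4 markers/Mb >= 2
    expect_true(q@globalDensity >= 2)

    # sparse map fails the density threshold
    sparse <- uniformFixture(n = 30, L = 50, seed = 4L)
    expect_false(densityPass(runDQC(sparse)))

    # concentrated map (nearly all markers in the first tenth) fails the
    # distribution test; the chi-squared statistic matches a hand-pooled
    # table
    p <- c(withr::with_seed(1, runif(199, 0, 5)), 50)
    conc <- MareyMap(p, seq(0, 100, length.out = 200))
    qc <- runDQC(conc)
    expect_false(distributionPass(qc))
    counts <- localDensityProfile(conc, 1)$counts
    pool <- function(cnt, expPerBin) {
        out <- integer(0); acc <- 0; accw <- 0
        for (ci in cnt) {
            acc <- acc + ci; accw <- accw + 1
            if (expPerBin * accw >= 5) { out <- c(out, acc); acc <- 0; accw <- 0 }
        }
        if (accw > 0) out[length(out)] <- out[length(out)] + acc
        out
    }
    pooled <- pool(counts, 200 / 50)
    byHand <- suppressWarnings(
        chisq.test(pooled, p = rep(1 / length(pooled), length(pooled))))
    expect_equal(q2 <- qc@chi2Stat, unname(byHand$statistic))
})

test_that("chi-squared distribution test is calibrated under the null", {
    rejected <- vapply(1:100, function(s) {
        mm <- uniformFixture(n = 200, L = 50, seed = s)
        isFALSE(distributionPass(runDQC(mm)))
    }, logical(1))
    expect_lte(mean(rejected), 0.10)   # about the nominal 5% level
})

test_that("outlier cleaning removes only extreme genetic jumps", {
    # equal gaps: IQR = 0, no gap above the fence
    mm <- MareyMap(seq(0, 49), seq(0, 98, by = 2))
    cl <- cleanOutliers(mm)
    expect_equal(nrow(removedMarkers(cl)), 0L)
    expect_equal(fractionRemoved(cl), 0)

    # 3 planted 50-cM jumps among ~1-cM gaps: exactly the 3 downstream
    # markers of the planted gaps go
    withr::with_seed(10, {
        gaps <- runif(99, 0.5, 1)
        gaps[c(25, 50, 75)] <- 50
        gen <- cumsum(c(0, gaps))
        mm2 <- MareyMap(seq(0, 49.5, by = 0.5), gen)
    })
    cl2 <- cleanOutliers(mm2)
    expect_equal(nrow(removedMarkers(cl2)), 3L)
    expect_setequal(removedMarkers(cl2)$phys,
                    physPos(mm2)[c(26, 51, 76)])
    expect_equal(nMarkers(cleanedMap(cl2)) + 3L, nMarkers(mm2))

    # removal is capped at ceiling(5% n) even with many flagged gaps
    withr::with_seed(11, {
        gaps3 <- runif(99, 0.5, 1)
        gaps3[seq(5, 95, by = 10)] <- 60    # 10 planted jumps
        mm3 <- MareyMap(seq(0, 49.5, by = 0.5), cumsum(c(0, gaps3)))
    })
    cl3 <- cleanOutliers(mm3)
    expect_equal(nrow(removedMarkers(cl3)), ceiling(0.05 * 100))
    # largest gaps are taken first
    expect_true(all(removedMarkers(cl3)$gap >= 60))

    # small maps are refused
    small <- MareyMap(1:10, (1:10) * 2)
    expect_warning(cl4 <- cleanOutliers(small), "refused")
    expect_equal(nMarkers(cleanedMap(cl4)), 10L)
})
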