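## The full pipeline: DQC -> (clean) -> regression -> typing -> boundary
## detection -> heterochromatin-adjusted recombination map.

#' Run the full heterochromatin-boundary pipeline on one chromosome
#'
#' Executes, in order: data quality control (\code{\link{runDQC}}),
#' optional outlier cleaning (\code{\link{cleanOutliers}}, iterated while
#' DQC fails), cubic and Loess Marey-curve fits with derivative
#' recombination rates, centromeric-gap detection, chromosome-type
#' identification, cumulative R-squared curve construction, sliding-window
#' centromeric boundary detection, telomeric boundary detection, and
#' zeroing of the final Loess-based rate map across heterochromatin.  The
#' run is fully deterministic for a given map and options.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param span Loess span (0.05--1, default 0.15).
#' @param densityThreshold DQC minimum density, markers/Mb (default 2).
#' @param alpha DQC significance level (default 0.05).
#' @param autoClean clean outliers (at most \code{maxCleanIter} passes)
#'   while DQC fails, without prompting.
#' @param force proceed even if DQC fails (default FALSE: failing DQC
#'   without \code{autoClean} is an error).
#' @param forceNoGap force the no-centromeric-gap algorithm.
#' @param chromosomeTypeOverride optional \code{"telocentric"} or
#'   \code{"atelocentric"}.
#' @param edgeFraction outer span fraction counting as a chromosome end
#'   for telocentric calling (default 0.10).
#' @param gapFactor,minGapMb centromeric-gap thresholds, see
#'   \code{\link{detectCentromericGap}}.
#' @param gridPoints number of grid intervals of the exported rate map
#'   (default 1000).
#' @param maxCleanIter cleaning iterations allowed with \code{autoClean}.
#' @return an \linkS4class{HcbResult}.
#' @examples
#' sim <- simulateMap(mareyScenario(seed = 7L))
#' res <- mareyHCB(sim$map, force = TRUE)
#' internalBoundaries(res)
#' @export
mareyHCB <- function(map, span = 0.15, densityThreshold = 2, alpha = 0.05,
                     autoClean = FALSE, force = FALSE, forceNoGap = FALSE,
                     chromosomeTypeOverride = NULL, edgeFraction = 0.10,
                     gapFactor = 20, minGapMb = 1, gridPoints = 1000L,
                     maxCleanIter = 5L) {
    stopifnot(is(map, "MareyMap"))
    ## Step 0: DQC (+ optional cleaning)
    q <- runDQC(map, densityThreshold, alpha)
    if (!dqcPass(q) && autoClean) {
        for (i in seq_len(maxCleanIter)) {
            cl <- cleanOutliers(map)
            if (nrow(removedMarkers(cl)) == 0L) break
            map <- cleanedMap(cl)
            q <- quality(cl)
            if (dqcPass(q)) break
        }
    }
    if (!dqcPass(q) && !force && !autoClean)
        stop("data quality control failed (density ",
             sprintf("%.2f", q@globalDensity), "/Mb, distribution p = ",
             signif(q@chi2Pvalue, 3),
             "); clean the data (autoClean = TRUE) or rerun with force = TRUE")
    p <- physPos(map)
    ## Step 1: regression models and preliminary rates
    polyFit <- fitPolynomial3(map)
    loessFit <- fitLoess(map, span = span)
    grid <- seq(p[1L], p[length(p)], length.out = gridPoints + 1L)
    polyRate <- recombinationRate(polyFit, grid)
    loessRate <- recombinationRate(loessFit, grid)
    polyArgmin <- grid[which.min(polyRate)]
    loessArgmin <- grid[which.min(loessRate)]
    ## Step 2: centromeric gap + chromosome type
    gap <- detectCentromericGap(map, gapFactor, minGapMb, forceNoGap)
    chromType <- identifyChromosomeType(map, polyArgmin, loessArgmin,
                                        edgeFraction,
                                        chromosomeTypeOverride, gap)
    ## Step 3: cumulative R^2 curves and window size
    curves <- r2Curves(map, polyFit)
    w <- slidingWindowSize(map)
    ## Step 4: centromeric boundaries
    cen <- detectCentromere(map, curves, chromType, polyArgmin, w)
    ## Step 5: telomeric boundaries
    tel <- detectTelomeres(map, curves, chromType, cen$interval)
    flags <- c(cen$flags, tel$flags)
    ## enforce non-overlap of centromeric and telomeric heterochromatin
    tl <- tel$telomereLeft; tr <- tel$telomereRight
    if (length(tl) && tl[2L] > cen$interval[1L]) {
        tl[2L] <- cen$interval[1L]
        flags <- c(flags, "telomere_left_clipped")
    }
    if (length(tr) && tr[1L] < cen$interval[2L]) {
        tr[1L] <- cen$interval[2L]
        flags <- c(flags, "telomere_right_clipped")
    }
    hcb <- new("HCB", centromeric = cen$interval, telomereLeft = tl,
               telomereRight = tr, flags = flags)
    ## Step 6: heterochromatin-adjusted Loess recombination map
    rateGrid <- extrapolateRates(loessFit, hcb, grid)
    rawGrid <- data.frame(phys = grid, rate = loessRate)
    new("HcbResult", mapUsed = map, quality = q, chromType = chromType,
        hcb = hcb, rateGrid = rateGrid, rawRateGrid = rawGrid,
        windowMb = w, span = span)
}

#' Run the pipeline on every chromosome of a MareyGenome
#'
#' @param genome a \linkS4class{MareyGenome}.
#' @param ... options passed to \code{\link{mareyHCB}}.
#' @return named list of \linkS4class{HcbResult}, one per chromosome.
#' @export
mareyHCBGenome <- function(genome, ...) {
    stopifnot(is(genome, "MareyGenome"))
    lapply(chromosomes(genome), mareyHCB, ...)
}
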