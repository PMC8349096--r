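## Step 0: data quality control (density + distribution) and cleaning.

#' Global marker density
#'
#' Number of markers divided by the physical map length, where the map
#' length is the largest physical position (Mb).
#'
#' @param map a \linkS4class{MareyMap}.
#' @return markers/Mb.
#' @examples
#' mm <- simulateMap(mareyScenario(seed = 1L))$map
#' globalDensity(mm)
#' @export
globalDensity <- function(map) {
    stopifnot(is(map, "MareyMap"))
    L <- mapLength(map)
    if (L <= 0) stop("degenerate map: physical length is zero")
    nMarkers(map) / L
}

#' Local marker-density profile in fixed-width bins
#'
#' Bins are anchored at 0 Mb and half-open, \eqn{[kw, (k+1)w)}; the number
#' of bins is \code{ceiling(L / binWidth)} with L the map length, so with
#' 1-Mb bins each count is a local density in markers/Mb.  A marker exactly
#' at the map end is counted in the last bin.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param binWidth bin width, Mb (default 1).
#' @return list with \code{counts} (per-bin marker counts), \code{breaks}
#'   (bin edges) and \code{mean} (mean count over bins).
#' @export
localDensityProfile <- function(map, binWidth = 1) {
    stopifnot(is(map, "MareyMap"), binWidth > 0)
    L <- mapLength(map)
    nb <- ceiling(L / binWidth)
    idx <- pmin(floor(physPos(map) / binWidth), nb - 1L) + 1L
    counts <- tabulate(idx, nbins = nb)
    list(counts = counts, breaks = seq(0, nb * binWidth, by = binWidth),
         mean = sum(counts) / nb)
}

#' Data quality control (DQC)
#'
#' Tests (1) the global marker density against a minimum threshold
#' (2 markers/Mb by default) and (2) the homogeneity of the marker
#' distribution along the physical map.  The distribution test is a
#' Pearson chi-squared goodness-of-fit of the 1-Mb bin occupancy against
#' the uniform expectation; bins are pooled left-to-right until every
#' expected count reaches 5 (Cochran's rule).  When fewer than two pooled
#' bins remain the test is inconclusive and \code{distributionPass} is
#' \code{NA}.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param densityThreshold minimum density, markers/Mb.
#' @param alpha significance level; the distribution passes when
#'   \eqn{p \ge \alpha}.
#' @param seed accepted for interface stability; the uniform reference is
#'   computed analytically, so no randomness is involved and the value is
#'   ignored.
#' @return a \linkS4class{QualityReport}.
#' @examples
#' mm <- simulateMap(mareyScenario(seed = 1L))$map
#' runDQC(mm)
#' @export
runDQC <- function(map, densityThreshold = 2, alpha = 0.05, seed = NULL) {
    stopifnot(is(map, "MareyMap"))
    n <- nMarkers(map)
    L <- mapLength(map)
    dens <- globalDensity(map)
    prof <- localDensityProfile(map, binWidth = 1)
    counts <- prof$counts
    widths <- diff(prof$breaks)
    ## greedy left-to-right pooling until expected >= 5
    expPerMb <- n / sum(widths)
    pooledC <- numeric(0); pooledW <- numeric(0)
    accC <- 0; accW <- 0
    for (i in seq_along(counts)) {
        accC <- accC + counts[i]; accW <- accW + widths[i]
        if (expPerMb * accW >= 5) {
            pooledC <- c(pooledC, accC); pooledW <- c(pooledW, accW)
            accC <- 0; accW <- 0
        }
    }
    if (accW > 0) {        # fold the short tail into the last pooled bin
        if (length(pooledC)) {
            pooledC[length(pooledC)] <- pooledC[length(pooledC)] + accC
            pooledW[length(pooledW)] <- pooledW[length(pooledW)] + accW
        } else { pooledC <- accC; pooledW <- accW }
    }
    if (length(pooledC) < 2L) {
        chi2 <- NA_real_; pval <- NA_real_; distPass <- NA
        warning("distribution test inconclusive: fewer than 2 pooled bins")
    } else {
        ht <- suppressWarnings(
            stats::chisq.test(pooledC, p = pooledW / sum(pooledW)))
        chi2 <- unname(ht$statistic); pval <- unname(ht$p.value)
        distPass <- pval >= alpha
    }
    new("QualityReport", nMarkers = as.integer(n), mapLength = L,
        globalDensity = dens, densityPass = dens >= densityThreshold,
        chi2Stat = chi2, chi2Pvalue = pval, distributionPass = distPass,
        threshold = densityThreshold, alpha = alpha)
}

#' Clean genetic-map outliers
#'
#' Computes the inter-marker genetic gaps \eqn{g_i = gen_{i+1} - gen_i}
#' along the physically sorted map, derives boxplot statistics of the gaps,
#' and flags gaps exceeding the extreme-outlier fence Q3 + 3 IQR.  For each
#' flagged gap the downstream marker (the point jumping away on the genetic
#' map) is removed, largest gaps first, up to
#' \code{ceiling(targetFraction * n)} markers.  Maps with fewer than 20
#' markers are returned unchanged with a warning.  DQC is re-run on the
#' cleaned map; callers wanting the iterative clean-until-pass behaviour
#' should loop \code{runDQC}/\code{cleanOutliers}.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param targetFraction maximum fraction of markers to remove (default
#'   0.05).
#' @return a \linkS4class{CleanResult}.
#' @export
cleanOutliers <- function(map, targetFraction = 0.05) {
    stopifnot(is(map, "MareyMap"), targetFraction > 0)
    n <- nMarkers(map)
    empty <- data.frame(phys = numeric(0), gen = numeric(0),
                        gap = numeric(0))
    if (n < 20L) {
        warning("fewer than 20 markers: cleaning refused, map unchanged")
        return(new("CleanResult", cleanedMap = map, removed = empty,
                   fractionRemoved = 0, quality = runDQC(map)))
    }
    gaps <- diff(genPos(map))
    qs <- stats::quantile(gaps, c(0.25, 0.75), names = FALSE)
    fence <- qs[2L] + 3 * (qs[2L] - qs[1L])
    flagged <- which(gaps > fence)          # gap i -> marker i+1 removed
    maxRemove <- ceiling(targetFraction * n)
    if (length(flagged) > maxRemove)
        flagged <- flagged[order(gaps[flagged], decreasing = TRUE)][seq_len(maxRemove)]
    if (!length(flagged)) {
        return(new("CleanResult", cleanedMap = map, removed = empty,
                   fractionRemoved = 0, quality = runDQC(map)))
    }
    drop <- flagged + 1L
    m <- markers(map)
    removed <- data.frame(phys = m$phys[drop], gen = m$gen[drop],
                          gap = gaps[flagged])
    cleaned <- MareyMap(m$phys[-drop], m$gen[-drop],
                        chromosomeId = chromosomeId(map))
    new("CleanResult", cleanedMap = cleaned, removed = removed,
        fractionRemoved = length(drop) / n, quality = runDQC(cleaned))
}
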