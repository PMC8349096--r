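## Steps 2, 4, 5, 6: chromosome typing, centromeric-gap detection,
## centromeric and telomeric boundary identification, and
## heterochromatin-aware rate extrapolation.

#' Sliding-window size for boundary detection
#'
#' The window size is the largest distance between two consecutive marker
#' physical positions, so a window anchored at any marker always spans its
#' neighbour.  During sliding, a window instance that happens to hold fewer
#' than two markers is widened on its far edge until it does.
#'
#' @param map a \linkS4class{MareyMap}.
#' @return window size, Mb.
#' @examples
#' slidingWindowSize(MareyMap(phys = c(0, 1, 3, 4), gen = c(0, 1, 2, 3)))
#' @export
slidingWindowSize <- function(map) {
    stopifnot(is(map, "MareyMap"))
    max(diff(physPos(map)))
}

#' Detect a centromeric assembly gap
#'
#' Centromeres are often unassembled, leaving an extended physical interval
#' without markers.  The largest consecutive physical gap is called a
#' centromeric gap when it is at least \code{gapFactor} times the median
#' consecutive gap and at least \code{minGapMb} wide.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param gapFactor multiple of the median gap required (default 20).
#' @param minGapMb absolute minimum gap width, Mb (default 1).
#' @param forceNoGap when TRUE the no-gap algorithm is forced and no gap is
#'   reported regardless of the data.
#' @return numeric(2) flanking-marker interval (Mb), or \code{NULL} when no
#'   gap qualifies.
#' @export
detectCentromericGap <- function(map, gapFactor = 20, minGapMb = 1,
                                 forceNoGap = FALSE) {
    stopifnot(is(map, "MareyMap"))
    if (forceNoGap) return(NULL)
    p <- physPos(map)
    gaps <- diff(p)
    i <- which.max(gaps)
    if (gaps[i] >= gapFactor * stats::median(gaps) && gaps[i] >= minGapMb)
        c(p[i], p[i + 1L])
    else NULL
}

#' Identify the chromosome type from recombination-rate minima
#'
#' A chromosome is called telocentric (a single arm, centromere at one end)
#' when the physical position of the smallest polynomial-based
#' recombination rate lies within the outer \code{edgeFraction} of the map
#' span; otherwise it is atelocentric.  Atelocentric chromosomes are
#' subtyped metacentric when the Loess-based rate minimum falls within
#' 40--60% of the span, not metacentric otherwise.  When the polynomial and
#' Loess minima disagree about telocentric placement the subtype is
#' undetermined and a user override of the form is honoured.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param polyRateArgmin,loessRateArgmin physical positions (Mb) of the
#'   rate minima under the two regression models.
#' @param edgeFraction outer fraction of the span that counts as an end
#'   (default 0.10).
#' @param override optional \code{"telocentric"} or \code{"atelocentric"}
#'   to force the form (the a-priori-knowledge confirmation).
#' @param gapInterval optional numeric(2) centromeric gap from
#'   \code{\link{detectCentromericGap}}.
#' @return a \linkS4class{ChromosomeType}.
#' @export
identifyChromosomeType <- function(map, polyRateArgmin, loessRateArgmin,
                                   edgeFraction = 0.10, override = NULL,
                                   gapInterval = NULL) {
    stopifnot(is(map, "MareyMap"))
    p <- physPos(map)
    rel <- function(x) (x - p[1L]) / (p[length(p)] - p[1L])
    polyRel <- rel(polyRateArgmin)
    loessRel <- rel(loessRateArgmin)
    atEdge <- function(r) r <= edgeFraction || r >= 1 - edgeFraction
    teloPoly <- atEdge(polyRel)
    teloLoess <- atEdge(loessRel)
    form <- if (teloPoly) "telocentric" else "atelocentric"
    agree <- teloPoly == teloLoess
    if (!is.null(override)) {
        override <- match.arg(override, c("telocentric", "atelocentric"))
        form <- override
    }
    if (form == "telocentric") {
        side <- if (polyRel >= 0.5) "right" else "left"
        subtype <- "none"
    } else {
        side <- "interior"
        subtype <- if (!agree) "undetermined"
            else if (loessRel >= 0.40 && loessRel <= 0.60) "metacentric"
            else "not_metacentric"
    }
    new("ChromosomeType", form = form, subtype = subtype,
        centromereSide = side,
        hasCentromericGap = !is.null(gapInterval),
        gapInterval = if (is.null(gapInterval)) numeric(0)
                      else as.numeric(gapInterval))
}

## One-sided sliding-window search along a cumulative R^2 curve.
## direction "left": windows move leftward from `start` on the forward
## curve and stop when the mean within-window growth is positive;
## direction "right": windows move rightward on the backward curve and
## stop when it is negative.  The window step equals the window size; the
## first window's inner edge touches `start`.  Returns the boundary
## (proximal window edge snapped to the nearest marker) plus flags.
.searchBoundary <- function(positions, curve, start, window,
                            direction = c("left", "right"),
                            gapMode = FALSE) {
    direction <- match.arg(direction)
    sgn <- if (direction == "left") 1 else -1
    n <- length(positions)
    lo <- positions[1L]; hi <- positions[n]
    j <- 0L
    repeat {
        j <- j + 1L
        if (direction == "left") {
            win <- c(start - j * window, start - (j - 1L) * window)
            if (win[2L] <= lo)
                return(list(pos = lo, flags = "centromere_low_confidence"))
        } else {
            win <- c(start + (j - 1L) * window, start + j * window)
            if (win[1L] >= hi)
                return(list(pos = hi, flags = "centromere_low_confidence"))
        }
        idx <- which(positions >= win[1L] & positions <= win[2L])
        while (length(idx) < 2L) {
            ## widen on the far edge until the window holds two markers
            if (direction == "left") {
                cand <- which(positions < win[1L])
                if (!length(cand)) break
                win[1L] <- positions[max(cand)]
            } else {
                cand <- which(positions > win[2L])
                if (!length(cand)) break
                win[2L] <- positions[min(cand)]
            }
            idx <- which(positions >= win[1L] & positions <= win[2L])
        }
        if (length(idx) < 2L) {
            end <- if (direction == "left") lo else hi
            return(list(pos = end, flags = "centromere_low_confidence"))
        }
        growth <- mean(diff(curve[idx]))
        ok <- sgn * growth > 0
        if (ok && gapMode) {
            ## confirmation: accumulated point slopes, adding one point at
            ## a time, must keep the direction of the growth-rate mean
            p0 <- positions[idx[1L]]; c0 <- curve[idx[1L]]
            slopes <- (curve[idx[-1L]] - c0) / (positions[idx[-1L]] - p0)
            acc <- cumsum(slopes) / seq_along(slopes)
            ok <- sgn * mean(acc) > 0
        }
        if (ok) {
            edge <- if (direction == "left") win[2L] else win[1L]
            snap <- positions[which.min(abs(positions - edge))]
            return(list(pos = snap, flags = character(0)))
        }
    }
}

#' Detect centromeric heterochromatin boundaries
#'
#' Starting from the physical position of the smallest polynomial-based
#' recombination rate, sliding windows (step = size, from
#' \code{\link{slidingWindowSize}}) expand the point into a region by
#' testing the mean of local growth rates of the cumulative R-squared
#' curves against zero: the left boundary search slides leftward over the
#' forward curve until the mean growth is positive, the right boundary
#' search slides rightward over the backward curve until it is negative;
#' the boundary is the window edge proximal to the start, snapped to the
#' nearest marker.  With a centromeric gap, an additional confirmation
#' requires the accumulated within-window point slopes to keep the same
#' sign.  Telocentric chromosomes use a single window moving away from the
#' centromeric side; the other centromeric limit is the chromosome end.  A
#' window reaching the chromosome end sets the boundary to that end and
#' flags it low-confidence.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param r2 an \linkS4class{R2Curves}.
#' @param chromType a \linkS4class{ChromosomeType}.
#' @param rateArgmin start position, Mb (polynomial rate minimum).
#' @param window sliding-window size, Mb.
#' @return list with \code{interval} numeric(2) and \code{flags}.
#' @export
detectCentromere <- function(map, r2, chromType, rateArgmin, window) {
    stopifnot(is(map, "MareyMap"), is(r2, "R2Curves"),
              is(chromType, "ChromosomeType"))
    p <- physPos(map)
    gapMode <- chromType@hasCentromericGap
    flags <- character(0)
    if (chromType@form == "telocentric") {
        if (chromType@centromereSide == "right") {
            b <- .searchBoundary(p, forwardR2(r2), rateArgmin, window,
                                 "left", gapMode)
            interval <- c(b$pos, p[length(p)])
        } else {
            b <- .searchBoundary(p, backwardR2(r2), rateArgmin, window,
                                 "right", gapMode)
            interval <- c(p[1L], b$pos)
        }
        flags <- b$flags
    } else {
        l <- .searchBoundary(p, forwardR2(r2), rateArgmin, window,
                             "left", gapMode)
        r <- .searchBoundary(p, backwardR2(r2), rateArgmin, window,
                             "right", gapMode)
        interval <- c(l$pos, r$pos)
        flags <- unique(c(l$flags, r$flags))
        if (interval[1L] > interval[2L]) {
            interval <- sort(interval)
            flags <- c(flags, "centromere_inverted")
        }
    }
    list(interval = interval, flags = flags)
}

#' Detect telomeric heterochromatin boundaries
#'
#' A telomere shows up as a depletion of the cumulative R-squared curve:
#' its inner boundary is the physical position of the curve's smallest
#' value on the flank outside the centromeric interval (outermost position
#' on ties).  For atelocentric chromosomes the left telomere runs from the
#' first marker to the forward-curve minimum on the left flank and the
#' right telomere from the backward-curve minimum on the right flank to the
#' last marker; a telocentric chromosome has a single telomere on the arm's
#' distal side.  An empty flank collapses the telomere to the chromosome
#' end (zero width) and flags it.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param r2 an \linkS4class{R2Curves}.
#' @param chromType a \linkS4class{ChromosomeType}.
#' @param centromeric numeric(2) centromeric interval from
#'   \code{\link{detectCentromere}}.
#' @return list with \code{telomereLeft}, \code{telomereRight} (numeric(2)
#'   or numeric(0)) and \code{flags}.
#' @export
detectTelomeres <- function(map, r2, chromType, centromeric) {
    stopifnot(is(map, "MareyMap"), is(r2, "R2Curves"))
    p <- physPos(map)
    n <- length(p)
    flags <- character(0)
    leftTel <- function() {
        flank <- which(p < centromeric[1L])
        if (!length(flank)) {
            flags <<- c(flags, "telomere_left_collapsed")
            return(c(p[1L], p[1L]))
        }
        v <- forwardR2(r2)[flank]
        hit <- which(v <= min(v) + 1e-12)       # tolerance absorbs float ties
        amin <- flank[hit[1L]]                  # outermost on ties
        if (amin == 1L) flags <<- c(flags, "telomere_left_zero_width")
        c(p[1L], p[amin])
    }
    rightTel <- function() {
        flank <- which(p > centromeric[2L])
        if (!length(flank)) {
            flags <<- c(flags, "telomere_right_collapsed")
            return(c(p[n], p[n]))
        }
        v <- backwardR2(r2)[flank]
        hit <- which(v <= min(v) + 1e-12)       # tolerance absorbs float ties
        amin <- flank[hit[length(hit)]]         # outermost on ties
        if (amin == n) flags <<- c(flags, "telomere_right_zero_width")
        c(p[amin], p[n])
    }
    if (chromType@form == "telocentric") {
        if (chromType@centromereSide == "right")
            list(telomereLeft = leftTel(), telomereRight = numeric(0),
                 flags = flags)
        else
            list(telomereLeft = numeric(0), telomereRight = rightTel(),
                 flags = flags)
    } else {
        tl <- leftTel(); tr <- rightTel()
        list(telomereLeft = tl, telomereRight = tr, flags = flags)
    }
}

#' Zero recombination rates across heterochromatin
#'
#' Evaluates the fitted derivative on a grid and adjusts it: inside any
#' heterochromatin interval (centromeric, telomeric) the rate is reset to
#' zero; outside, negative derivatives are floored at zero.
#'
#' @param fit a \linkS4class{MareyFit}.
#' @param hcb an \linkS4class{HCB}.
#' @param grid physical positions, Mb, within the fitted range.
#' @return data.frame with columns \code{phys} and \code{rate}.
#' @export
extrapolateRates <- function(fit, hcb, grid) {
    stopifnot(is(fit, "MareyFit"), is(hcb, "HCB"))
    rate <- pmax(recombinationRate(fit, grid), 0)
    intervals <- c(list(hcb@centromeric),
                   if (length(hcb@telomereLeft)) list(hcb@telomereLeft),
                   if (length(hcb@telomereRight)) list(hcb@telomereRight))
    for (iv in intervals)
        if (!any(is.na(iv)))
            rate[grid >= iv[1L] & grid <= iv[2L]] <- 0
    data.frame(phys = grid, rate = rate)
}
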