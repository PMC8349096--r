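## Step 1 and Step 3: Marey-curve regression, derivative recombination
## rates, and cumulative forward/backward R-squared curves.

.checkRange <- function(x, rng, what = "position") {
    tol <- 1e-8 * max(1, abs(rng))
    if (any(x < rng[1L] - tol) || any(x > rng[2L] + tol))
        stop("extrapolation request: ", what, "s outside fitted range [",
             signif(rng[1L], 6), ", ", signif(rng[2L], 6), "] Mb")
    pmin(pmax(x, rng[1L]), rng[2L])
}

#' Fit a third-degree polynomial Marey curve
#'
#' Least-squares cubic of genetic on physical position.  The derivative is
#' evaluated in closed form, \eqn{3 a_3 x^2 + 2 a_2 x + a_1}.
#'
#' @param map a \linkS4class{MareyMap}, at least 5 markers.
#' @return a \linkS4class{MareyFit} of kind \code{"polynomial3"}.
#' @examples
#' mm <- MareyMap(phys = 0:9, gen = 2 * (0:9))
#' fit <- fitPolynomial3(mm)
#' recombinationRate(fit, c(1, 5))   # exactly 2 cM/Mb
#' @export
fitPolynomial3 <- function(map) {
    stopifnot(is(map, "MareyMap"))
    if (nMarkers(map) < 5L) stop("need at least 5 markers for a cubic fit")
    x <- physPos(map); y <- genPos(map)
    X <- cbind(1, x, x^2, x^3)
    fit <- stats::lm.fit(X, y)
    if (fit$rank < 4L || any(!is.finite(fit$coefficients)))
        stop("rank-deficient design: cubic fit failed (degenerate ",
             "physical positions)")
    cf <- unname(fit$coefficients)
    names(cf) <- c("a0", "a1", "a2", "a3")
    rng <- range(x)
    new("MareyFit", kind = "polynomial3", span = NA_real_,
        coefficients = cf,
        predictFun = function(z) {
            z <- .checkRange(z, rng)
            unname(cf[1L] + cf[2L] * z + cf[3L] * z^2 + cf[4L] * z^3)
        },
        derivativeFun = function(z) {
            z <- .checkRange(z, rng)
            unname(cf[2L] + 2 * cf[3L] * z + 3 * cf[4L] * z^2)
        },
        range = rng)
}

#' Fit a Loess Marey curve
#'
#' Locally weighted regression of genetic on physical position.  The span
#' is the proportion of markers entering each local fit (allowed range
#' 0.05--1).  Because local regression has no closed-form derivative, the
#' recombination rate is obtained by central finite differences of
#' predictions on a dense grid of 1000 steps across the fitted range and
#' linear interpolation in between.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param span Loess span, default 0.15.
#' @param gridSteps number of grid intervals for the finite-difference
#'   derivative (default 1000).
#' @return a \linkS4class{MareyFit} of kind \code{"loess"}.
#' @export
fitLoess <- function(map, span = 0.15, gridSteps = 1000L) {
    stopifnot(is(map, "MareyMap"))
    if (span < 0.05 || span > 1)
        stop("span must lie within [0.05, 1]")
    n <- nMarkers(map)
    if (n * span < 4) {
        minSpan <- ceiling(400 / n) / 100
        stop("span too small for ", n, " markers: local fits need at ",
             "least 4 neighbours; minimum feasible span is ", minSpan)
    }
    x <- physPos(map); y <- genPos(map)
    lo <- stats::loess(y ~ x, span = span, degree = 2,
                       family = "gaussian",
                       control = stats::loess.control(surface = "direct"))
    rng <- range(x)
    predictFun <- function(z) {
        z <- .checkRange(z, rng)
        as.numeric(stats::predict(lo, newdata = data.frame(x = z)))
    }
    grid <- seq(rng[1L], rng[2L], length.out = gridSteps + 1L)
    h <- grid[2L] - grid[1L]
    pg <- predictFun(grid)
    dv <- numeric(length(grid))
    dv[1L] <- (pg[2L] - pg[1L]) / h
    dv[length(dv)] <- (pg[length(pg)] - pg[length(pg) - 1L]) / h
    inner <- 2:(length(grid) - 1L)
    dv[inner] <- (pg[inner + 1L] - pg[inner - 1L]) / (2 * h)
    dfun <- stats::approxfun(grid, dv, rule = 2L)
    new("MareyFit", kind = "loess", span = span, coefficients = numeric(0),
        predictFun = predictFun,
        derivativeFun = function(z) dfun(.checkRange(z, rng)),
        range = rng)
}

#' Predict genetic position from a fitted Marey curve
#'
#' @param fit a \linkS4class{MareyFit}.
#' @param positions physical positions, Mb, within the fitted range.
#' @return genetic positions, cM.
#' @export
predictGen <- function(fit, positions) {
    stopifnot(is(fit, "MareyFit"))
    fit@predictFun(positions)
}

#' Local recombination rate (first derivative of the Marey curve)
#'
#' Values may be negative at this stage; flooring at zero and zeroing
#' across heterochromatin happen only in \code{\link{extrapolateRates}}.
#'
#' @param fit a \linkS4class{MareyFit}.
#' @param positions physical positions, Mb, within the fitted range.
#' @return rates, cM/Mb.
#' @export
recombinationRate <- function(fit, positions) {
    stopifnot(is(fit, "MareyFit"))
    fit@derivativeFun(positions)
}

## R^2 of a cubic fit on (x, y); TSS == 0 -> 1 by convention.  x is
## centred before building the powers: R^2 is invariant and the design
## stays well conditioned on short windows.
.cubicR2 <- function(x, y) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(1)
    xc <- x - mean(x)
    fit <- stats::lm.fit(cbind(1, xc, xc^2, xc^3), y)
    1 - sum(fit$residuals^2) / tss
}

#' Cumulative goodness-of-fit curve in one direction
#'
#' Entry k of the forward curve is the coefficient of determination of a
#' cubic refitted on markers 1..k in physical order; the backward curve
#' mirrors from the chromosome end (entry k uses markers k..n).  Windows
#' with fewer than \code{minPrefix} markers carry the value of the first
#' computable window, so the two curves agree on the full data
#' (forward[n] == backward[1]).  Alternatives kept for sensitivity checks:
#' \code{refit = FALSE} scores the supplied global cubic on each prefix
#' instead of refitting, and \code{statistic = "rss"} accumulates raw
#' residual sums of squares of the global fit.
#'
#' @param map a \linkS4class{MareyMap} with at least 5 markers.
#' @param fit global cubic \linkS4class{MareyFit}; required unless
#'   refitting (the default), where it is unused.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param refit refit the cubic on every prefix (default TRUE).
#' @param statistic \code{"r2"} (default) or \code{"rss"}.
#' @param minPrefix smallest window size that is fitted (default 5).
#' @return numeric vector aligned with the sorted marker positions.
#' @export
r2Cumulative <- function(map, fit = NULL,
                         direction = c("forward", "backward"),
                         refit = TRUE, statistic = c("r2", "rss"),
                         minPrefix = 5L) {
    direction <- match.arg(direction)
    statistic <- match.arg(statistic)
    stopifnot(is(map, "MareyMap"))
    n <- nMarkers(map)
    if (n < minPrefix) stop("need at least ", minPrefix, " markers")
    x <- physPos(map); y <- genPos(map)
    if (direction == "backward") { x <- rev(x); y <- rev(y) }
    out <- rep(NA_real_, n)
    if (statistic == "rss") {
        if (is.null(fit)) stop("statistic 'rss' needs the global fit")
        res <- y - fit@predictFun(x)
        out <- cumsum(res^2)
    } else if (refit) {
        for (k in minPrefix:n)
            out[k] <- .cubicR2(x[seq_len(k)], y[seq_len(k)])
        out[seq_len(minPrefix - 1L)] <- out[minPrefix]
    } else {
        if (is.null(fit)) stop("refit = FALSE needs the global fit")
        pred <- fit@predictFun(x)
        for (k in minPrefix:n) {
            yy <- y[seq_len(k)]
            tss <- sum((yy - mean(yy))^2)
            out[k] <- if (tss == 0) 1
                      else 1 - sum((yy - pred[seq_len(k)])^2) / tss
        }
        out[seq_len(minPrefix - 1L)] <- out[minPrefix]
    }
    if (direction == "backward") out <- rev(out)
    out
}

#' Forward and backward cumulative R-squared curves
#'
#' Convenience wrapper bundling both directions of
#' \code{\link{r2Cumulative}} into an \linkS4class{R2Curves} object.
#'
#' @inheritParams r2Cumulative
#' @return an \linkS4class{R2Curves}.
#' @export
r2Curves <- function(map, fit = NULL, refit = TRUE,
                     statistic = "r2", minPrefix = 5L) {
    fwd <- r2Cumulative(map, fit, "forward", refit, statistic, minPrefix)
    bwd <- r2Cumulative(map, fit, "backward", refit, statistic, minPrefix)
    ## both full windows use all markers; kill the float summation jitter
    bwd[1L] <- fwd[length(fwd)]
    new("R2Curves", positions = physPos(map), forward = fwd,
        backward = bwd)
}
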