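## Synthetic Marey maps with known heterochromatin structure, subsampling,
## shift metrics and robustness experiments.

#' ShiftTable: per-boundary shifts with summary statistics
#'
#' @slot shifts per-boundary shift values, Mb.
#' @slot stats named numeric: min, max, mean, median (Mb).
#' @exportClass ShiftTable
setClass("ShiftTable",
    representation(shifts = "numeric", stats = "numeric"))

setValidity("ShiftTable", function(object) {
    s <- object@shifts
    st <- object@stats
    if (!all(c("min", "max", "mean", "median") %in% names(st)))
        return("stats must contain min, max, mean, median")
    ok <- isTRUE(all.equal(unname(st[c("min", "max", "mean", "median")]),
                           c(min(s), max(s), mean(s),
                             stats::median(s)), tolerance = 1e-12))
    if (!ok) return("stats inconsistent with shift values")
    TRUE
})

#' @rdname accessors
#' @export
setGeneric("shiftStats", function(x) standardGeneric("shiftStats"))
#' @rdname accessors
#' @export
setMethod("shiftStats", "ShiftTable", function(x) x@stats)
#' @rdname accessors
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))
#' @rdname accessors
#' @export
setMethod("shifts", "ShiftTable", function(x) x@shifts)

setMethod("show", "ShiftTable", function(object) {
    cat("ShiftTable over", length(object@shifts), "boundaries (Mb)\n")
    print(round(object@stats, 2))
})

#' Build a simulation scenario
#'
#' Defaults describe the two study conditions used throughout the package
#' tests: a 44-Mb metacentric chromosome (two concatenated ~22-Mb arms)
#' with a flat 4-Mb centromere at 20--24 Mb and 2-Mb telomeres, and a
#' 22-Mb telocentric arm with the centromere on the right (20--22 Mb) and
#' a single 2-Mb distal telomere.  Euchromatin carries 5 markers/Mb,
#' heterochromatin 2 markers/Mb (none in the centromere when
#' \code{hasGap}); genetic positions follow a monotone flat/logistic
#' template scaled to \code{geneticLength} plus truncated Gaussian noise.
#'
#' @param form \code{"metacentric"} or \code{"telocentric"}.
#' @param length physical length, Mb.
#' @param centromere numeric(2) centromeric interval, Mb.
#' @param telomeres list of numeric(2) telomeric intervals, Mb.
#' @param hasGap simulate a centromeric assembly gap (no markers there).
#' @param densityEu,densityHet markers/Mb in eu-/heterochromatin.
#' @param noiseSd Gaussian noise sd on genetic positions in euchromatin,
#'   cM.
#' @param hetNoiseFactor noise multiplier inside heterochromatin (default
#'   3): heterochromatic markers are of lower quality, producing the
#'   fit-quality depletion that boundary detection exploits.
#' @param geneticLength total genetic length of the template, cM.
#' @param seed integer seed used by \code{\link{simulateMap}}.
#' @return a \linkS4class{Scenario}.
#' @examples
#' mareyScenario(seed = 1L)
#' mareyScenario("telocentric", seed = 1L)
#' @export
mareyScenario <- function(form = c("metacentric", "telocentric"),
                          length = NULL, centromere = NULL,
                          telomeres = NULL, hasGap = FALSE,
                          densityEu = 5, densityHet = 2, noiseSd = 0.75,
                          hetNoiseFactor = 3, geneticLength = NULL,
                          seed = 1L) {
    form <- match.arg(form)
    if (form == "metacentric") {
        if (is.null(length)) length <- 44
        if (is.null(centromere)) centromere <- c(20, 24)
        if (is.null(telomeres))
            telomeres <- list(c(0, 2), c(length - 2, length))
        if (is.null(geneticLength)) geneticLength <- 100
    } else {
        if (is.null(length)) length <- 22
        if (is.null(centromere)) centromere <- c(length - 3, length)
        if (is.null(telomeres)) telomeres <- list(c(0, 0.7))
        if (is.null(geneticLength)) geneticLength <- 50
    }
    new("Scenario", length = length, form = form,
        centromere = as.numeric(centromere),
        telomeres = lapply(telomeres, as.numeric), hasGap = hasGap,
        densityEu = densityEu, densityHet = densityHet, noiseSd = noiseSd,
        hetNoiseFactor = hetNoiseFactor, geneticLength = geneticLength,
        seed = as.integer(seed))
}

## Non-overlapping region table: heterochromatin intervals + euchromatin
## complement, each with its marker density.
.scenarioRegions <- function(scenario) {
    het <- c(list(cen = scenario@centromere), scenario@telomeres)
    het <- het[order(vapply(het, `[`, numeric(1), 1L))]
    regions <- list()
    cur <- 0
    for (iv in het) {
        if (iv[1L] > cur)
            regions[[length(regions) + 1L]] <-
                list(iv = c(cur, iv[1L]), type = "eu")
        isCen <- isTRUE(all.equal(iv, scenario@centromere))
        regions[[length(regions) + 1L]] <-
            list(iv = iv, type = if (isCen) "cen" else "tel")
        cur <- iv[2L]
    }
    if (cur < scenario@length)
        regions[[length(regions) + 1L]] <-
            list(iv = c(cur, scenario@length), type = "eu")
    regions
}

## Monotone genetic template: zero slope inside heterochromatin, a
## logistic rise inside each euchromatin block, rises proportional to
## block widths and scaled so the template spans geneticLength cM.
.templateFun <- function(scenario, steepness = 10) {
    regions <- .scenarioRegions(scenario)
    euWidth <- sum(vapply(regions, function(r)
        if (r$type == "eu") diff(r$iv) else 0, numeric(1)))
    sig <- function(t) stats::plogis(steepness * (t - 0.5))
    s0 <- sig(0); s1 <- sig(1)
    base <- 0
    pieces <- list()
    for (r in regions) {
        if (r$type == "eu") {
            rise <- scenario@geneticLength * diff(r$iv) / euWidth
            pieces[[length(pieces) + 1L]] <-
                list(iv = r$iv, base = base, rise = rise)
            base <- base + rise
        } else {
            pieces[[length(pieces) + 1L]] <-
                list(iv = r$iv, base = base, rise = 0)
        }
    }
    function(x) {
        y <- numeric(length(x))
        for (p in pieces) {
            in_p <- x >= p$iv[1L] & x <= p$iv[2L]
            if (!any(in_p)) next
            if (p$rise == 0) y[in_p] <- p$base
            else {
                t <- (x[in_p] - p$iv[1L]) / diff(p$iv)
                y[in_p] <- p$base + p$rise * (sig(t) - s0) / (s1 - s0)
            }
        }
        y
    }
}

#' Simulate a Marey map with known heterochromatin boundaries
#'
#' Marker physical positions are drawn uniformly within each region at the
#' scenario's densities (none inside the centromere when the scenario has
#' a gap); genetic positions follow the monotone template (flat in
#' heterochromatin, logistic rise in euchromatin) plus Gaussian noise
#' truncated at 0 cM.  The generator is deterministic given the scenario
#' seed.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param chromosomeId label for the simulated chromosome.
#' @return list with \code{map} (a \linkS4class{MareyMap}), \code{truth}
#'   (an \linkS4class{HCB} holding the generating boundaries) and
#'   \code{template} (the noise-free template function).
#' @export
simulateMap <- function(scenario, chromosomeId = "sim") {
    stopifnot(is(scenario, "Scenario"))
    regions <- .scenarioRegions(scenario)
    tmpl <- .templateFun(scenario)
    phys <- withr::with_seed(scenario@seed, {
        unlist(lapply(regions, function(r) {
            dens <- switch(r$type,
                eu = scenario@densityEu,
                tel = scenario@densityHet,
                cen = if (scenario@hasGap) 0 else scenario@densityHet)
            n <- round(dens * diff(r$iv))
            if (n <= 0) numeric(0)
            else stats::runif(n, r$iv[1L], r$iv[2L])
        }))
    })
    if (length(phys) < 5L)
        stop("scenario densities too low: fewer than 5 markers")
    ## heterochromatic markers are noisier: the local fit-quality drop
    ## along the centromere and telomeres mirrors real Marey maps
    het <- c(list(scenario@centromere), scenario@telomeres)
    inHet <- Reduce(`|`, lapply(het, function(iv)
        phys >= iv[1L] & phys <= iv[2L]))
    sd <- scenario@noiseSd *
        ifelse(inHet, scenario@hetNoiseFactor, 1)
    gen <- withr::with_seed(scenario@seed + 1L,
        pmax(tmpl(phys) + stats::rnorm(length(phys), 0, sd), 0))
    map <- MareyMap(phys, gen, chromosomeId = chromosomeId)
    tels <- scenario@telomeres
    leftT <- Filter(function(iv) iv[1L] <= 0 + 1e-9, tels)
    rightT <- Filter(function(iv) iv[2L] >= scenario@length - 1e-9, tels)
    truth <- new("HCB", centromeric = scenario@centromere,
        telomereLeft = if (length(leftT)) leftT[[1L]] else numeric(0),
        telomereRight = if (length(rightT)) rightT[[1L]] else numeric(0),
        flags = character(0))
    list(map = map, truth = truth, template = tmpl)
}

#' Ground-truth internal boundaries of a scenario
#'
#' Named like \code{\link{internalBoundaries}} output so detected and true
#' boundaries can be compared elementwise.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @return named numeric of internal boundary positions, Mb.
#' @export
trueInternalBoundaries <- function(scenario) {
    stopifnot(is(scenario, "Scenario"))
    cen <- scenario@centromere
    if (scenario@form == "telocentric") {
        right <- cen[2L] >= scenario@length - 1e-9
        tel <- scenario@telomeres[[1L]]
        c(centromeric = if (right) cen[1L] else cen[2L],
          telomeric = if (right) tel[2L] else tel[1L])
    } else {
        tels <- scenario@telomeres
        c(centromeric_left = cen[1L], centromeric_right = cen[2L],
          telomere_left_end = tels[[1L]][2L],
          telomere_right_start = tels[[2L]][1L])
    }
}

#' Randomly subsample a Marey map
#'
#' Draws a uniform subset of \code{round(fraction * n)} markers without
#' replacement (deterministic given the seed) and re-sorts.
#'
#' @param map a \linkS4class{MareyMap}.
#' @param fraction proportion of markers to keep, in (0, 1].
#' @param seed integer seed.
#' @return a \linkS4class{MareyMap}.
#' @export
subsampleMap <- function(map, fraction, seed) {
    stopifnot(is(map, "MareyMap"), fraction > 0, fraction <= 1)
    n <- nMarkers(map)
    k <- round(fraction * n)
    if (k < 5L) stop("subsample would keep fewer than 5 markers")
    keep <- withr::with_seed(as.integer(seed),
                             sort(sample.int(n, k, replace = FALSE)))
    m <- markers(map)
    MareyMap(m$phys[keep], m$gen[keep], chromosomeId = chromosomeId(map))
}

#' Shift between an observed and an expected boundary
#'
#' The absolute physical distance (Mb) between a detected heterochromatin
#' boundary and its reference position.
#'
#' @param observed,expected boundary positions, Mb.
#' @return |observed - expected|, Mb.
#' @examples
#' boundaryShift(20.33, 19.95)   # 0.38
#' @export
boundaryShift <- function(observed, expected) {
    stopifnot(is.finite(observed), is.finite(expected))
    abs(observed - expected)
}

#' Summary statistics of a set of boundary shifts
#'
#' @param x numeric vector of shifts, Mb (non-empty).
#' @return a \linkS4class{ShiftTable} with min, max, arithmetic mean and
#'   median (mean of the two central order statistics for even n).
#' @examples
#' summarizeShifts(c(0.57, 0.38, 1.08, 1.89, 4.58))
#' @export
summarizeShifts <- function(x) {
    if (!length(x)) stop("no shift values supplied")
    stopifnot(is.numeric(x), all(is.finite(x)))
    new("ShiftTable", shifts = x,
        stats = c(min = min(x), max = max(x), mean = mean(x),
                  median = stats::median(x)))
}

## Per-boundary shifts of a result against a scenario's ground truth;
## falls back to nearest matching when the detected chromosome form
## differs from the scenario's.
.resultShifts <- function(result, scenario) {
    truth <- trueInternalBoundaries(scenario)
    det <- internalBoundaries(result)
    if (length(det) == length(truth) &&
        identical(names(det), names(truth)))
        return(abs(det - truth))
    vapply(truth, function(tv) min(abs(det - tv)), numeric(1))
}

#' Boundary-recovery shifts on one simulated map
#'
#' Simulates the scenario, runs \code{\link{mareyHCB}} (with the
#' chromosome form fixed to the scenario's, mirroring the a-priori type
#' confirmation) and returns the per-boundary shifts against the
#' generating truth.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param map optional pre-simulated or subsampled \code{MareyMap}
#'   replacing the scenario's own simulation.
#' @param ... passed to \code{\link{mareyHCB}}.
#' @return named numeric of shifts, Mb; the sliding-window size used is
#'   attached as \code{attr(, "windowMb")}.
#' @export
recoveryShifts <- function(scenario, map = NULL, ...) {
    if (is.null(map)) map <- simulateMap(scenario)$map
    override <- if (scenario@form == "telocentric") "telocentric"
                else "atelocentric"
    res <- mareyHCB(map, force = TRUE,
                    chromosomeTypeOverride = override, ...)
    out <- .resultShifts(res, scenario)
    attr(out, "windowMb") <- windowSize(res)
    out
}

#' Robustness of boundary detection to marker-density degradation
#'
#' For each fraction, subsamples the scenario's simulated map
#' \code{replicates} times (seeded, without replacement), reruns the full
#' pipeline, and averages the mean per-boundary shift against the
#' scenario's ground truth.  Deterministic given \code{baseSeed}.
#'
#' @param scenario a \linkS4class{Scenario}.
#' @param fractions fractions of markers to keep (default 1.0 down to 0.3
#'   by 0.1).
#' @param replicates subsample replicates per fraction (default 30).
#' @param baseSeed integer seed controlling all subsampling.
#' @param ... passed to \code{\link{mareyHCB}}.
#' @return data.frame with columns \code{fraction}, \code{meanShift} (Mb)
#'   and \code{replicates}.
#' @export
robustnessExperiment <- function(scenario,
                                 fractions = seq(1.0, 0.3, by = -0.1),
                                 replicates = 30L, baseSeed = 1L, ...) {
    stopifnot(all(fractions > 0), all(fractions <= 1))
    sim <- simulateMap(scenario)
    counter <- 0L
    rows <- lapply(fractions, function(f) {
        ms <- vapply(seq_len(replicates), function(r) {
            counter <<- counter + 1L
            seed <- as.integer(baseSeed) + 7919L * counter
            sub <- subsampleMap(sim$map, f, seed)
            mean(recoveryShifts(scenario, map = sub, ...))
        }, numeric(1))
        data.frame(fraction = f, meanShift = mean(ms),
                   replicates = replicates)
    })
    do.call(rbind, rows)
}
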