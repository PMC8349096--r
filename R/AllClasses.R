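#' @import methods
NULL

#' MareyMap: markers of one chromosome
#'
#' A Marey map pairs, for every genetic marker of one chromosome, its
#' physical position (Mb) with its genetic position (cM).  The local slope
#' of the gen-vs-phys curve is the recombination rate in cM/Mb.  Markers are
#' stored sorted by physical position; exact duplicate (phys, gen) rows are
#' dropped at construction.
#'
#' @slot chromosomeId single character label.
#' @slot markers data.frame with numeric columns \code{phys} (Mb) and
#'   \code{gen} (cM), sorted ascending by \code{phys}.
#' @slot unitOriginal unit of the physical positions in the source file,
#'   \code{"Mb"} or \code{"bp"}; positions are always held in Mb.
#'
#' @exportClass MareyMap
setClass("MareyMap",
    representation(
        chromosomeId = "character",
        markers      = "data.frame",
        unitOriginal = "character"
    ),
    prototype(
        chromosomeId = "chr",
        markers      = data.frame(phys = numeric(0), gen = numeric(0)),
        unitOriginal = "Mb"
    )
)

setValidity("MareyMap", function(object) {
    m <- object@markers
    msg <- character(0)
    if (length(object@chromosomeId) != 1L)
        msg <- c(msg, "chromosomeId must be a single string")
    if (!all(c("phys", "gen") %in% names(m)))
        msg <- c(msg, "markers must have columns 'phys' and 'gen'")
    else {
        if (nrow(m) < 2L)
            msg <- c(msg, "a Marey map needs at least 2 markers")
        if (!all(is.finite(m$phys)) || !all(is.finite(m$gen)))
            msg <- c(msg, "marker positions must be finite")
        else {
            if (any(m$phys < 0) || any(m$gen < 0))
                msg <- c(msg, "marker positions must be non-negative")
            if (is.unsorted(m$phys))
                msg <- c(msg, "markers must be sorted by physical position")
            if (anyDuplicated(m[, c("phys", "gen")]))
                msg <- c(msg, "exact duplicate (phys, gen) markers present")
        }
    }
    if (!object@unitOriginal %in% c("Mb", "bp"))
        msg <- c(msg, "unitOriginal must be 'Mb' or 'bp'")
    if (length(msg)) msg else TRUE
})

#' Construct a MareyMap
#'
#' Rows are sorted by physical position (genetic values travel with their
#' row), exact duplicate (phys, gen) pairs are dropped with a message, and
#' markers sharing a physical position but differing in genetic position are
#' kept with a warning (local regression tolerates ties).
#'
#' @param phys numeric physical positions, Mb (or bp with \code{unit="bp"}).
#' @param gen numeric genetic positions, cM.
#' @param chromosomeId chromosome label.
#' @param unit unit of \code{phys} on input: \code{"Mb"} (default) or
#'   \code{"bp"} (divided by 1e6).
#' @return a \code{MareyMap}.
#' @examples
#' mm <- MareyMap(phys = c(2, 1, 3), gen = c(4, 2, 6), chromosomeId = "2L")
#' physPos(mm)
#' @export
MareyMap <- function(phys, gen, chromosomeId = "chr", unit = c("Mb", "bp")) {
    unit <- match.arg(unit)
    stopifnot(is.numeric(phys), is.numeric(gen), length(phys) == length(gen))
    keep <- is.finite(phys) & is.finite(gen)
    phys <- as.numeric(phys[keep])
    gen  <- as.numeric(gen[keep])
    if (unit == "bp") phys <- phys / 1e6
    ord <- order(phys, gen)
    m <- data.frame(phys = phys[ord], gen = gen[ord])
    dup <- duplicated(m)
    if (any(dup)) {
        message(sum(dup), " exact duplicate marker(s) dropped on chromosome ",
                chromosomeId)
        m <- m[!dup, , drop = FALSE]
    }
    if (anyDuplicated(m$phys))
        warning("markers with equal physical but different genetic positions ",
                "kept on chromosome ", chromosomeId)
    rownames(m) <- NULL
    new("MareyMap", chromosomeId = as.character(chromosomeId)[1L],
        markers = m, unitOriginal = unit)
}

#' MareyGenome: a set of Marey maps keyed by chromosome
#'
#' @slot name genome label.
#' @slot chromosomes named list of \linkS4class{MareyMap}; names are the
#'   (unique) chromosome identifiers.
#' @exportClass MareyGenome
setClass("MareyGenome",
    representation(name = "character", chromosomes = "list"),
    prototype(name = "genome", chromosomes = list())
)

setValidity("MareyGenome", function(object) {
    msg <- character(0)
    chrs <- object@chromosomes
    if (length(chrs)) {
        if (is.null(names(chrs)) || anyDuplicated(names(chrs)))
            msg <- c(msg, "chromosome ids must be unique and named")
        if (!all(vapply(chrs, is, logical(1), "MareyMap")))
            msg <- c(msg, "all chromosomes must be MareyMap objects")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname MareyGenome-class
#' @param name genome label.
#' @param chromosomes named list of \code{MareyMap} objects.
#' @return a \code{MareyGenome}.
#' @export
MareyGenome <- function(name = "genome", chromosomes = list()) {
    if (is.null(names(chromosomes)) && length(chromosomes))
        names(chromosomes) <- vapply(chromosomes, chromosomeId, character(1))
    new("MareyGenome", name = name, chromosomes = chromosomes)
}

#' QualityReport: density and distribution diagnostics
#'
#' Output of \code{\link{runDQC}}.  \code{distributionPass} is \code{NA}
#' when the homogeneity test was inconclusive (fewer than two pooled bins).
#'
#' @slot nMarkers marker count.
#' @slot mapLength physical map length, Mb (largest physical position).
#' @slot globalDensity markers/Mb.
#' @slot densityPass logical, \code{globalDensity >= threshold}.
#' @slot chi2Stat,chi2Pvalue Pearson chi-squared homogeneity test of the
#'   1-Mb bin occupancy against the uniform expectation.
#' @slot distributionPass logical or NA.
#' @slot threshold density threshold used, markers/Mb.
#' @slot alpha significance level of the distribution test.
#' @exportClass QualityReport
setClass("QualityReport",
    representation(
        nMarkers = "integer", mapLength = "numeric",
        globalDensity = "numeric", densityPass = "logical",
        chi2Stat = "numeric", chi2Pvalue = "numeric",
        distributionPass = "logical", threshold = "numeric",
        alpha = "numeric"
    )
)

setValidity("QualityReport", function(object) {
    msg <- character(0)
    if (object@mapLength <= 0) msg <- c(msg, "mapLength must be positive")
    if (!is.na(object@chi2Pvalue) &&
        (object@chi2Pvalue < 0 || object@chi2Pvalue > 1))
        msg <- c(msg, "chi2Pvalue must lie in [0, 1]")
    if (abs(object@globalDensity - object@nMarkers / object@mapLength) >
        1e-8 * max(1, object@globalDensity))
        msg <- c(msg, "globalDensity must equal nMarkers / mapLength")
    if (length(msg)) msg else TRUE
})

#' CleanResult: outcome of one outlier-cleaning pass
#'
#' @slot cleanedMap the cleaned \linkS4class{MareyMap}.
#' @slot removed data.frame of removed markers (phys, gen, gap).
#' @slot fractionRemoved proportion of the original markers removed.
#' @slot quality \linkS4class{QualityReport} recomputed on the cleaned map.
#' @exportClass CleanResult
setClass("CleanResult",
    representation(
        cleanedMap = "MareyMap", removed = "data.frame",
        fractionRemoved = "numeric", quality = "QualityReport"
    )
)

#' MareyFit: a fitted Marey regression curve
#'
#' Either a global third-degree polynomial or a Loess local regression of
#' genetic on physical position.  \code{predictGen} evaluates the curve and
#' \code{recombinationRate} its first derivative (cM/Mb).  The polynomial
#' derivative is the closed form \eqn{3 a_3 x^2 + 2 a_2 x + a_1}; the Loess
#' derivative comes from central finite differences of predictions on a
#' dense grid.
#'
#' @slot kind \code{"polynomial3"} or \code{"loess"}.
#' @slot span Loess span (proportion of markers per local fit); \code{NA}
#'   for the polynomial.
#' @slot coefficients named numeric (a0, a1, a2, a3) for the polynomial;
#'   empty for Loess.
#' @slot predictFun function phys -> cM.
#' @slot derivativeFun function phys -> cM/Mb.
#' @slot range fitted physical range (Mb); evaluation outside errors.
#' @exportClass MareyFit
setClass("MareyFit",
    representation(
        kind = "character", span = "numeric", coefficients = "numeric",
        predictFun = "function", derivativeFun = "function",
        range = "numeric"
    )
)

setValidity("MareyFit", function(object) {
    msg <- character(0)
    if (!object@kind %in% c("polynomial3", "loess"))
        msg <- c(msg, "kind must be 'polynomial3' or 'loess'")
    if (object@kind == "polynomial3" && length(object@coefficients) != 4L)
        msg <- c(msg, "polynomial3 needs 4 coefficients (a0..a3)")
    if (length(object@range) != 2L || diff(object@range) <= 0)
        msg <- c(msg, "range must be an increasing length-2 numeric")
    if (length(msg)) msg else TRUE
})

#' R2Curves: cumulative goodness-of-fit along the chromosome
#'
#' Entry k of \code{forward} is the coefficient of determination of a cubic
#' refitted on markers 1..k (physical order); \code{backward} mirrors from
#' the chromosome end (entry k uses markers k..n).  Entries whose window
#' holds fewer than 5 markers carry the value of the first computable one,
#' so \code{forward[n] == backward[1]} (both use all markers).
#'
#' @slot positions marker physical positions, Mb.
#' @slot forward,backward numeric vectors of length n.
#' @exportClass R2Curves
setClass("R2Curves",
    representation(positions = "numeric", forward = "numeric",
                   backward = "numeric")
)

setValidity("R2Curves", function(object) {
    msg <- character(0)
    n <- length(object@positions)
    if (length(object@forward) != n || length(object@backward) != n)
        msg <- c(msg, "forward/backward must align with positions")
    if (n && abs(object@forward[n] - object@backward[1L]) > 1e-9)
        msg <- c(msg, "forward[n] must equal backward[1] (full-data fit)")
    if (length(msg)) msg else TRUE
})

#' ChromosomeType: centromere placement class of a chromosome
#'
#' Telocentric chromosomes (single arms) have the centromere at one end;
#' atelocentric chromosomes have it in the interior and are subtyped
#' metacentric when the lowest recombination rate falls within 40--60% of
#' the physical length.
#'
#' @slot form \code{"telocentric"} or \code{"atelocentric"}.
#' @slot subtype \code{"metacentric"}, \code{"not_metacentric"} or
#'   \code{"undetermined"}; only meaningful for atelocentric chromosomes.
#' @slot centromereSide \code{"left"}, \code{"right"} or \code{"interior"}.
#' @slot hasCentromericGap logical.
#' @slot gapInterval numeric(2) (Mb) when a centromeric gap was called,
#'   numeric(0) otherwise.
#' @exportClass ChromosomeType
setClass("ChromosomeType",
    representation(
        form = "character", subtype = "character",
        centromereSide = "character", hasCentromericGap = "logical",
        gapInterval = "numeric"
    ),
    prototype(form = "atelocentric", subtype = "undetermined",
              centromereSide = "interior", hasCentromericGap = FALSE,
              gapInterval = numeric(0))
)

setValidity("ChromosomeType", function(object) {
    msg <- character(0)
    if (!object@form %in% c("telocentric", "atelocentric"))
        msg <- c(msg, "form must be telocentric or atelocentric")
    if (!object@subtype %in% c("metacentric", "not_metacentric",
                               "undetermined", "none"))
        msg <- c(msg, "invalid subtype")
    if (object@form == "telocentric" &&
        !object@centromereSide %in% c("left", "right"))
        msg <- c(msg, "telocentric chromosomes have centromereSide left/right")
    if (!length(object@gapInterval) %in% c(0L, 2L))
        msg <- c(msg, "gapInterval must be numeric(0) or numeric(2)")
    if (length(msg)) msg else TRUE
})

#' HCB: heterochromatin boundary intervals
#'
#' Internal boundaries separate euchromatin from the centromeric and
#' telomeric heterochromatin; external boundaries are the first and last
#' marker positions.  Telomere slots are numeric(0) when absent (telocentric
#' chromosomes have a single telomere).
#'
#' @slot centromeric numeric(2), left/right centromeric boundary (Mb).
#' @slot telomereLeft,telomereRight numeric(2) (start, end) or numeric(0).
#' @slot flags character vector of quality flags (e.g. low-confidence
#'   boundaries that hit a chromosome end).
#' @exportClass HCB
setClass("HCB",
    representation(centromeric = "numeric", telomereLeft = "numeric",
                   telomereRight = "numeric", flags = "character"),
    prototype(centromeric = c(NA_real_, NA_real_),
              telomereLeft = numeric(0), telomereRight = numeric(0),
              flags = character(0))
)

setValidity("HCB", function(object) {
    msg <- character(0)
    chk <- function(x, nm) {
        if (!length(x)) return(character(0))
        if (length(x) != 2L) return(paste(nm, "must be numeric(0) or (2)"))
        if (!any(is.na(x)) && x[1L] > x[2L])
            return(paste(nm, "interval must satisfy left <= right"))
        character(0)
    }
    msg <- c(msg, chk(object@centromeric, "centromeric"),
             chk(object@telomereLeft, "telomereLeft"),
             chk(object@telomereRight, "telomereRight"))
    if (length(msg)) msg else TRUE
})

#' HcbResult: full result of the boundary + recombination-rate pipeline
#'
#' @slot mapUsed the \linkS4class{MareyMap} actually analysed
#'   (post-cleaning).
#' @slot quality \linkS4class{QualityReport} of \code{mapUsed}.
#' @slot chromType \linkS4class{ChromosomeType}.
#' @slot hcb \linkS4class{HCB}.
#' @slot rateGrid data.frame (phys, rate): final Loess-based recombination
#'   map, zeroed inside heterochromatin, floored at 0 elsewhere.
#' @slot rawRateGrid data.frame (phys, rate): unadjusted derivative.
#' @slot windowMb sliding-window size used for boundary detection, Mb.
#' @slot span Loess span used for the final rate map.
#' @exportClass HcbResult
setClass("HcbResult",
    representation(
        mapUsed = "MareyMap", quality = "QualityReport",
        chromType = "ChromosomeType", hcb = "HCB",
        rateGrid = "data.frame", rawRateGrid = "data.frame",
        windowMb = "numeric", span = "numeric"
    )
)

setValidity("HcbResult", function(object) {
    msg <- character(0)
    g <- object@rateGrid
    if (!all(c("phys", "rate") %in% names(g)))
        msg <- c(msg, "rateGrid needs columns phys and rate")
    else if (nrow(g) && any(g$rate < 0))
        msg <- c(msg, "final rates must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Scenario: parameters of a synthetic Marey map
#'
#' Describes one simulated chromosome: physical length, heterochromatin
#' layout (centromere and telomere intervals, optional centromeric assembly
#' gap), per-region marker densities, the genetic length of the monotone
#' template, and the noise level.
#'
#' @slot length physical length, Mb.
#' @slot form \code{"metacentric"}, \code{"submetacentric"} or
#'   \code{"telocentric"}.
#' @slot centromere numeric(2) (Mb).
#' @slot telomeres list of numeric(2) intervals (Mb).
#' @slot hasGap logical; when TRUE no markers are placed in the centromere.
#' @slot densityEu,densityHet markers/Mb in euchromatin / heterochromatin.
#' @slot noiseSd Gaussian noise on genetic positions in euchromatin, cM.
#' @slot hetNoiseFactor multiplier on \code{noiseSd} inside
#'   heterochromatin; markers there are of visibly lower quality, which is
#'   the fit-depletion signal boundary detection reads.
#' @slot geneticLength total genetic length of the template, cM.
#' @slot seed integer RNG seed.
#' @exportClass Scenario
setClass("Scenario",
    representation(
        length = "numeric", form = "character", centromere = "numeric",
        telomeres = "list", hasGap = "logical", densityEu = "numeric",
        densityHet = "numeric", noiseSd = "numeric",
        hetNoiseFactor = "numeric", geneticLength = "numeric",
        seed = "integer"
    )
)

setValidity("Scenario", function(object) {
    msg <- character(0)
    iv <- c(list(object@centromere), object@telomeres)
    for (x in iv) {
        if (length(x) != 2L || x[1L] > x[2L] ||
            x[1L] < 0 || x[2L] > object@length)
            msg <- c(msg, "intervals must lie within [0, length]")
    }
    if (object@densityEu < 0 || object@densityHet < 0)
        msg <- c(msg, "densities must be non-negative")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (object@hetNoiseFactor < 1)
        msg <- c(msg, "hetNoiseFactor must be at least 1")
    if (length(msg)) msg else TRUE
})
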