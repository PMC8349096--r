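#' Accessors for MareyHCB classes
#'
#' Small accessor generics: slot access is never done directly by user
#' code.
#'
#' @param x an object from this package.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setMethod("markers", "MareyMap", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("chromosomeId", function(x) standardGeneric("chromosomeId"))
#' @rdname accessors
#' @export
setMethod("chromosomeId", "MareyMap", function(x) x@chromosomeId)

#' @rdname accessors
#' @export
setGeneric("physPos", function(x) standardGeneric("physPos"))
#' @rdname accessors
#' @export
setMethod("physPos", "MareyMap", function(x) x@markers$phys)

#' @rdname accessors
#' @export
setGeneric("genPos", function(x) standardGeneric("genPos"))
#' @rdname accessors
#' @export
setMethod("genPos", "MareyMap", function(x) x@markers$gen)

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setMethod("nMarkers", "MareyMap", function(x) nrow(x@markers))

#' @rdname accessors
#' @export
setGeneric("mapLength", function(x) standardGeneric("mapLength"))

#' Physical map length (largest physical position, Mb)
#' @rdname accessors
#' @export
setMethod("mapLength", "MareyMap", function(x) max(x@markers$phys))

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setMethod("chromosomes", "MareyGenome", function(x) x@chromosomes)

#' @rdname accessors
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))
#' @rdname accessors
#' @export
setMethod("genomeName", "MareyGenome", function(x) x@name)

#' Extract one chromosome's MareyMap from a MareyGenome
#' @param x a \code{MareyGenome}.
#' @param i chromosome id or index.
#' @param j,... unused.
#' @param drop unused.
#' @export
setMethod("[[", "MareyGenome", function(x, i, j, ...) x@chromosomes[[i]])

#' @rdname accessors
#' @export
setMethod("length", "MareyGenome", function(x) length(x@chromosomes))

#' @rdname accessors
#' @export
setGeneric("cleanedMap", function(x) standardGeneric("cleanedMap"))
#' @rdname accessors
#' @export
setMethod("cleanedMap", "CleanResult", function(x) x@cleanedMap)

#' @rdname accessors
#' @export
setGeneric("removedMarkers", function(x) standardGeneric("removedMarkers"))
#' @rdname accessors
#' @export
setMethod("removedMarkers", "CleanResult", function(x) x@removed)

#' @rdname accessors
#' @export
setGeneric("fractionRemoved", function(x) standardGeneric("fractionRemoved"))
#' @rdname accessors
#' @export
setMethod("fractionRemoved", "CleanResult", function(x) x@fractionRemoved)

#' @rdname accessors
#' @export
setGeneric("quality", function(x) standardGeneric("quality"))
#' @rdname accessors
#' @export
setMethod("quality", "CleanResult", function(x) x@quality)
#' @rdname accessors
#' @export
setMethod("quality", "HcbResult", function(x) x@quality)

#' @rdname accessors
#' @export
setGeneric("densityPass", function(x) standardGeneric("densityPass"))
#' @rdname accessors
#' @export
setMethod("densityPass", "QualityReport", function(x) x@densityPass)

#' @rdname accessors
#' @export
setGeneric("distributionPass", function(x) standardGeneric("distributionPass"))
#' @rdname accessors
#' @export
setMethod("distributionPass", "QualityReport", function(x) x@distributionPass)

#' @rdname accessors
#' @export
setGeneric("dqcPass", function(x) standardGeneric("dqcPass"))

#' Overall DQC verdict: density pass and distribution not rejected
#' @rdname accessors
#' @export
setMethod("dqcPass", "QualityReport", function(x)
    isTRUE(x@densityPass) && !isFALSE(x@distributionPass))

#' @rdname accessors
#' @export
setGeneric("fitKind", function(x) standardGeneric("fitKind"))
#' @rdname accessors
#' @export
setMethod("fitKind", "MareyFit", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("coef", "MareyFit", function(object, ...) object@coefficients)

#' @rdname accessors
#' @export
setGeneric("fitRange", function(x) standardGeneric("fitRange"))
#' @rdname accessors
#' @export
setMethod("fitRange", "MareyFit", function(x) x@range)

#' @rdname accessors
#' @export
setGeneric("forwardR2", function(x) standardGeneric("forwardR2"))
#' @rdname accessors
#' @export
setMethod("forwardR2", "R2Curves", function(x) x@forward)

#' @rdname accessors
#' @export
setGeneric("backwardR2", function(x) standardGeneric("backwardR2"))
#' @rdname accessors
#' @export
setMethod("backwardR2", "R2Curves", function(x) x@backward)

#' @rdname accessors
#' @export
setMethod("physPos", "R2Curves", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("chromosomeType", function(x) standardGeneric("chromosomeType"))
#' @rdname accessors
#' @export
setMethod("chromosomeType", "HcbResult", function(x) x@chromType)

#' @rdname accessors
#' @export
setGeneric("hcb", function(x) standardGeneric("hcb"))
#' @rdname accessors
#' @export
setMethod("hcb", "HcbResult", function(x) x@hcb)

#' @rdname accessors
#' @export
setGeneric("centromericBoundaries",
           function(x) standardGeneric("centromericBoundaries"))
#' @rdname accessors
#' @export
setMethod("centromericBoundaries", "HCB", function(x) x@centromeric)
#' @rdname accessors
#' @export
setMethod("centromericBoundaries", "HcbResult",
          function(x) x@hcb@centromeric)

#' @rdname accessors
#' @export
setGeneric("telomericIntervals",
           function(x) standardGeneric("telomericIntervals"))

#' Telomeric heterochromatin intervals (list, possibly length 1)
#' @rdname accessors
#' @export
setMethod("telomericIntervals", "HCB", function(x) {
    out <- list()
    if (length(x@telomereLeft))  out$left  <- x@telomereLeft
    if (length(x@telomereRight)) out$right <- x@telomereRight
    out
})
#' @rdname accessors
#' @export
setMethod("telomericIntervals", "HcbResult",
          function(x) telomericIntervals(x@hcb))

#' @rdname accessors
#' @export
setGeneric("internalBoundaries",
           function(x) standardGeneric("internalBoundaries"))

#' Internal heterochromatin boundaries
#'
#' The internal boundaries exclude chromosome ends: a telocentric
#' chromosome carries 2 (one centromeric, one telomeric), an atelocentric
#' one carries 4 (two centromeric, the inner edge of each telomere).
#' @rdname accessors
#' @export
setMethod("internalBoundaries", "HcbResult", function(x) {
    h <- x@hcb
    if (x@chromType@form == "telocentric") {
        cb <- if (x@chromType@centromereSide == "right")
            h@centromeric[1L] else h@centromeric[2L]
        tb <- if (length(h@telomereLeft)) h@telomereLeft[2L]
              else h@telomereRight[1L]
        c(centromeric = cb, telomeric = tb)
    } else {
        c(centromeric_left = h@centromeric[1L],
          centromeric_right = h@centromeric[2L],
          telomere_left_end = h@telomereLeft[2L],
          telomere_right_start = h@telomereRight[1L])
    }
})

#' @rdname accessors
#' @export
setGeneric("rateGrid", function(x) standardGeneric("rateGrid"))
#' @rdname accessors
#' @export
setMethod("rateGrid", "HcbResult", function(x) x@rateGrid)

#' @rdname accessors
#' @export
setGeneric("rawRateGrid", function(x) standardGeneric("rawRateGrid"))
#' @rdname accessors
#' @export
setMethod("rawRateGrid", "HcbResult", function(x) x@rawRateGrid)

#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname accessors
#' @export
setMethod("windowSize", "HcbResult", function(x) x@windowMb)

#' @rdname accessors
#' @export
setGeneric("mapUsed", function(x) standardGeneric("mapUsed"))
#' @rdname accessors
#' @export
setMethod("mapUsed", "HcbResult", function(x) x@mapUsed)

## show methods -------------------------------------------------------------

setMethod("show", "MareyMap", function(object) {
    m <- object@markers
    cat("MareyMap of chromosome", object@chromosomeId, "\n")
    cat(" ", nrow(m), "markers,",
        sprintf("%.2f", max(m$phys)), "Mb,",
        sprintf("%.2f", max(m$gen)), "cM\n")
})

setMethod("show", "MareyGenome", function(object) {
    cat("MareyGenome", object@name, "with", length(object@chromosomes),
        "chromosome(s):", paste(names(object@chromosomes), collapse = ", "),
        "\n")
})

setMethod("show", "QualityReport", function(object) {
    cat("Marey map quality report\n")
    cat(sprintf("  markers: %d   map length: %.2f Mb   density: %.2f /Mb (threshold %.2f): %s\n",
        object@nMarkers, object@mapLength, object@globalDensity,
        object@threshold, if (object@densityPass) "PASS" else "FAIL"))
    dp <- if (is.na(object@distributionPass)) "inconclusive"
          else if (object@distributionPass) "PASS" else "FAIL"
    cat(sprintf("  distribution: chi2 = %.3f, p = %.4g: %s\n",
        object@chi2Stat, object@chi2Pvalue, dp))
})

setMethod("show", "MareyFit", function(object) {
    cat("MareyFit (", object@kind, ")", sep = "")
    if (object@kind == "loess") cat(", span =", object@span)
    cat(", range [", sprintf("%.2f", object@range[1L]), ",",
        sprintf("%.2f", object@range[2L]), "] Mb\n")
    if (object@kind == "polynomial3")
        cat("  coefficients (a0..a3):",
            paste(signif(object@coefficients, 4), collapse = ", "), "\n")
})

setMethod("show", "ChromosomeType", function(object) {
    cat("ChromosomeType:", object@form)
    if (object@form == "atelocentric") cat(" /", object@subtype)
    cat(" (centromere", object@centromereSide, ")")
    if (object@hasCentromericGap)
        cat(sprintf(", centromeric gap [%.2f, %.2f] Mb",
            object@gapInterval[1L], object@gapInterval[2L]))
    cat("\n")
})

setMethod("show", "HCB", function(object) {
    cat("Heterochromatin boundaries (Mb)\n")
    cat(sprintf("  centromeric: [%.3f, %.3f]\n",
        object@centromeric[1L], object@centromeric[2L]))
    if (length(object@telomereLeft))
        cat(sprintf("  left telomere: [%.3f, %.3f]\n",
            object@telomereLeft[1L], object@telomereLeft[2L]))
    if (length(object@telomereRight))
        cat(sprintf("  right telomere: [%.3f, %.3f]\n",
            object@telomereRight[1L], object@telomereRight[2L]))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "HcbResult", function(object) {
    cat("MareyHCB result for chromosome",
        object@mapUsed@chromosomeId, "\n")
    show(object@chromType)
    show(object@hcb)
    cat(sprintf("  sliding window: %.3f Mb; Loess span: %.2f; rate grid: %d points\n",
        object@windowMb, object@span, nrow(object@rateGrid)))
})

setMethod("show", "Scenario", function(object) {
    cat("Scenario:", object@form, sprintf("%.1f Mb", object@length),
        sprintf("centromere [%.1f, %.1f]%s",
                object@centromere[1L], object@centromere[2L],
                if (object@hasGap) " (gap)" else ""), "\n")
    cat(sprintf("  densities eu/het %.1f/%.1f per Mb, noise %.2f cM, %.1f cM total, seed %d\n",
        object@densityEu, object@densityHet, object@noiseSd,
        object@geneticLength, object@seed))
})
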