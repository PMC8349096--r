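#' Published D. melanogaster R5 boundary comparison table
#'
#' Cytologically derived reference heterochromatin boundaries and the
#' boundaries detected by the Marey-map method on the five chromosomal
#' arms (X, 2L, 2R, 3L, 3R) of the fruit-fly Release 5 genome, one
#' centromeric and one telomeric internal boundary per arm, all in Mb.
#' Used to exercise the shift arithmetic
#' (\code{\link{boundaryShift}}, \code{\link{summarizeShifts}}).
#'
#' @return data.frame with columns \code{arm},
#'   \code{centromeric_reference}, \code{centromeric_detected},
#'   \code{telomeric_reference}, \code{telomeric_detected}.
#' @examples
#' tab <- dmelReferenceBoundaries()
#' summarizeShifts(boundaryShift(tab$centromeric_detected,
#'                               tab$centromeric_reference))
#' @export
dmelReferenceBoundaries <- function() {
    utils::read.csv(system.file("extdata",
                                "dmel_r5_reference_boundaries.csv",
                                package = "MareyHCB"))
}
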