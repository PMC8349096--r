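## Static visualisation of a pipeline result.

#' Plot a Marey map with its fitted curve, rates and heterochromatin
#'
#' Overlays the marker scatter (cM, left axis), the Loess Marey curve, the
#' final adjusted recombination-rate curve (cM/Mb, rescaled to the same
#' axis) and shaded heterochromatin intervals.  Zero-width telomeres are
#' simply not drawn.
#'
#' @param result an \linkS4class{HcbResult}.
#' @param map optional \code{MareyMap}; defaults to the map inside the
#'   result.  Supplying a different chromosome is an error.
#' @return a ggplot object.
#' @export
plotResult <- function(result, map = NULL) {
    stopifnot(is(result, "HcbResult"))
    if (is.null(map)) map <- mapUsed(result)
    if (chromosomeId(map) != chromosomeId(mapUsed(result)))
        stop("map chromosome '", chromosomeId(map),
             "' does not match result chromosome '",
             chromosomeId(mapUsed(result)), "'")
    pts <- markers(map)
    fit <- fitLoess(map, span = result@span)
    grid <- rateGrid(result)
    curve <- data.frame(phys = grid$phys, gen = predictGen(fit, grid$phys))
    maxGen <- max(pts$gen)
    maxRate <- max(grid$rate, 1e-9)
    rates <- data.frame(phys = grid$phys,
                        scaled = grid$rate / maxRate * maxGen)
    h <- hcb(result)
    bands <- Filter(function(iv) length(iv) == 2L && iv[2L] > iv[1L],
                    c(list(h@centromeric), telomericIntervals(h)))
    gg <- ggplot2::ggplot()
    for (iv in bands)
        gg <- gg + ggplot2::annotate("rect", xmin = iv[1L], xmax = iv[2L],
                                     ymin = -Inf, ymax = Inf,
                                     fill = "gold", alpha = 0.3)
    gg +
        ggplot2::geom_point(data = pts,
                            ggplot2::aes(x = phys, y = gen),
                            size = 0.8, colour = "grey30") +
        ggplot2::geom_line(data = curve,
                           ggplot2::aes(x = phys, y = gen),
                           colour = "steelblue") +
        ggplot2::geom_line(data = rates,
                           ggplot2::aes(x = phys, y = scaled),
                           colour = "firebrick") +
        ggplot2::scale_y_continuous(
            name = "genetic position (cM)",
            sec.axis = ggplot2::sec_axis(~ . * maxRate / maxGen,
                                         name = "recombination rate (cM/Mb)")) +
        ggplot2::labs(x = "physical position (Mb)",
                      title = paste0("Chromosome ",
                                     chromosomeId(mapUsed(result)),
                                     ": Marey map and heterochromatin")) +
        ggplot2::theme_minimal()
}

#' Plot from files written by writeResults
#'
#' Rebuilds the overlay figure from a result CSV/JSON pair and the
#' matching Marey-map CSV, without rerunning the pipeline: markers from
#' the map file, the Loess curve refitted at the recorded span, the
#' adjusted rate curve from the result CSV, and heterochromatin bands
#' from the sidecar.
#'
#' @param resultCsv path given to \code{\link{writeResults}}.
#' @param mapCsv 3-column Marey CSV of the same chromosome.
#' @param separator separator of \code{mapCsv}.
#' @return a ggplot object.
#' @export
plotResultFiles <- function(resultCsv, mapCsv, separator = "tab") {
    back <- readResults(resultCsv)
    g <- readMareyCsv(mapCsv, separator = separator)
    id <- back$meta$chromosome
    if (!id %in% names(chromosomes(g)))
        stop("chromosome '", id, "' of the result is not in ", mapCsv)
    map <- g[[id]]
    pts <- markers(map)
    fit <- fitLoess(map, span = back$meta$span)
    curve <- data.frame(phys = back$rates$phys_mb,
                        gen = predictGen(fit, back$rates$phys_mb))
    maxGen <- max(pts$gen)
    maxRate <- max(back$rates$rate_cM_per_Mb, 1e-9)
    rates <- data.frame(phys = back$rates$phys_mb,
                        scaled = back$rates$rate_cM_per_Mb / maxRate * maxGen)
    bounds <- back$meta$boundaries
    bands <- c(list(unlist(bounds$centromere)),
               if (is.matrix(bounds$telomeres))
                   split(bounds$telomeres, seq_len(nrow(bounds$telomeres)))
               else bounds$telomeres)
    bands <- Filter(function(iv) length(iv) == 2L && iv[2L] > iv[1L], bands)
    gg <- ggplot2::ggplot()
    for (iv in bands)
        gg <- gg + ggplot2::annotate("rect", xmin = iv[1L], xmax = iv[2L],
                                     ymin = -Inf, ymax = Inf,
                                     fill = "gold", alpha = 0.3)
    gg +
        ggplot2::geom_point(data = pts, ggplot2::aes(x = phys, y = gen),
                            size = 0.8, colour = "grey30") +
        ggplot2::geom_line(data = curve, ggplot2::aes(x = phys, y = gen),
                           colour = "steelblue") +
        ggplot2::geom_line(data = rates,
                           ggplot2::aes(x = phys, y = scaled),
                           colour = "firebrick") +
        ggplot2::scale_y_continuous(
            name = "genetic position (cM)",
            sec.axis = ggplot2::sec_axis(~ . * maxRate / maxGen,
                                         name = "recombination rate (cM/Mb)")) +
        ggplot2::labs(x = "physical position (Mb)",
                      title = paste("Chromosome", id)) +
        ggplot2::theme_minimal()
}
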