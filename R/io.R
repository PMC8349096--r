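## CSV input and result export.

.SEPARATORS <- c(comma = ",", semicolon = ";", tab = "\t")

.matchColumns <- function(nms) {
    low <- tolower(trimws(nms))
    hit <- function(pats) {
        i <- which(vapply(low, function(x)
            any(vapply(pats, function(p) grepl(p, x), logical(1))),
            logical(1)))
        if (length(i)) i[1L] else NA_integer_
    }
    chr  <- hit(c("^chr", "chromosome"))
    phys <- hit(c("^mb$", "phys", "physical"))
    gen  <- hit(c("^cm$", "^gen", "genetic"))
    list(chr = chr, phys = phys, gen = gen,
        complete = !is.na(phys) && !is.na(gen))
}

#' Read a Marey map CSV into a MareyGenome
#'
#' Expects a header row and at least two columns holding genetic (cM) and
#' physical (Mb or bp) marker positions; a chromosome-identifier column is
#' required only for multi-chromosome files.  Columns are located by
#' case-insensitive header match ({chr, chromosome}, {mb, phys, physical},
#' {cm, gen, genetic}); if the headers match nothing, the positional order
#' (chromosome id, genetic, physical) is assumed.  Rows with missing or
#' non-numeric positions are dropped and counted in the load report
#' attached as \code{attr(x, "loadReport")}.
#'
#' @param path CSV file path.
#' @param separator one of \code{"comma"}, \code{"semicolon"}, \code{"tab"}.
#' @param physicalUnit \code{"Mb"} (default) or \code{"bp"} (divided by
#'   1e6 on load).
#' @param genomeName label for the returned \linkS4class{MareyGenome}.
#' @return a \code{MareyGenome}; each chromosome's markers are sorted by
#'   physical position.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(chr = "2L", cM = c(0, 5, 9), Mb = c(0, 2, 4)),
#'           f, row.names = FALSE)
#' g <- readMareyCsv(f, separator = "comma")
#' g[["2L"]]
#' @export
readMareyCsv <- function(path, separator = c("tab", "comma", "semicolon"),
                         physicalUnit = c("Mb", "bp"),
                         genomeName = NULL) {
    if (is.character(separator) && length(separator) == 1L &&
        !separator %in% names(.SEPARATORS))
        stop("unknown separator '", separator,
             "': use 'comma', 'semicolon' or 'tab'")
    separator <- match.arg(separator)
    physicalUnit <- match.arg(physicalUnit)
    if (!file.exists(path)) stop("cannot read file: ", path)
    raw <- utils::read.table(path, header = TRUE,
                             sep = .SEPARATORS[[separator]],
                             stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "")
    if (!ncol(raw) >= 2L) stop("need at least 2 columns in ", path)
    cols <- .matchColumns(names(raw))
    if (!cols$complete) {
        ## positional fallback: (id, gen, phys) or (gen, phys)
        if (ncol(raw) >= 3L) cols <- list(chr = 1L, phys = 3L, gen = 2L)
        else cols <- list(chr = NA_integer_, phys = 2L, gen = 1L)
    }
    chr <- if (is.na(cols$chr)) rep("chr", nrow(raw))
           else as.character(raw[[cols$chr]])
    phys <- suppressWarnings(as.numeric(raw[[cols$phys]]))
    gen  <- suppressWarnings(as.numeric(raw[[cols$gen]]))
    bad <- !is.finite(phys) | !is.finite(gen)
    nDropped <- sum(bad)
    if (nDropped)
        message(nDropped, " row(s) with missing/non-numeric positions dropped")
    keep <- !bad
    chr <- chr[keep]; phys <- phys[keep]; gen <- gen[keep]
    maps <- list()
    for (id in unique(chr)) {
        sel <- chr == id
        if (sum(sel) < 2L) next
        maps[[id]] <- MareyMap(phys[sel], gen[sel], chromosomeId = id,
                               unit = physicalUnit)
    }
    if (!length(maps))
        stop("no chromosome in ", path, " has at least 2 valid markers")
    if (is.null(genomeName))
        genomeName <- sub("\\.[^.]*$", "", basename(path))
    g <- MareyGenome(name = genomeName, chromosomes = maps)
    attr(g, "loadReport") <- list(nRows = nrow(raw), nDropped = nDropped,
                                  nChromosomes = length(maps))
    g
}

.hcbToList <- function(result) {
    ct <- result@chromType
    h <- result@hcb
    q <- result@quality
    tels <- telomericIntervals(h)
    list(
        chromosome = chromosomeId(result@mapUsed),
        type = ct@form,
        subtype = ct@subtype,
        centromere_side = ct@centromereSide,
        gap = ct@hasCentromericGap,
        gap_interval = if (length(ct@gapInterval)) ct@gapInterval else NULL,
        boundaries = list(
            centromere = h@centromeric,
            telomeres = unname(tels)
        ),
        flags = h@flags,
        window_mb = result@windowMb,
        span = result@span,
        quality = list(
            n_markers = q@nMarkers, map_length_mb = q@mapLength,
            global_density = q@globalDensity, density_pass = q@densityPass,
            chi2_stat = q@chi2Stat, chi2_pvalue = q@chi2Pvalue,
            distribution_pass = q@distributionPass, threshold = q@threshold
        )
    )
}

#' Write an HcbResult to disk
#'
#' Writes the final recombination-rate grid as a two-column CSV
#' (\code{phys_mb}, \code{rate_cM_per_Mb}) and a JSON sidecar (same path,
#' \code{.json} extension) holding the chromosome type, boundary positions,
#' sliding-window size, span and the quality report.
#'
#' @param result an \linkS4class{HcbResult}.
#' @param path output CSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @return invisibly, a character vector of the two files written.
#' @seealso \code{\link{readResults}} for the round-trip reader.
#' @export
writeResults <- function(result, path) {
    stopifnot(is(result, "HcbResult"))
    g <- result@rateGrid
    out <- data.frame(phys_mb = g$phys, rate_cM_per_Mb = g$rate)
    tryCatch(utils::write.csv(out, path, row.names = FALSE),
             error = function(e) stop("cannot write to ", path, ": ",
                                      conditionMessage(e)))
    jsonPath <- paste0(sub("\\.[^.]*$", "", path), ".json")
    jsonlite::write_json(.hcbToList(result), jsonPath,
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(c(csv = path, json = jsonPath))
}

#' Read back files produced by writeResults
#'
#' @param path the CSV path given to \code{\link{writeResults}}.
#' @return list with \code{rates} (data.frame phys_mb, rate_cM_per_Mb) and
#'   \code{meta} (the parsed JSON sidecar).
#' @export
readResults <- function(path) {
    rates <- utils::read.csv(path)
    jsonPath <- paste0(sub("\\.[^.]*$", "", path), ".json")
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    list(rates = rates, meta = meta)
}

#' Write a MareyMap (or MareyGenome) as a standard 3-column CSV
#'
#' Column order follows the conventional layout: chromosome identifier,
#' genetic distance (cM), physical distance (Mb).
#'
#' @param x a \code{MareyMap} or \code{MareyGenome}.
#' @param path output CSV path.
#' @param separator field separator name, as in \code{\link{readMareyCsv}}.
#' @return invisibly, \code{path}.
#' @export
writeMareyCsv <- function(x, path, separator = "tab") {
    if (!separator %in% names(.SEPARATORS))
        stop("unknown separator '", separator, "'")
    maps <- if (is(x, "MareyGenome")) chromosomes(x) else list(x)
    df <- do.call(rbind, lapply(maps, function(mm)
        data.frame(chr = chromosomeId(mm), cM = genPos(mm),
                   Mb = physPos(mm))))
    utils::write.table(df, path, sep = .SEPARATORS[[separator]],
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}
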