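## Plain-text interchange for spectra: two-column delimited tables
## (index, count) with a JSON metadata sidecar.

.spectrumIndexName <- function(x) {
    switch(class(x),
        SiteFrequencySpectrum = "k",
        BurdenDistribution = "j",
        DivisionalDistribution = "l",
        CloneSizeDistribution = "kappa",
        VAFSpectrum = "allele_index",
        "index")
}

#' Write a spectrum as delimited text with a JSON sidecar
#'
#' The table holds the occupied classes as two tab-separated columns
#' (index, count); the sidecar \code{<file>.json} records the class, the
#' population size and any metadata, so the spectrum round-trips through
#' [readSpectrum()].
#'
#' @param x a \code{Spectrum} subclass.
#' @param file output path for the table.
#' @return \code{file}, invisibly.
#' @export
writeSpectrum <- function(x, file) {
    stopifnot(is(x, "Spectrum"))
    idx <- spectrumIndex(x)
    keep <- x@counts != 0
    df <- data.frame(index = idx[keep], count = x@counts[keep])
    names(df)[1] <- .spectrumIndexName(x)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- list(class = class(x)[1], popSize = x@popSize,
                 minIndex = x@minIndex, length = length(x@counts),
                 metadata = x@metadata)
    if (is(x, "VAFSpectrum")) meta$nCells <- x@nCells
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(file)
}

#' Read a spectrum written by [writeSpectrum()]
#'
#' @param file path of the table; the sidecar \code{<file>.json} must sit
#'   next to it.
#' @return the reconstructed \code{Spectrum} subclass.
#' @export
readSpectrum <- function(file) {
    sidecar <- paste0(file, ".json")
    if (!file.exists(sidecar)) stop("missing metadata sidecar ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    df <- utils::read.table(file, header = TRUE, sep = "\t")
    counts <- numeric(meta$length)
    pos <- df[[1]] - meta$minIndex + 1
    counts[pos] <- df[[2]]
    md <- as.list(meta$metadata)
    switch(meta$class,
        SiteFrequencySpectrum =
            siteFrequencySpectrum(counts, meta$popSize, metadata = md),
        BurdenDistribution =
            burdenDistribution(counts, meta$popSize, metadata = md),
        DivisionalDistribution =
            divisionalDistribution(counts, meta$popSize, metadata = md),
        CloneSizeDistribution =
            cloneSizeDistribution(counts, meta$popSize, metadata = md),
        VAFSpectrum = vafSpectrum(counts, meta$nCells, metadata = md),
        stop("unknown spectrum class ", meta$class))
}

#' Read a VAF table as a VAF spectrum
#'
#' Expects delimited text with two columns, \code{allele_index} and
#' \code{n_mutations}, on the doubled-VAF axis described in
#' [VAFSpectrum-class] (a mutation in j of the n cells sits at index 2j).
#'
#' @param file path to the delimited file.
#' @param nCells number of cells in the sample.
#' @param sep field separator (default any whitespace).
#' @return a [VAFSpectrum-class].
#' @export
readVAF <- function(file, nCells, sep = "") {
    df <- utils::read.table(file, header = TRUE, sep = sep)
    if (ncol(df) < 2) stop("expected columns allele_index, n_mutations")
    idx <- as.integer(df[[1]])
    if (any(idx < 1) || any(idx > 2 * nCells))
        stop("allele indices must lie in [1, 2 * nCells]")
    counts <- numeric(2 * nCells)
    counts[idx] <- df[[2]]
    vafSpectrum(counts, nCells)
}
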