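# shared helpers: fixed-width ensemble spectra and small hand-built trees

# pad each replicate's spectrum to a common width and return the matrix
ensembleSpectra <- function(ensemble, extract, width) {
    vapply(ensemble, function(r) {
        s <- spectrumCounts(extract(r@tree))
        length(s) <- width
        s[is.na(s)] <- 0
        s
    }, numeric(width))
}

meanSpectrum <- function(ensemble, extract, width) {
    rowMeans(ensembleSpectra(ensemble, extract, width))
}

# tree with a redundant (nested) resistance event inside a founder subtree:
# root -> (F, B); F resistant founder -> (F1, F2); F1 carries a second,
# redundant resistance flag; all of F1, F2, B alive
nestedFounderTree <- function() {
    lineageTree(parent = c(0, 1, 1, 2, 2),
                nmut = c(0, 1, 1, 1, 1),
                type = c(0, 1, 0, 1, 1),
                founder = c(FALSE, TRUE, FALSE, TRUE, FALSE),
                birthTime = c(0, 1, 1, 2, 2),
                alive = c(FALSE, FALSE, TRUE, TRUE, TRUE))
}
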