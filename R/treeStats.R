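## Extraction of summary statistics (SFS, W_k, tMB, scMB, D_l, CSD) from a
## recorded lineage tree, plus binomial subsampling and VAF conversion.

.checkAliveTree <- function(tree) {
    stopifnot(is(tree, "LineageTree"))
    n <- sum(tree@alive)
    if (n < 1)
        stop("tree has no alive cells: statistics are undefined for an ",
             "extinct population")
    n
}

#' Site frequency spectrum of a lineage tree
#'
#' Iterates over all nodes: a node carrying \eqn{\mu_i} mutations with
#' \eqn{k \ge 1} alive descendant leaves contributes \eqn{\mu_i} to
#' \eqn{S_k}. The companion branch-width counts \eqn{W_k} (number of nodes,
#' leaves and root included, with exactly k alive descendants) are stored in
#' the \code{widths} slot. Dead subtrees contribute nothing.
#'
#' @param tree a [LineageTree-class] with at least one alive cell.
#' @return a [SiteFrequencySpectrum-class] with \code{popSize} the number of
#'   alive cells.
#' @export
sfsFromTree <- function(tree) {
    N <- .checkAliveTree(tree)
    k <- cpp_alive_descendants(tree@parent, tree@alive)
    keep <- k >= 1L
    S <- numeric(N)
    agg <- rowsum(as.numeric(tree@nmut[keep]), k[keep])
    idx <- as.integer(rownames(agg))
    S[idx] <- agg[, 1]
    W <- tabulate(k[keep], nbins = N)
    siteFrequencySpectrum(S, popSize = N, widths = W)
}

#' Single-cell mutational burden distribution of a lineage tree
#'
#' For each alive leaf, the burden \eqn{j} is the sum of branch mutation
#' counts along its root path; \eqn{M_j} counts leaves with burden j.
#'
#' @inheritParams sfsFromTree
#' @return a [BurdenDistribution-class] (index starts at j = 0).
#' @export
scmbFromTree <- function(tree) {
    N <- .checkAliveTree(tree)
    paths <- cpp_leaf_paths(tree@parent, tree@nmut, tree@alive)
    j <- paths$burden
    M <- tabulate(j + 1L, nbins = max(j) + 1L)
    burdenDistribution(M, popSize = N)
}

#' Divisional distribution of a lineage tree
#'
#' For each alive leaf, \eqn{l} is the number of division nodes on its root
#' path (the leaf's edge depth); \eqn{D_l} counts leaves with l divisions.
#' The mean \eqn{\bar l} is recorded in the metadata.
#'
#' @inheritParams sfsFromTree
#' @return a [DivisionalDistribution-class] (index starts at l = 0).
#' @export
divisionalFromTree <- function(tree) {
    N <- .checkAliveTree(tree)
    paths <- cpp_leaf_paths(tree@parent, tree@nmut, tree@alive)
    l <- paths$divisions
    D <- tabulate(l + 1L, nbins = max(l) + 1L)
    divisionalDistribution(D, popSize = N,
                           metadata = list(meanDivisions = mean(l)))
}

#' Resistant clone size distribution of a lineage tree
#'
#' Clones are the subtrees rooted at outermost resistance-founder nodes
#' (a founder inside another founder's subtree is redundant and absorbed,
#' so clones never overlap). \eqn{\Theta_\kappa} counts surviving clones
#' with \eqn{\kappa} alive cells; the per-clone table records founder node,
#' founding time, size, and order of arrival among surviving clones.
#'
#' @inheritParams sfsFromTree
#' @return a [CloneSizeDistribution-class]; empty when no founder survives.
#' @export
csdFromTree <- function(tree) {
    N <- .checkAliveTree(tree)
    founders <- which(tree@founder)
    if (length(founders)) {
        ## keep only outermost founders: no founder among the ancestors
        inner <- logical(length(tree@parent))
        for (i in seq_along(tree@parent)) {
            p <- tree@parent[i]
            if (p > 0L && (inner[p] || tree@founder[p])) inner[i] <- TRUE
        }
        founders <- founders[!inner[founders]]
    }
    if (!length(founders))
        return(cloneSizeDistribution(numeric(0), popSize = N,
            clones = data.frame(founder = integer(0), time = numeric(0),
                                size = integer(0), order = integer(0))))
    k <- cpp_alive_descendants(tree@parent, tree@alive)
    sizes <- k[founders]
    times <- tree@birthTime[founders]
    surv <- sizes > 0L
    founders <- founders[surv]; sizes <- sizes[surv]; times <- times[surv]
    ord <- order(times)
    clones <- data.frame(founder = founders[ord], time = times[ord],
                         size = sizes[ord],
                         order = seq_along(founders))
    Theta <- if (length(sizes)) tabulate(sizes, nbins = max(sizes))
             else numeric(0)
    cloneSizeDistribution(Theta, popSize = N, clones = clones)
}

#' Subsample a site frequency spectrum
#'
#' Models sequencing a well-mixed sample of \code{n} of the \code{N} cells:
#' every mutation of abundance \eqn{K} is resampled to abundance
#' \eqn{\mathrm{Binomial}(n, K/N)} (or hypergeometrically with
#' \code{hypergeometric = TRUE}); abundance-0 outcomes drop out. With
#' \code{expectation = TRUE} no random numbers are drawn and the expected
#' sampled spectrum \eqn{E[S^{(n)}_k] = \sum_K S_K \, \mathrm{Binom}(k; n,
#' K/N)} is returned.
#'
#' @param sfs a [SiteFrequencySpectrum-class].
#' @param n sample size, 1 <= n <= N.
#' @param seed integer seed (ignored in expectation mode).
#' @param expectation return the expected sampled spectrum.
#' @param hypergeometric draw without replacement instead of binomially.
#' @return a [SiteFrequencySpectrum-class] on population size \code{n}.
#' @export
subsampleSFS <- function(sfs, n, seed = 1L, expectation = FALSE,
                         hypergeometric = FALSE) {
    stopifnot(is(sfs, "SiteFrequencySpectrum"))
    N <- sfs@popSize
    if (n < 1 || n > N) stop("need 1 <= n <= N")
    if (n == N) return(sfs)  # sampling the whole population is a no-op
    S <- sfs@counts
    Ks <- which(S > 0)
    out <- numeric(n)
    if (expectation) {
        for (K in Ks)
            out <- out + S[K] * stats::dbinom(seq_len(n), n, K / N)
    } else {
        set.seed(as.integer(seed))
        for (K in Ks) {
            cnt <- as.integer(round(S[K]))
            knew <- if (hypergeometric)
                stats::rhyper(cnt, K, N - K, n)
            else stats::rbinom(cnt, n, K / N)
            knew <- knew[knew > 0]
            if (length(knew))
                out <- out + tabulate(knew, nbins = n)
        }
    }
    siteFrequencySpectrum(out, popSize = n,
        metadata = c(sfs@metadata,
                     list(subsampledFrom = N,
                          sampling = if (hypergeometric) "hypergeometric"
                                     else "binomial")))
}

#' Convert a VAF spectrum into a site frequency spectrum
#'
#' For a pure, diploid, copy-number-neutral sample of \code{n} cells each
#' mutation occupies one allele per carrying cell, so on the doubled-VAF
#' (cancer cell fraction) axis a mutation in \eqn{k} cells sits at index
#' \eqn{2k} and the SFS is recovered as \eqn{S_k = V_{2k}}. Mass at odd
#' indices cannot arise under these assumptions and is reported separately
#' in the metadata as \code{unconvertible}.
#'
#' @param vaf a [VAFSpectrum-class].
#' @return a [SiteFrequencySpectrum-class] on \code{nCells} cells.
#' @export
vafToSFS <- function(vaf) {
    stopifnot(is(vaf, "VAFSpectrum"))
    n <- vaf@nCells
    V <- vaf@counts
    kmax <- min(n, floor(length(V) / 2))
    S <- numeric(max(kmax, 0))
    if (kmax >= 1) S[seq_len(kmax)] <- V[2 * seq_len(kmax)]
    odd <- sum(V[seq(1, length(V), by = 2)])
    siteFrequencySpectrum(S, popSize = n,
                          metadata = list(unconvertible = odd,
                                          assumption = "diploid CN-neutral"))
}
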