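#' Accessors for count spectra and trees
#'
#' \code{spectrumCounts} returns the count vector; \code{spectrumIndex} the
#' matching integer index (k, j, l or kappa); \code{populationSize} the
#' population size N a statistic refers to; \code{totalBurden} the total
#' mutational burden \eqn{B = \sum_k S_k} of an SFS.
#'
#' @param x a \code{Spectrum} subclass or (for \code{populationSize}) a
#'   \code{LineageTree}.
#' @return numeric vector or scalar.
#' @name spectrum-accessors
NULL

#' @rdname spectrum-accessors
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @rdname spectrum-accessors
#' @export
setGeneric("spectrumIndex", function(x) standardGeneric("spectrumIndex"))

#' @rdname spectrum-accessors
#' @export
setGeneric("populationSize", function(x) standardGeneric("populationSize"))

#' @rdname spectrum-accessors
#' @export
setGeneric("totalBurden", function(x) standardGeneric("totalBurden"))

#' @rdname spectrum-accessors
#' @export
setMethod("spectrumCounts", "Spectrum", function(x) x@counts)

#' @rdname spectrum-accessors
#' @export
setMethod("spectrumIndex", "Spectrum",
    function(x) seq_along(x@counts) + x@minIndex - 1L)

#' @rdname spectrum-accessors
#' @export
setMethod("populationSize", "Spectrum", function(x) x@popSize)

#' @rdname spectrum-accessors
#' @export
setMethod("populationSize", "LineageTree", function(x) sum(x@alive))

#' @rdname spectrum-accessors
#' @export
setMethod("totalBurden", "SiteFrequencySpectrum", function(x) sum(x@counts))

setMethod("show", "RatePair", function(object) {
    cat(sprintf("RatePair: birth = %g, death = %g (net %+g)\n",
                object@birth, object@death, object@birth - object@death))
})

setMethod("show", "TreatmentPlan", function(object) {
    fmt <- function(r) sprintf("b_s=%g d_s=%g b_r=%g d_r=%g",
                               r[1], r[2], r[3], r[4])
    cat("TreatmentPlan\n")
    cat("  phase 1 (growth):   ", fmt(object@phase1), "\n")
    cat("  phase 2 (treatment):", fmt(object@phase2), "\n")
    cat(sprintf("  mutation model: m = %g, nu = %g\n",
                object@mutation@m, object@mutation@nu))
    cat(sprintf("  detection: fixed %s = %g\n", object@detectionRule$type,
                object@detectionRule$value))
    if (object@endRule$type == "none")
        cat("  end rule: none (phase 1 only)\n")
    else cat(sprintf("  end rule: fixed %s = %g\n", object@endRule$type,
                     object@endRule$value))
})

setMethod("show", "LineageTree", function(object) {
    cat(sprintf(
        "LineageTree: %d nodes, %d alive cells (%d resistant), %d dead leaves\n",
        length(object@parent), sum(object@alive),
        sum(object@alive & object@type == 1L),
        sum(!treeHasChildren(object) & !object@alive)))
    cat(sprintf("  detection time %.4g, final time %.4g\n",
                object@detectionTime, object@finalTime))
})

setMethod("show", "SimulationResult", function(object) {
    cat(sprintf("SimulationResult (seed %d, %d attempt%s)\n",
                object@seed, object@attempts,
                if (object@attempts == 1L) "" else "s"))
    show(object@tree)
})

setMethod("show", "Spectrum", function(object) {
    nz <- which(object@counts > 0)
    cat(sprintf("%s: N = %g, %d occupied classes, total count %g\n",
                class(object), object@popSize, length(nz),
                sum(object@counts)))
    if (length(nz)) {
        head <- utils::head(nz, 8)
        cat("  ", paste(sprintf("[%d] %g", head + object@minIndex - 1L,
                                object@counts[head]), collapse = "  "),
            if (length(nz) > 8) " ..." else "", "\n", sep = "")
    }
})
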