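#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Birth and death rates of a linear birth-death process
#'
#' A pair of per-cell, per-unit-time event rates. The net growth rate
#' \code{birth - death} may have any sign.
#'
#' @slot birth numeric(1), birth rate, >= 0.
#' @slot death numeric(1), death rate, >= 0.
#' @export
setClass("RatePair", representation(birth = "numeric", death = "numeric"),
    validity = function(object) {
        if (length(object@birth) != 1 || length(object@death) != 1)
            return("birth and death must be scalars")
        if (!is.finite(object@birth) || !is.finite(object@death))
            return("rates must be finite")
        if (object@birth < 0 || object@death < 0)
            return("rates must be nonnegative")
        TRUE
    })

#' @param birth,death nonnegative per-cell rates.
#' @rdname RatePair-class
#' @export
ratePair <- function(birth, death = 0) {
    new("RatePair", birth = as.numeric(birth), death = as.numeric(death))
}

#' Transition kernel of the linear birth-death process
#'
#' Evaluation strategy for \eqn{p(a \to n, t)}: closed forms for pure birth,
#' pure death and single-ancestor starts; a log-space stable sum while
#' \eqn{\min(a, n) \le} \code{exactCutoff}; a renormalized saddlepoint
#' approximation of the a-fold offspring law beyond it.
#'
#' @slot rates a [RatePair-class].
#' @slot exactCutoff integer threshold on \eqn{\min(a,n)} separating the
#'   exact stable sum from the saddlepoint regime (default 50).
#' @slot renormalize logical; renormalize the saddlepoint mass over its
#'   support (default TRUE).
#' @export
setClass("TransitionKernel",
    representation(rates = "RatePair", exactCutoff = "integer",
                   renormalize = "logical"),
    validity = function(object) {
        if (object@exactCutoff < 1) return("exactCutoff must be >= 1")
        TRUE
    })

#' @param rates a [RatePair-class].
#' @param exactCutoff regime threshold on min(a, n).
#' @param renormalize renormalize the saddlepoint mass.
#' @rdname TransitionKernel-class
#' @export
transitionKernel <- function(rates, exactCutoff = 50L, renormalize = TRUE) {
    new("TransitionKernel", rates = rates,
        exactCutoff = as.integer(exactCutoff), renormalize = renormalize)
}

#' First-passage time model for a supercritical birth-death process
#'
#' The time to first reach size \code{targetSize} from a single cell,
#' conditioned on survival, approximated by a Gumbel law with scale
#' \eqn{1/(b-d)} and location fixed by matching the known mean.
#'
#' @slot rates a [RatePair-class] with \code{birth > death}.
#' @slot targetSize numeric(1), the size N to be reached.
#' @export
setClass("FirstPassageModel",
    representation(rates = "RatePair", targetSize = "numeric"),
    validity = function(object) {
        if (object@rates@birth <= object@rates@death)
            return("first passage to a large size requires birth > death")
        if (object@targetSize < 2) return("targetSize must be >= 2")
        TRUE
    })

#' @param rates supercritical [RatePair-class].
#' @param targetSize size to be reached.
#' @rdname FirstPassageModel-class
#' @export
firstPassageModel <- function(rates, targetSize) {
    new("FirstPassageModel", rates = rates,
        targetSize = as.numeric(targetSize))
}

#' Neutral and resistance mutation model
#'
#' Neutral mutations arrive on each daughter cell at each division as
#' Poisson(\code{m}) under the infinite-sites assumption (every mutation is
#' globally unique, no reversion). Each daughter of a sensitive cell
#' independently acquires a resistance mutation with probability \code{nu}.
#'
#' @slot m mean neutral mutations per daughter per division.
#' @slot nu per-daughter, per-division resistance probability.
#' @export
setClass("MutationModel", representation(m = "numeric", nu = "numeric"),
    validity = function(object) {
        if (object@m < 0) return("m must be >= 0")
        if (object@nu < 0 || object@nu > 1) return("nu must be in [0, 1]")
        TRUE
    })

#' @param m mean neutral mutations per daughter per division.
#' @param nu per-daughter resistance probability.
#' @rdname MutationModel-class
#' @export
mutationModel <- function(m, nu = 0) {
    new("MutationModel", m = as.numeric(m), nu = as.numeric(nu))
}

#' Two-phase treatment plan
#'
#' Growth phase (phase 1) rates per cell type, treatment phase (phase 2)
#' rates per cell type, the mutation model, and the two stopping rules:
#' detection (fixed size \code{detectionSize} or fixed time
#' \code{detectionTime}) and end of treatment (fixed duration
#' \code{treatmentDuration} or fixed size \code{finalSize}). A plan with no
#' end rule simulates phase 1 only.
#'
#' @slot phase1,phase2 numeric(4): (b_s, d_s, b_r, d_r).
#' @slot mutation a [MutationModel-class].
#' @slot detectionRule,endRule list(type, value); type is "size", "time",
#'   "duration" or "none".
#' @export
setClass("TreatmentPlan",
    representation(phase1 = "numeric", phase2 = "numeric",
                   mutation = "MutationModel",
                   detectionRule = "list", endRule = "list"),
    validity = function(object) {
        if (length(object@phase1) != 4 || length(object@phase2) != 4)
            return("phase rate vectors must have length 4 (b_s, d_s, b_r, d_r)")
        if (any(object@phase1 < 0) || any(object@phase2 < 0))
            return("all rates must be nonnegative")
        if (!object@detectionRule$type %in% c("size", "time"))
            return("detection rule must be fixed size or fixed time")
        if (!object@endRule$type %in% c("none", "duration", "size"))
            return("end rule must be none, duration or size")
        TRUE
    })

#' @param bs1,ds1,br1,dr1 phase-1 rates for sensitive/resistant cells;
#'   resistant cells default to neutrality before treatment.
#' @param bs2,ds2,br2,dr2 phase-2 rates; default to the phase-1 values.
#' @param m,nu mutation model parameters.
#' @param detectionSize,detectionTime exactly one of the two detection rules.
#' @param treatmentDuration,finalSize at most one of the two end rules.
#' @rdname TreatmentPlan-class
#' @export
treatmentPlan <- function(bs1, ds1 = 0, br1 = bs1, dr1 = ds1,
                          bs2 = bs1, ds2 = ds1, br2 = br1, dr2 = dr1,
                          m = 1, nu = 0,
                          detectionSize = NULL, detectionTime = NULL,
                          treatmentDuration = NULL, finalSize = NULL) {
    if (is.null(detectionSize) == is.null(detectionTime))
        stop("give exactly one of detectionSize and detectionTime")
    det <- if (!is.null(detectionSize))
        list(type = "size", value = as.numeric(detectionSize))
    else list(type = "time", value = as.numeric(detectionTime))
    if (!is.null(treatmentDuration) && !is.null(finalSize))
        stop("give at most one of treatmentDuration and finalSize")
    end <- if (!is.null(treatmentDuration))
        list(type = "duration", value = as.numeric(treatmentDuration))
    else if (!is.null(finalSize))
        list(type = "size", value = as.numeric(finalSize))
    else list(type = "none", value = NA_real_)
    new("TreatmentPlan", phase1 = c(bs1, ds1, br1, dr1),
        phase2 = c(bs2, ds2, br2, dr2),
        mutation = mutationModel(m, nu), detectionRule = det, endRule = end)
}

#' Recorded lineage tree of a simulated population
#'
#' A binary genealogy: the root is the ancestor cell; leaves are cells alive
#' at the stopping point plus dead cells (flagged, excluded from all
#' statistics). Nodes are stored in chronological order so every parent
#' index is smaller than its children's indices.
#'
#' @slot parent integer parent index per node (0 at the root).
#' @slot nmut integer neutral mutation count on the incoming branch.
#' @slot type integer, 0 sensitive / 1 resistant.
#' @slot founder logical, TRUE where resistance was acquired.
#' @slot birthTime numeric, time the cell appeared.
#' @slot alive logical, TRUE for cells alive at stop.
#' @slot detectionTime,finalTime numeric(1) elapsed times.
#' @export
setClass("LineageTree",
    representation(parent = "integer", nmut = "integer", type = "integer",
                   founder = "logical", birthTime = "numeric",
                   alive = "logical", detectionTime = "numeric",
                   finalTime = "numeric"),
    validity = function(object) {
        n <- length(object@parent)
        lens <- c(length(object@nmut), length(object@type),
                  length(object@founder), length(object@birthTime),
                  length(object@alive))
        if (any(lens != n)) return("node slots must have equal length")
        if (n >= 1 && object@parent[1] != 0L) return("root must be node 1")
        if (n >= 2 && any(object@parent[-1] >= seq_len(n)[-1]))
            return("parents must precede children")
        if (any(object@nmut < 0)) return("mutation counts must be >= 0")
        TRUE
    })

#' @param parent,nmut,type,founder,birthTime,alive node vectors.
#' @param detectionTime,finalTime elapsed times.
#' @rdname LineageTree-class
#' @export
lineageTree <- function(parent, nmut, type = integer(length(parent)),
                        founder = logical(length(parent)),
                        birthTime = numeric(length(parent)),
                        alive = rep(TRUE, length(parent)),
                        detectionTime = NA_real_, finalTime = NA_real_) {
    new("LineageTree", parent = as.integer(parent), nmut = as.integer(nmut),
        type = as.integer(type), founder = as.logical(founder),
        birthTime = as.numeric(birthTime), alive = as.logical(alive),
        detectionTime = as.numeric(detectionTime),
        finalTime = as.numeric(finalTime))
}

#' One conditioned realization of a treatment plan
#'
#' @slot tree the recorded [LineageTree-class].
#' @slot survived logical; FALSE only when final-survival conditioning was
#'   off and the population died during treatment.
#' @slot seed integer seed that produced the event stream.
#' @slot attempts rejection-sampling attempts used for survival conditioning.
#' @slot replicate replicate index within an ensemble.
#' @export
setClass("SimulationResult",
    representation(tree = "LineageTree", survived = "logical",
                   seed = "integer", attempts = "integer",
                   replicate = "integer"))

## ---- count spectra ---------------------------------------------------------

#' Integer-indexed count spectra
#'
#' Common backbone of the summary statistics: a vector of nonnegative counts
#' indexed by consecutive integers starting at \code{minIndex} (1 for
#' frequency-type spectra, 0 for per-cell burden distributions), the
#' population size the statistic refers to, and free-form metadata.
#'
#' @slot counts numeric vector of class counts.
#' @slot minIndex integer index of \code{counts[1]}.
#' @slot popSize numeric(1) population size N.
#' @slot metadata list of provenance information.
#' @export
setClass("Spectrum",
    representation("VIRTUAL", counts = "numeric", minIndex = "integer",
                   popSize = "numeric", metadata = "list"),
    validity = function(object) {
        if (any(object@counts < 0)) return("counts must be nonnegative")
        TRUE
    })

#' Site frequency spectrum
#'
#' Counts \eqn{S_k} of mutations present in exactly \eqn{k} alive cells,
#' \eqn{k = 1, \dots, N}, optionally with the companion branch-width counts
#' \eqn{W_k} (number of tree nodes with exactly k alive descendant leaves).
#'
#' @slot widths numeric W_k companion counts (may be empty).
#' @export
setClass("SiteFrequencySpectrum", contains = "Spectrum",
    representation(widths = "numeric"))

#' @param counts S_k counts for k = 1..length(counts).
#' @param popSize population size N.
#' @param widths optional W_k counts.
#' @param metadata optional list.
#' @rdname SiteFrequencySpectrum-class
#' @export
siteFrequencySpectrum <- function(counts, popSize, widths = numeric(0),
                                  metadata = list()) {
    new("SiteFrequencySpectrum", counts = as.numeric(counts), minIndex = 1L,
        popSize = as.numeric(popSize), widths = as.numeric(widths),
        metadata = metadata)
}

#' Single-cell mutational burden distribution
#'
#' Counts \eqn{M_j} of alive cells carrying exactly \eqn{j} mutations,
#' \eqn{j \ge 0}; \code{sum(counts) == popSize}.
#' @export
setClass("BurdenDistribution", contains = "Spectrum")

#' @param counts M_j counts for j = 0..(length(counts) - 1).
#' @param popSize population size N.
#' @param metadata optional list.
#' @rdname BurdenDistribution-class
#' @export
burdenDistribution <- function(counts, popSize, metadata = list()) {
    new("BurdenDistribution", counts = as.numeric(counts), minIndex = 0L,
        popSize = as.numeric(popSize), metadata = metadata)
}

#' Divisional distribution
#'
#' Counts \eqn{D_l} of alive cells whose root-to-leaf path contains
#' \eqn{l} division nodes, \eqn{l \ge 0}.
#' @export
setClass("DivisionalDistribution", contains = "Spectrum")

#' @param counts D_l counts for l = 0..(length(counts) - 1).
#' @param popSize population size N.
#' @param metadata optional list.
#' @rdname DivisionalDistribution-class
#' @export
divisionalDistribution <- function(counts, popSize, metadata = list()) {
    new("DivisionalDistribution", counts = as.numeric(counts), minIndex = 0L,
        popSize = as.numeric(popSize), metadata = metadata)
}

#' Resistant clone size distribution
#'
#' Counts \eqn{\Theta_\kappa} of non-nested resistant clones (outermost
#' resistance-founder subtrees) with \eqn{\kappa} alive cells, with a
#' per-clone record table.
#'
#' @slot clones data.frame with founder node, founding time, size, and
#'   order of arrival among surviving clones.
#' @export
setClass("CloneSizeDistribution", contains = "Spectrum",
    representation(clones = "data.frame"))

#' @param counts Theta_kappa counts for kappa = 1..length(counts).
#' @param popSize population size N.
#' @param clones per-clone record table.
#' @param metadata optional list.
#' @rdname CloneSizeDistribution-class
#' @export
cloneSizeDistribution <- function(counts, popSize,
                                  clones = data.frame(), metadata = list()) {
    new("CloneSizeDistribution", counts = as.numeric(counts), minIndex = 1L,
        popSize = as.numeric(popSize), clones = clones, metadata = metadata)
}

#' Variant allele frequency spectrum of a diploid sample
#'
#' Counts \eqn{V_k} of mutations binned by doubled allele frequency on the
#' \eqn{2n}-allele axis of an n-cell diploid, copy-number-neutral sample:
#' for heterozygous CN-neutral sites twice the VAF is the cancer cell
#' fraction, so a mutation carried by \eqn{j} cells (VAF \eqn{j/(2n)}) sits
#' at even index \eqn{k = 2j}, and the cell-level SFS is recovered as
#' \eqn{S_k = V_{2k}}. Mass at odd indices signals violated assumptions.
#'
#' @slot nCells number of sampled cells n.
#' @export
setClass("VAFSpectrum", contains = "Spectrum",
    representation(nCells = "numeric"))

#' @param counts V_k counts for allele counts k = 1..length(counts).
#' @param nCells number of cells in the sample.
#' @param metadata optional list.
#' @rdname VAFSpectrum-class
#' @export
vafSpectrum <- function(counts, nCells, metadata = list()) {
    new("VAFSpectrum", counts = as.numeric(counts), minIndex = 1L,
        popSize = as.numeric(nCells), nCells = as.numeric(nCells),
        metadata = metadata)
}
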