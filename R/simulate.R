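## Gillespie simulation of the two-phase, two-type birth-death process with
## full lineage-tree recording. The event loop lives in src/simulator.cpp;
## this file handles seeds, survival conditioning and the S4 surface.

.ruleCode <- function(rule) switch(rule$type,
    size = 1L, time = 2L, duration = 1L, none = 0L,
    stop("unknown stopping rule"))

.treeFromList <- function(res) {
    lineageTree(parent = res$parent, nmut = res$nmut, type = res$type,
                founder = res$founder, birthTime = res$btime,
                alive = res$alive, detectionTime = res$detectionTime,
                finalTime = res$finalTime)
}

#' Simulate a treatment plan once
#'
#' Exact stochastic simulation of the two-phase birth-death process defined
#' by a [TreatmentPlan-class], recording the complete binary lineage tree.
#' Waiting times are exponential in the total event rate; the event cell is
#' chosen proportionally to its rates; a birth replaces a leaf by two
#' daughters, each independently gaining Poisson(\code{m}) neutral mutations
#' and (for a sensitive parent) becoming resistant with probability
#' \code{nu}; a death removes the leaf. Rates switch from phase 1 to phase 2
#' at detection.
#'
#' Survival conditioning is by rejection: attempts whose population dies out
#' before detection (and, with \code{conditionOnFinalSurvival = TRUE}, before
#' the end of treatment) are discarded and rerun with a fresh seed derived
#' deterministically from \code{seed}. Populations that hit zero during
#' phase 2 are legitimate outcomes and kept by default.
#'
#' @param plan a [TreatmentPlan-class].
#' @param seed integer seed fixing the full event stream.
#' @param conditionOnSurvival reject attempts extinct before detection
#'   (default TRUE).
#' @param conditionOnFinalSurvival additionally reject attempts extinct
#'   before the end of treatment (default FALSE).
#' @param maxPopulation hard cap on the population size.
#' @param maxEvents hard cap on the number of events.
#' @param maxAttempts cap on rejection-sampling attempts.
#' @return a [SimulationResult-class].
#' @examples
#' plan <- treatmentPlan(bs1 = 1, ds1 = 0, m = 1, detectionSize = 50)
#' res <- simulateTumor(plan, seed = 1)
#' populationSize(res@tree)  # 50
#' @export
simulateTumor <- function(plan, seed = 1L, conditionOnSurvival = TRUE,
                          conditionOnFinalSurvival = FALSE,
                          maxPopulation = 1e7, maxEvents = 1e9,
                          maxAttempts = 10000L) {
    stopifnot(is(plan, "TreatmentPlan"))
    validObject(plan)
    if (all(plan@phase1 == 0)) stop("phase-1 rates are all zero")
    mm <- plan@mutation
    det <- plan@detectionRule; end <- plan@endRule

    set.seed(as.integer(seed))
    attempt <- 0L
    repeat {
        attempt <- attempt + 1L
        if (attempt > maxAttempts)
            stop("no surviving realization in ", maxAttempts, " attempts")
        subseed <- sample.int(.Machine$integer.max - 1L, 1L)
        set.seed(subseed)
        res <- cpp_simulate_tree(plan@phase1, plan@phase2, mm@m, mm@nu,
                                 .ruleCode(det), det$value,
                                 .ruleCode(end), end$value,
                                 maxPopulation, maxEvents)
        survived <- res$nAlive > 0L
        if (!conditionOnSurvival && !conditionOnFinalSurvival) break
        if (res$extinct && conditionOnSurvival) next
        if (!survived && conditionOnFinalSurvival) next
        break
    }
    new("SimulationResult", tree = .treeFromList(res),
        survived = res$nAlive > 0L, seed = as.integer(seed),
        attempts = attempt, replicate = 1L)
}

#' Simulate an ensemble of independent replicates
#'
#' Runs \code{nReplicates} independent simulations of one plan with
#' per-replicate seeds derived deterministically from \code{baseSeed}; the
#' same (plan, baseSeed, n) triple reproduces bit-identical event streams.
#'
#' @inheritParams simulateTumor
#' @param nReplicates number of replicates, >= 1.
#' @param baseSeed integer seed for the whole ensemble.
#' @param ... passed on to [simulateTumor()].
#' @return list of [SimulationResult-class] objects.
#' @export
runEnsemble <- function(plan, nReplicates, baseSeed = 1L, ...) {
    if (length(nReplicates) != 1 || nReplicates < 1)
        stop("nReplicates must be >= 1")
    set.seed(as.integer(baseSeed))
    seeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    out <- vector("list", nReplicates)
    for (i in seq_len(nReplicates)) {
        out[[i]] <- simulateTumor(plan, seed = seeds[i], ...)
        out[[i]]@replicate <- i
    }
    out
}

.treeChildCount <- function(tree) {
    tabulate(tree@parent[tree@parent > 0L], nbins = length(tree@parent))
}

treeHasChildren <- function(tree) .treeChildCount(tree) > 0L

#' Export a lineage tree as Newick text
#'
#' Writes the full recorded binary tree (alive and dead leaves) with branch
#' lengths equal to the per-branch neutral mutation counts. Tip labels
#' encode node index, cell type and alive status, e.g. \code{c12_r_alive}.
#'
#' @param tree a [LineageTree-class].
#' @param file optional path; with \code{NULL} the Newick string is
#'   returned invisibly instead.
#' @return the Newick string, invisibly.
#' @export
exportNewick <- function(tree, file = NULL) {
    stopifnot(is(tree, "LineageTree"))
    nch <- .treeChildCount(tree)
    n <- length(tree@parent)
    isTip <- nch == 0L
    ntip <- sum(isTip)
    if (ntip < 2) {
        nwk <- sprintf("(c1_%s_%s:%d);",
                       if (tree@type[1] == 1L) "r" else "s",
                       if (tree@alive[1]) "alive" else "dead", tree@nmut[1])
    } else {
        ## map to ape numbering: tips 1..ntip, internals ntip+1..
        newId <- integer(n)
        newId[isTip] <- seq_len(ntip)
        newId[!isTip] <- ntip + seq_len(n - ntip)
        edge <- cbind(newId[tree@parent[-1]], newId[-1])
        phy <- structure(list(
            edge = edge,
            edge.length = as.numeric(tree@nmut[-1]),
            tip.label = sprintf("c%d_%s_%s", which(isTip),
                                ifelse(tree@type[isTip] == 1L, "r", "s"),
                                ifelse(tree@alive[isTip], "alive", "dead")),
            Nnode = n - ntip), class = "phylo")
        phy <- ape::reorder.phylo(phy, "cladewise")
        nwk <- ape::write.tree(phy)
    }
    if (!is.null(file)) writeLines(nwk, file)
    invisible(nwk)
}
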