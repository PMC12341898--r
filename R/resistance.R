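## Analytics and samplers for heterogeneous treatment response: resistant
## clone size distributions, first/second clone ordering, the largest
## surviving clone, the Landau law for the total resistant load, the
## compound resistant SFS with its subset-sum peaks, and scMB mixtures.

.planRates <- function(plan, phase, type) {
    r <- if (phase == 1) plan@phase1 else plan@phase2
    if (type == "s") ratePair(r[1], r[2]) else ratePair(r[3], r[4])
}

.planNd <- function(plan) {
    if (plan@detectionRule$type != "size")
        stop("this analysis needs a fixed-size detection rule")
    plan@detectionRule$value
}

#' Expected resistant clone size distribution at detection
#'
#' Resistant lineages are founded at rate \eqn{2 \nu b_{s,1}} per sensitive
#' division and then grow with the resistant phase-1 rates:
#' \deqn{E[\Theta_\kappa] \approx \frac{1}{1 - p_s(1 \to 0, t_d)}
#' \int_0^{t_d} 2 \nu b_{s,1} e^{(b_{s,1} - d_{s,1}) t} \,
#' p_r(1 \to \kappa, t_d - t) \, dt.}
#' Under pre-treatment neutrality (resistant = sensitive rates) this
#' collapses to the detection-SFS series with \eqn{m \to \nu}:
#' \eqn{2 \nu N_d \sum_l (d_1/b_1)^l / ((\kappa+l)(\kappa+l+1))}.
#'
#' @param kappa clone size (vectorized), >= 1.
#' @param plan a [TreatmentPlan-class] with \code{nu > 0} and fixed-size
#'   detection.
#' @param relTol quadrature tolerance for the non-neutral case.
#' @return expected clone counts E[Theta_kappa].
#' @export
csdDetection <- function(kappa, plan, relTol = 1e-3) {
    stopifnot(is(plan, "TreatmentPlan"))
    nu <- plan@mutation@nu
    if (nu == 0) return(rep(0, length(kappa)))
    Nd <- .planNd(plan)
    s1 <- .planRates(plan, 1, "s"); r1 <- .planRates(plan, 1, "r")
    neutral <- s1@birth == r1@birth && s1@death == r1@death
    if (neutral)
        return(sfsDetection(kappa, m = nu, rates = s1, Nd = Nd))
    ## detection time for the fixed-time integral: the point where the
    ## survival-conditioned mean reaches Nd (not the first-passage mean,
    ## whose Gumbel offset would overstate e^{r td} by e^gamma)
    td <- stats::uniroot(function(t) conditionedMeanSize(s1, t) - Nd,
                         c(1e-8, 10 * firstPassageMean(s1, Nd)),
                         tol = 1e-10)$root
    surv <- 1 - extinctionProbability(s1, td, 1)
    rs <- s1@birth - s1@death
    vapply(kappa, function(kp) {
        f <- function(tt) vapply(tt, function(x) {
            2 * nu * s1@birth * exp(rs * x) *
                transitionProbability(r1, 1L, kp, td - x)
        }, numeric(1))
        stats::integrate(f, 0, td, rel.tol = relTol,
                         subdivisions = 500L)$value / surv
    }, numeric(1))
}

#' Expected resistant clone size distribution after treatment
#'
#' Component \code{"new"}: clones founded by surviving sensitive cells
#' during treatment, \eqn{\int_0^{t_f} 2 \nu b_{s,2} N_d e^{(b_{s,2} -
#' d_{s,2}) t'} p_{r,2}(1 \to \kappa, t_f - t') \, dt'}. Component
#' \code{"pre"}: the detection-time clone size distribution propagated
#' through the resistant phase-2 kernel, \eqn{\sum_{\kappa'}
#' E[\Theta_{\kappa'}^{det}] \, p_{r,2}(\kappa' \to \kappa, t_f)}.
#'
#' @param kappa clone size (vectorized), >= 1.
#' @param plan a [TreatmentPlan-class] with a fixed-duration end rule (or
#'   pass \code{tf}).
#' @param component "total", "new" or "pre".
#' @param tf treatment duration; defaults to the plan's end rule.
#' @param relTol quadrature tolerance.
#' @return expected clone counts.
#' @export
csdAfterTreatment <- function(kappa, plan,
                              component = c("total", "new", "pre"),
                              tf = NULL, relTol = 1e-3) {
    component <- match.arg(component)
    stopifnot(is(plan, "TreatmentPlan"))
    nu <- plan@mutation@nu
    Nd <- .planNd(plan)
    if (is.null(tf)) {
        if (plan@endRule$type != "duration")
            stop("give tf directly or use a fixed-duration end rule")
        tf <- plan@endRule$value
    }
    s2 <- .planRates(plan, 2, "s"); r2 <- .planRates(plan, 2, "r")
    newPart <- function() {
        if (tf == 0 || nu == 0 || s2@birth == 0) return(rep(0, length(kappa)))
        rs <- s2@birth - s2@death
        vapply(kappa, function(kp) {
            f <- function(tt) vapply(tt, function(x) {
                2 * nu * s2@birth * Nd * exp(rs * x) *
                    transitionProbability(r2, 1L, kp, tf - x)
            }, numeric(1))
            stats::integrate(f, 0, tf, rel.tol = relTol,
                             subdivisions = 500L)$value
        }, numeric(1))
    }
    prePart <- function() {
        if (tf == 0) return(csdDetection(kappa, plan))
        kmaxInit <- ceiling(max(Nd / 10, max(kappa) *
                                exp(-(r2@birth - r2@death) * tf) * 5, 200))
        init <- csdDetection(seq_len(min(kmaxInit, Nd)), plan)
        sfsPreGeneral(kappa, init, r2, tf, N0 = Nd,
                      conditionOnSurvival = FALSE)
    }
    switch(component,
        new = newPart(),
        pre = prePart(),
        total = newPart() + prePart())
}

#' Sample the ordering of the first two surviving resistant clones
#'
#' Draws arrival times \eqn{(T_1, T_2)} of the first and second
#' drift-surviving resistant lineages by inverse-transform sampling of an
#' inhomogeneous Poisson process with intensity \eqn{2 \nu b_1 N(t) (1 -
#' d_1/b_1)} (founding rate thinned by eventual survival), long-run scale
#' factors \eqn{V_1, V_2 \sim} Exp with mean \eqn{(b_1-d_1)/b_1}, and
#' returns per sample the detection-time sizes \eqn{V_i e^{(b_1-d_1)(t_d -
#' T_i)}} and their difference \eqn{\Delta}. In roughly one-third of
#' samples the second clone is the larger one (\eqn{\Delta < 0}): drift
#' alone can overturn the arrival order.
#'
#' @param plan a [TreatmentPlan-class] with \code{nu > 0}, supercritical
#'   sensitive phase-1 rates and fixed-size detection.
#' @param nSamples number of samples.
#' @param seed integer seed.
#' @return data.frame with columns T1, T2, V1, V2, size1, size2, delta.
#' @export
sampleCloneOrdering <- function(plan, nSamples, seed = 1L) {
    stopifnot(is(plan, "TreatmentPlan"))
    nu <- plan@mutation@nu
    if (nu <= 0) stop("clone ordering needs nu > 0")
    Nd <- .planNd(plan)
    s1 <- .planRates(plan, 1, "s")
    b1 <- s1@birth; d1 <- s1@death
    if (b1 <= d1) stop("sensitive phase-1 rates must be supercritical")
    if (nu * Nd < 2)
        warning("nu * Nd = ", nu * Nd,
                " is small: two surviving clones are unlikely in this regime")
    r <- b1 - d1
    td <- firstPassageMean(s1, Nd)
    set.seed(as.integer(seed))
    ## inverse transformation sampling throughout: uniform draws mapped
    ## through the inverse CDFs. Cumulative intensity Lambda(t) =
    ## 2 nu (e^{rt} - 1), so T = log(1 + L / (2 nu)) / r for standard-
    ## exponential increments L of the time-changed process.
    u <- matrix(stats::runif(4 * nSamples), ncol = 4)
    L1 <- -log(u[, 1])
    L2 <- L1 - log(u[, 2])
    T1 <- log1p(L1 / (2 * nu)) / r
    T2 <- log1p(L2 / (2 * nu)) / r
    vmean <- r / b1
    V1 <- -vmean * log(u[, 3])
    V2 <- -vmean * log(u[, 4])
    size1 <- V1 * exp(r * (td - T1))
    size2 <- V2 * exp(r * (td - T2))
    data.frame(T1 = T1, T2 = T2, V1 = V1, V2 = V2,
               size1 = size1, size2 = size2, delta = size1 - size2)
}

#' Size of the largest surviving resistant clone
#'
#' Order-statistics approximation, valid for \eqn{\nu N_d \gg 1}: with
#' \eqn{A = 2 \nu N_d \, b_1/(b_1 - d_1)}, the largest clone size
#' \eqn{\tilde\kappa} has density \eqn{A/\tilde\kappa^2 \,
#' (1 - 1/\tilde\kappa)^{A-1}} on \eqn{[1, \infty)}, distribution function
#' \eqn{(1 - 1/\tilde\kappa)^A} and median \eqn{1/(1 - 2^{-1/A})}.
#'
#' @param A the compound parameter \eqn{2 \nu N_d b_1 / (b_1 - d_1)} > 0.
#' @param kappa clone size(s) >= 1 (ignored for \code{query = "median"}).
#' @param query "density", "cdf" or "median".
#' @return requested value(s).
#' @examples
#' largestClone(A = 1, query = "median")  # 2
#' @export
largestClone <- function(A, kappa = NULL, query = c("density", "cdf",
                                                    "median")) {
    query <- match.arg(query)
    if (A <= 0) stop("A must be > 0")
    if (query == "median") return(1 / (1 - 2^(-1 / A)))
    if (is.null(kappa) || any(kappa < 1)) stop("kappa must be >= 1")
    if (query == "density")
        A / kappa^2 * (1 - 1 / kappa)^(A - 1)
    else
        (1 - 1 / kappa)^A
}

#' Compound parameter A of the largest-clone law
#'
#' @param plan a [TreatmentPlan-class] with fixed-size detection.
#' @return \eqn{A = 2 \nu N_d \, b_1/(b_1 - d_1)}.
#' @export
largestCloneA <- function(plan) {
    s1 <- .planRates(plan, 1, "s")
    2 * plan@mutation@nu * .planNd(plan) * s1@birth / (s1@birth - s1@death)
}

#' Luria-Delbruck (Landau) law of the total resistant population
#'
#' For \eqn{\nu \ll 1} and \eqn{\nu N_d \gg 1} the number of resistant
#' cells R at detection follows a shifted, scaled Landau distribution:
#' \deqn{P(R) = \frac{b_1 - d_1}{b_1} \frac{1}{2 \nu N_d}
#' p_{Landau}\!\left(\frac{b_1 - d_1}{b_1} \frac{R}{2 \nu N_d} -
#' \ln(2 \nu N_d)\right).}
#' \code{query = "median"} inverts the Landau CDF by root finding.
#'
#' @param plan a [TreatmentPlan-class] with fixed-size detection.
#' @param R resistant cell count(s) (for "density").
#' @param query "density" or "median".
#' @return density values, or the median of R.
#' @export
resistantTotalDistribution <- function(plan, R = NULL,
                                       query = c("density", "median")) {
    query <- match.arg(query)
    s1 <- .planRates(plan, 1, "s")
    nu <- plan@mutation@nu
    Nd <- .planNd(plan)
    cfac <- (s1@birth - s1@death) / s1@birth
    scale <- 2 * nu * Nd
    if (query == "median")
        return((qlandau(0.5) + log(scale)) * scale / cfac)
    if (is.null(R)) stop("query = 'density' needs R")
    cfac / scale * dlandau(cfac * R / scale - log(scale))
}

#' Compound SFS of fully resistant clones
#'
#' When resistance rates are unchanged by treatment (\eqn{b_r, d_r}
#' constant across phases), the union of all resistant clones carries the
#' familiar growing-population spectrum at its own size \eqn{N_r}:
#' \eqn{E[S_k^R] = 2 m N_r \sum_l (d_r/b_r)^l / ((k+l)(k+l+1))}.
#'
#' @param k site frequency (vectorized).
#' @param m mean mutations per daughter per division.
#' @param ratesR resistant [RatePair-class] (supercritical).
#' @param Nr total number of resistant cells.
#' @return expected counts.
#' @export
compoundResistantSFS <- function(k, m, ratesR, Nr) {
    sfsDetection(k, m, ratesR, Nr)
}

#' Predicted subset-sum peaks in a multiclonal SFS
#'
#' Mutations shared by a set Y of resistant clones (clonal in each, absent
#' elsewhere) sit at frequency \eqn{k = \sum_{j \in Y} \kappa_j} and add a
#' peak of height \eqn{C_Y} on top of the smooth compound spectrum. Peaks
#' whose subset sums collide are merged by summing their heights.
#'
#' @param cloneSizes numeric vector of clone sizes (K <= 15).
#' @param sharedCounts list of entries \code{list(clones = indices, count
#'   = C_Y)}; subsets with zero count may be omitted. Alternatively the
#'   data.frame returned by [cloneSharedCounts()].
#' @return data.frame with columns \code{k} (peak position),
#'   \code{height}, and \code{subsets} (merged subset labels).
#' @export
predictSfsPeaks <- function(cloneSizes, sharedCounts) {
    K <- length(cloneSizes)
    if (K > 15)
        stop("K > 15 clones: enumeration over 2^K subsets is not ",
             "practical, truncate to the largest clones")
    if (is.data.frame(sharedCounts))
        sharedCounts <- lapply(seq_len(nrow(sharedCounts)), function(i)
            list(clones = as.integer(strsplit(
                     sharedCounts$clones[i], "+", fixed = TRUE)[[1]]),
                 count = sharedCounts$count[i]))
    peaks <- list()
    for (entry in sharedCounts) {
        idx <- entry$clones
        if (!length(idx) || any(idx < 1 | idx > K))
            stop("subset indices must address the clone vector")
        if (entry$count == 0) next
        kpos <- sum(cloneSizes[idx])
        key <- as.character(kpos)
        lab <- paste(sort(idx), collapse = "+")
        if (is.null(peaks[[key]]))
            peaks[[key]] <- list(k = kpos, height = 0, subsets = character(0))
        peaks[[key]]$height <- peaks[[key]]$height + entry$count
        peaks[[key]]$subsets <- c(peaks[[key]]$subsets, lab)
    }
    if (!length(peaks))
        return(data.frame(k = numeric(0), height = numeric(0),
                          subsets = character(0)))
    out <- data.frame(
        k = vapply(peaks, `[[`, numeric(1), "k"),
        height = vapply(peaks, `[[`, numeric(1), "height"),
        subsets = vapply(peaks, function(p)
            paste(p$subsets, collapse = ";"), character(1)))
    out <- out[order(out$k), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Shared-ancestry mutation counts of surviving resistant clones
#'
#' For every tree node outside all clones that has alive descendants, the
#' mutations on its branch are clonal in exactly the clones whose founders
#' lie below it; accumulated over nodes this yields the heights \eqn{C_Y}
#' feeding [predictSfsPeaks()]. Meaningful when the sensitive population
#' has died out (all alive cells resistant).
#'
#' @param tree a [LineageTree-class].
#' @return list with \code{clones} (the per-clone record of
#'   [csdFromTree()]) and \code{shared}, a data.frame with columns
#'   \code{clones} (subset label "i+j+...") and \code{count}.
#' @export
cloneSharedCounts <- function(tree) {
    csd <- csdFromTree(tree)
    rec <- csd@clones
    K <- nrow(rec)
    if (K == 0)
        return(list(clones = rec,
                    shared = data.frame(clones = character(0),
                                        count = numeric(0))))
    if (K > 15) stop("more than 15 surviving clones")
    n <- length(tree@parent)
    ## bitmask of surviving founders below (or at) each node
    mask <- integer(n)
    mask[rec$founder] <- bitwShiftL(1L, rec$order - 1L)
    kAlive <- cpp_alive_descendants(tree@parent, tree@alive)
    if (n >= 2) {
        for (i in n:2) {
            p <- tree@parent[i]
            mask[p] <- bitwOr(mask[p], mask[i])
        }
    }
    ## nodes inside a clone (strictly below a founder) are excluded: their
    ## mutations are subclonal within one clone
    inside <- logical(n)
    isFounder <- logical(n); isFounder[rec$founder] <- TRUE
    if (n >= 2) {
        for (i in 2:n) {
            p <- tree@parent[i]
            inside[i] <- inside[p] || isFounder[p]
        }
    }
    sel <- which(!inside & kAlive > 0L & mask > 0L & tree@nmut > 0L)
    agg <- rowsum(as.numeric(tree@nmut[sel]), mask[sel])
    lab <- vapply(as.integer(rownames(agg)), function(mk)
        paste(which(bitwAnd(mk, bitwShiftL(1L, 0:(K - 1))) > 0L),
              collapse = "+"), character(1))
    list(clones = rec,
         shared = data.frame(clones = lab, count = agg[, 1]))
}

#' Expected scMB distribution of a multiclonal population
#'
#' Overlay of the sensitive compartment and one Poisson-mixture burden
#' distribution per resistant clone: \eqn{E[M_j] = E[M_j^S] + \sum_i
#' \kappa_i \, \mathrm{PoissMix}(j; \lambda_i, m)}, where \eqn{\lambda_i}
#' is clone i's mean division count. Clones sharing one birth rate merge
#' into a single shifted peak next to the sensitive peak; a clone-specific
#' birth rate splits them apart.
#'
#' @param clones data.frame with columns \code{size} and \code{lambda}
#'   (expected divisions per cell of that clone).
#' @param m mean mutations per daughter per division.
#' @param sensitive optional [BurdenDistribution-class] of the sensitive
#'   compartment (expected counts); NULL for none.
#' @param jmax largest burden evaluated.
#' @return a [BurdenDistribution-class] of expected counts.
#' @export
scmbMixture <- function(clones, m, sensitive = NULL, jmax = NULL) {
    if (!all(c("size", "lambda") %in% names(clones)))
        stop("clones needs columns size and lambda")
    if (is.null(jmax)) {
        mu <- max(c(m * clones$lambda,
                    if (!is.null(sensitive))
                        spectrumIndex(sensitive)[
                            which(sensitive@counts > 0)]), 1)
        jmax <- ceiling(max(mu) + 10 * sqrt(max(mu)) + 10)
    }
    M <- numeric(jmax + 1)
    Ntot <- 0
    for (i in seq_len(nrow(clones))) {
        div <- .divModel(clones$lambda[i], clones$size[i], "clone")
        sc <- scmbFromDivisional(div, m, jmax = jmax)
        M <- M + sc@counts
        Ntot <- Ntot + clones$size[i]
    }
    if (!is.null(sensitive)) {
        stopifnot(is(sensitive, "BurdenDistribution"))
        sc <- sensitive@counts
        len <- min(length(sc), jmax + 1)
        M[seq_len(len)] <- M[seq_len(len)] + sc[seq_len(len)]
        Ntot <- Ntot + sensitive@popSize
    }
    burdenDistribution(M, popSize = Ntot, metadata = list(m = m))
}
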