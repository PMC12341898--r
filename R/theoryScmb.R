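## Poisson-mixture predictions for the divisional distribution and the
## single-cell mutational burden distribution, with the fixed-size
## correction and the lineage inspection bias.

#' Mean-field divisional distribution at fixed time
#'
#' The probability that a randomly picked alive cell has undergone
#' \eqn{l} divisions after time \eqn{t} is Poisson with mean \eqn{2bt}:
#' twice the naive \eqn{bt}, because prolific lineages are overrepresented
#' among living cells (inspection bias). Death rates do not enter; only the
#' birth rate sets the divisional clock.
#'
#' @param b birth rate.
#' @param t elapsed time.
#' @param N population size used to scale \eqn{E[D_l] = N P_l}.
#' @return a [DivisionalDistribution-class] carrying \eqn{E[D_l]} with the
#'   Poisson mean in the metadata.
#' @export
divisionalMeanfield <- function(b, t, N = 1) {
    if (b < 0 || t < 0) stop("b and t must be >= 0")
    .divModel(2 * b * t, N, regime = "fixed-time mean-field")
}

.divModel <- function(lambda, N, regime) {
    lmax <- if (lambda == 0) 0 else ceiling(lambda + 10 * sqrt(lambda) + 10)
    P <- stats::dpois(0:lmax, lambda)
    divisionalDistribution(N * P, popSize = N,
        metadata = list(poissonMean = lambda, regime = regime))
}

#' Divisional distribution at fixed detection size
#'
#' Fixed-size observation shifts the mean-field divisional mean by the
#' constant 2: \eqn{P_l \sim \mathrm{Poiss}(2 b t_d - 2)} with \eqn{t_d}
#' the mean first-passage time to \code{Nd}. (The exact pure-birth mean is
#' \eqn{2(H_{N_d} - 1)}; the fixed-time correction constant is \eqn{\ln 4}
#' instead, see [divisionalExactMean()].) A negative adjusted mean (tiny
#' \code{Nd}) is clamped to 0 with a warning.
#'
#' @param b,d supercritical birth/death rates of the growth phase.
#' @param Nd detection size, >= 2.
#' @return a [DivisionalDistribution-class] on \code{Nd} cells.
#' @export
divisionalFixedSize <- function(b, d, Nd) {
    td <- firstPassageMean(ratePair(b, d), Nd)
    lambda <- 2 * b * td - 2
    if (lambda < 0) {
        warning("adjusted divisional mean below 0 for Nd = ", Nd,
                "; clamped to 0")
        lambda <- 0
    }
    .divModel(lambda, Nd, regime = "fixed-size detection")
}

#' Exact mean division count of a pure-birth population at fixed size
#'
#' \eqn{E[\bar l] = 2 (H_{N_d} - 1)} with \eqn{H_N} the harmonic number;
#' the mean-field fixed-time value exceeds it by \eqn{\ln 4} and the
#' fixed-size correction in [divisionalFixedSize()] by the constant 2.
#'
#' @param Nd population size.
#' @return exact expected mean number of divisions per cell.
#' @examples
#' divisionalExactMean(4)  # 13/6
#' @export
divisionalExactMean <- function(Nd) {
    2 * (sum(1 / seq_len(Nd)) - 1)
}

#' Offset constants of the mean-field divisional mean
#'
#' The mean-field divisional mean \eqn{2bt} exceeds the exact pure-birth
#' solution \eqn{2(H_{N} - 1)} by a constant: 2 when conditioning on fixed
#' size, \eqn{\ln 4} when conditioning on fixed time.
#'
#' @format named numeric of length 2, \code{fixedSize} and \code{fixedTime}.
#' @export
divisionalOffsetConstants <- c(fixedSize = 2, fixedTime = log(4))

#' Divisional distribution after homogeneous treatment
#'
#' Divisions made during treatment add \eqn{2 b_2 t_f} to the detection
#' mean: \eqn{P_l \sim \mathrm{Poiss}((2 b_1 t_d - 2) + 2 b_2 t_f)}. The
#' treatment time may be given directly (\code{tf}) or derived from sizes
#' as \eqn{t_f = \ln(N_f/N_d)/(b_2 - d_2)} (impossible for \eqn{b_2 =
#' d_2}, where \code{tf} is required).
#'
#' @param modelDetection a [DivisionalDistribution-class] from
#'   [divisionalFixedSize()] (or [divisionalMeanfield()]).
#' @param b2,d2 treatment-phase rates.
#' @param tf treatment duration; if NULL, derived from \code{Nd}/\code{Nf}.
#' @param Nd,Nf start/end sizes of treatment (used when \code{tf} is NULL
#'   and for the output population size).
#' @return a [DivisionalDistribution-class].
#' @export
divisionalAfterTreatment <- function(modelDetection, b2, d2, tf = NULL,
                                     Nd = NULL, Nf = NULL) {
    stopifnot(is(modelDetection, "DivisionalDistribution"))
    lambda0 <- modelDetection@metadata$poissonMean
    if (is.null(lambda0)) stop("modelDetection carries no Poisson mean")
    if (is.null(tf)) {
        if (is.null(Nd) || is.null(Nf))
            stop("give tf directly, or both Nd and Nf")
        if (.isCritical(b2, d2))
            stop("b2 = d2: sizes do not determine the duration, give tf")
        tf <- log(Nf / Nd) / (b2 - d2)
        if (tf < 0) stop("inconsistent sizes for the sign of b2 - d2")
    }
    N <- if (!is.null(Nf)) Nf else modelDetection@popSize
    .divModel(lambda0 + 2 * b2 * tf, N, regime = "after treatment")
}

#' Expected scMB distribution from a divisional distribution
#'
#' Each cell with \eqn{l} divisions carries Poisson(\eqn{l m}) mutations,
#' so \eqn{E[M_j] = \sum_l E[D_l] \, \mathrm{Poiss}(j; l m)}: a Poisson
#' mixture whose mean is \eqn{m \lambda} and which is overdispersed
#' relative to a single Poisson whenever the divisional law has positive
#' variance. The sum over \eqn{l} is truncated at mean + 10 SD.
#'
#' @param model a [DivisionalDistribution-class] (counts \eqn{E[D_l]}).
#' @param m mean mutations per daughter per division.
#' @param jmax largest burden evaluated (default: mixture mean + 10 SD).
#' @return a [BurdenDistribution-class] of expected counts \eqn{E[M_j]},
#'   \eqn{j = 0, \dots}.
#' @export
scmbFromDivisional <- function(model, m, jmax = NULL) {
    stopifnot(is(model, "DivisionalDistribution"))
    if (m < 0) stop("m must be >= 0")
    D <- model@counts
    ls <- spectrumIndex(model)
    if (is.null(jmax)) {
        mu <- m * sum(ls * D) / max(sum(D), .Machine$double.xmin)
        jmax <- ceiling(mu + 10 * sqrt(max(mu, 1)) + 10)
    }
    j <- 0:jmax
    M <- numeric(jmax + 1)
    for (i in seq_along(ls)) {
        if (D[i] == 0) next
        M <- M + D[i] * stats::dpois(j, ls[i] * m)
    }
    burdenDistribution(M, popSize = model@popSize,
        metadata = list(m = m, divisionalMean = model@metadata$poissonMean))
}
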