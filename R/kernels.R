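## Closed-form and numerical building blocks of the linear birth-death
## process: extinction probabilities, survival-conditioned growth, transition
## probabilities p(a -> n, t), and Gumbel first-passage times.

## Euler-Mascheroni constant, to double precision
.EULER_GAMMA <- 0.5772156649015329

## relative-tolerance switch for the critical case b = d, guarding the
## generic branch against catastrophic cancellation
.isCritical <- function(b, d) {
    ref <- max(b, d)
    ref == 0 || abs(b - d) / ref < 1e-12
}

## single-ancestor parameters of the linear birth-death process at time t:
## alpha = P(extinct by t), beta = geometric parameter of the offspring law
## p(1 -> 0) = alpha, p(1 -> n) = (1 - alpha)(1 - beta) beta^(n-1), n >= 1
.alphaBeta <- function(b, d, t) {
    if (t == 0) return(list(alpha = 0, beta = 0))
    if (.isCritical(b, d)) {
        bt <- b * t
        a <- bt / (1 + bt)
        return(list(alpha = a, beta = a))
    }
    ert <- exp((b - d) * t)
    den <- b * ert - d
    list(alpha = d * (ert - 1) / den, beta = b * (ert - 1) / den)
}

.checkRates <- function(rates) {
    stopifnot(is(rates, "RatePair"))
    validObject(rates)
    c(b = rates@birth, d = rates@death)
}

#' Extinction probability of a birth-death population
#'
#' Probability that a population of initial size \code{a} with constant
#' birth/death rates is extinct by time \code{t}, \eqn{\alpha(t)^a}, with
#' \eqn{\alpha(t) = d(e^{(b-d)t}-1)/(b e^{(b-d)t}-d)} for \eqn{b \ne d} and
#' \eqn{\alpha(t) = bt/(1+bt)} at criticality. The critical case is its own
#' closed-form branch; the two branches join continuously.
#'
#' @param rates a [RatePair-class].
#' @param t elapsed time, >= 0 (vectorized).
#' @param a initial population size, integer >= 1.
#' @return extinction probability in [0, 1].
#' @examples
#' extinctionProbability(ratePair(1, 0.5), t = 100)  # -> d/b = 0.5
#' @export
extinctionProbability <- function(rates, t, a = 1) {
    bd <- .checkRates(rates)
    if (any(t < 0)) stop("t must be nonnegative")
    if (length(a) != 1 || a < 1 || a != round(a))
        stop("a must be a single integer >= 1")
    vapply(t, function(ti) .alphaBeta(bd["b"], bd["d"], ti)$alpha,
           numeric(1))^a
}

#' Mean population size conditioned on survival
#'
#' \eqn{\tilde N(t) = a e^{(b-d)t} / (1 - \alpha(t)^a)}: the average size of
#' trajectories that have not gone extinct by time \code{t}. Always at least
#' the unconditional mean \eqn{a e^{(b-d)t}}.
#'
#' @inheritParams extinctionProbability
#' @return conditioned expected size.
#' @export
conditionedMeanSize <- function(rates, t, a = 1) {
    bd <- .checkRates(rates)
    if (any(t < 0)) stop("t must be nonnegative")
    if (length(a) != 1 || a < 1) stop("a must be a single integer >= 1")
    surv <- 1 - extinctionProbability(rates, t, a)
    unname(a * exp((bd["b"] - bd["d"]) * t) / surv)
}

## log-space stable evaluation of the exact a-ancestor transition mass
## p(a -> n, t) = sum_j C(a,j) C(n-1,j-1) alpha^(a-j) beta^(n-j)
##               ((1-alpha)(1-beta))^j                         (n >= 1)
.pExactSum <- function(a, n, alpha, beta) {
    la <- log(alpha); lb <- log(beta)
    l1a <- log1p(-alpha); l1b <- log1p(-beta)
    vapply(n, function(ni) {
        if (ni == 0) return(alpha^a)
        j <- seq_len(min(a, ni))
        lt <- lchoose(a, j) + lchoose(ni - 1, j - 1) + (a - j) * la +
            (ni - j) * lb + j * (l1a + l1b)
        if (alpha == 0) lt[j < a] <- -Inf   # only j = a contributes
        M <- max(lt)
        if (!is.finite(M)) return(0)
        exp(M) * sum(exp(lt - M))
    }, numeric(1))
}

## saddlepoint approximation on the cumulant generating function
## K(theta) = a log G(e^theta) of the a-fold offspring law, with
## G(s) = alpha + (1-alpha)(1-beta) s / (1 - beta s); vectorized
## safeguarded Newton for K'(theta) = n on theta in (-Inf, -log beta)
.pSaddle <- function(a, n, alpha, beta) {
    thetaHi <- -log(beta) - 1e-10
    theta <- rep(0, length(n))
    lo <- rep(-50, length(n))
    hi <- rep(thetaHi, length(n))
    for (iter in 1:200) {
        s <- exp(theta); u <- 1 - beta * s
        G <- alpha + (1 - alpha) * (1 - beta) * s / u
        G1 <- (1 - alpha) * (1 - beta) / u^2
        G2 <- 2 * beta * G1 / u
        Kp <- a * s * G1 / G
        lo <- ifelse(Kp < n, pmax(lo, theta), lo)
        hi <- ifelse(Kp > n, pmin(hi, theta), hi)
        Kpp <- a * ((s * G1 + s^2 * G2) * G - (s * G1)^2) / G^2
        thetaNew <- theta - (Kp - n) / Kpp
        bad <- !is.finite(thetaNew) | thetaNew <= lo | thetaNew >= hi
        thetaNew[bad] <- (lo[bad] + hi[bad]) / 2
        if (max(abs(thetaNew - theta)) < 1e-13) { theta <- thetaNew; break }
        theta <- thetaNew
    }
    s <- exp(theta); u <- 1 - beta * s
    G <- alpha + (1 - alpha) * (1 - beta) * s / u
    G1 <- (1 - alpha) * (1 - beta) / u^2
    G2 <- 2 * beta * G1 / u
    Kp <- a * s * G1 / G
    if (max(abs(Kp - n) / pmax(n, 1)) > 1e-6)
        stop("saddlepoint equation K'(theta) = n did not converge")
    Kpp <- a * ((s * G1 + s^2 * G2) * G - (s * G1)^2) / G^2
    exp(a * log(G) - n * theta) / sqrt(2 * pi * Kpp)
}

## support truncation for saddlepoint renormalization: [1, mean + 12 SD]
.saddleSupport <- function(a, b, d, t) {
    mean1 <- exp((b - d) * t)
    v1 <- if (.isCritical(b, d)) 2 * b * t
          else ((b + d) / (b - d)) * mean1 * (mean1 - 1)
    mu <- a * mean1
    sdv <- sqrt(a * v1)
    c(lower = max(1, floor(mu - 12 * sdv)), upper = ceiling(mu + 12 * sdv))
}

#' Transition probability of the linear birth-death process
#'
#' \eqn{p(a \to n, t)}: probability that a population of size \code{a} has
#' size \code{n} after time \code{t}. Dispatches between closed forms (pure
#' birth, pure death, single ancestor), an exact log-space stable sum for
#' \eqn{\min(a, n) \le} \code{exactCutoff}, and a renormalized saddlepoint
#' approximation beyond it. The saddlepoint mass is renormalized over
#' \eqn{n \in [1, \mathrm{mean} + 12\,\mathrm{SD}]} against the exact
#' survival probability \eqn{1 - \alpha(t)^a}.
#'
#' @param kernel a [TransitionKernel-class] (or a [RatePair-class], which is
#'   promoted with default settings).
#' @param a starting size, integer >= 1.
#' @param n final size(s), integer >= 0 (vectorized).
#' @param t elapsed time, >= 0.
#' @return vector of probabilities, one per element of \code{n}.
#' @examples
#' transitionProbability(ratePair(1, 0), a = 1, n = 2, t = log(2))  # 0.25
#' @export
transitionProbability <- function(kernel, a, n, t) {
    if (is(kernel, "RatePair")) kernel <- transitionKernel(kernel)
    stopifnot(is(kernel, "TransitionKernel"))
    b <- kernel@rates@birth; d <- kernel@rates@death
    if (length(a) != 1 || a < 1 || a != round(a))
        stop("a must be a single integer >= 1")
    if (any(n < 0) || any(n != round(n))) stop("n must be integers >= 0")
    if (length(t) != 1 || t < 0) stop("t must be a single nonnegative time")

    if (t == 0) return(as.numeric(n == a))
    if (b == 0 && d == 0) return(as.numeric(n == a))

    if (d == 0) {  # pure birth: shifted negative binomial
        p <- numeric(length(n))
        ok <- n >= a
        p[ok] <- exp(lchoose(n[ok] - 1, a - 1) - a * b * t +
                     (n[ok] - a) * log1p(-exp(-b * t)))
        return(p)
    }
    if (b == 0)  # pure death: binomial thinning with survival prob e^(-dt)
        return(stats::dbinom(n, a, exp(-d * t)))

    ab <- .alphaBeta(b, d, t)
    alpha <- ab$alpha; beta <- ab$beta
    if (a == 1) {
        p <- ifelse(n == 0, alpha,
                    (1 - alpha) * (1 - beta) * beta^(pmax(n, 1) - 1))
        return(as.numeric(p))
    }
    p <- numeric(length(n))
    exact <- pmin(a, n) <= kernel@exactCutoff
    if (any(exact))
        p[exact] <- .pExactSum(a, n[exact], alpha, beta)
    if (any(!exact)) {
        ps <- .pSaddle(a, n[!exact], alpha, beta)
        if (kernel@renormalize) {
            sup <- .saddleSupport(a, b, d, t)
            grid <- seq(sup["lower"], sup["upper"])
            Z <- sum(.pSaddle(a, grid, alpha, beta))
            ps <- ps * (1 - alpha^a) / Z
        }
        p[!exact] <- ps
    }
    p
}

#' Mean first-passage time to a target size
#'
#' Expected time for a supercritical birth-death population started from a
#' single cell to first reach size \code{N}, conditioned on survival:
#' \eqn{E[T_N] = (\ln((b-d)N/b) + \gamma) / (b-d)} with \eqn{\gamma} the
#' Euler-Mascheroni constant.
#'
#' @param rates supercritical [RatePair-class] (birth > death).
#' @param N target size, >= 2.
#' @return expected first-passage time.
#' @examples
#' firstPassageMean(ratePair(1, 0), 100)  # log(100) + 0.5772...
#' @export
firstPassageMean <- function(rates, N) {
    bd <- .checkRates(rates)
    if (bd["b"] <= bd["d"])
        stop("first-passage mean requires supercritical rates (b > d)")
    if (any(N < 2)) stop("N must be >= 2")
    r <- bd["b"] - bd["d"]
    unname((log(r * N / bd["b"]) + .EULER_GAMMA) / r)
}

#' Gumbel density of the first-passage time
#'
#' Density of the time to first reach \code{targetSize}, approximated by a
#' Gumbel distribution with scale \eqn{1/(b-d)} and location chosen so the
#' mean matches [firstPassageMean()].
#'
#' @param model a [FirstPassageModel-class].
#' @param t evaluation time(s).
#' @return density values.
#' @export
firstPassageDensity <- function(model, t) {
    stopifnot(is(model, "FirstPassageModel"))
    validObject(model)
    b <- model@rates@birth; d <- model@rates@death
    sigma <- 1 / (b - d)
    mu <- firstPassageMean(model@rates, model@targetSize) -
        .EULER_GAMMA * sigma
    z <- (t - mu) / sigma
    exp(-(z + exp(-z))) / sigma
}

#' Convert a fixed-time expectation into a fixed-size expectation
#'
#' Integrates a fixed-time statistic against the first-passage density of
#' the target size: \eqn{\int_0^\infty g(t) f_{T_N}(t) \, dt}, by adaptive
#' quadrature at relative tolerance \code{relTol}.
#'
#' @param statistic function of time returning the fixed-time expectation;
#'   need not be vectorized.
#' @param model a [FirstPassageModel-class].
#' @param relTol relative quadrature tolerance (default 1e-3).
#' @return the fixed-size expectation.
#' @export
fixedSizeExpectation <- function(statistic, model, relTol = 1e-3) {
    stopifnot(is(model, "FirstPassageModel"))
    b <- model@rates@birth; d <- model@rates@death
    sigma <- 1 / (b - d)
    mu <- firstPassageMean(model@rates, model@targetSize) -
        .EULER_GAMMA * sigma
    f <- function(tt) vapply(tt, statistic, numeric(1)) *
        firstPassageDensity(model, tt)
    lower <- max(0, mu - 12 * sigma)
    upper <- mu + 40 * sigma
    res <- stats::integrate(f, lower, upper, rel.tol = relTol,
                            subdivisions = 500L)
    if (res$message != "OK")
        stop("fixed-size quadrature failed: ", res$message)
    res$value
}
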