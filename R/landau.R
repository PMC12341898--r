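## The standard Landau distribution, evaluated numerically from its
## integral representation. It arises here as the large-population,
## small-mutation-rate limit of the Luria-Delbruck law for the total number
## of resistant cells: a unimodal density with a fat 1/x^2 right tail (no
## finite mean).

#' The standard Landau distribution
#'
#' Density, distribution function and quantile function of the standard
#' Landau distribution, computed by adaptive quadrature of
#' \deqn{p(x) = \frac{1}{\pi} \int_0^\infty e^{-t \log t - x t}
#' \sin(\pi t) \, dt.}
#' The density has its mode near \eqn{x \approx -0.223}, median
#' \eqn{\approx 1.356}, and decays like \eqn{x^{-2}} on the right, so no
#' moments exist.
#'
#' @param x,q evaluation points (vectorized).
#' @param p probabilities (vectorized).
#' @return density, cumulative probability, or quantile values.
#' @examples
#' qlandau(0.5)  # median, about 1.356
#' @export
dlandau <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi)) return(0)
        if (xi < -7) return(0)  # left tail decays doubly exponentially
        if (xi > 20) {
            ## far right tail: substituting u = x t in the sine
            ## representation confines the mass to u = O(1) within the
            ## first sine arch, no cancellation
            res <- stats::integrate(function(u) {
                t <- u / xi
                tl <- ifelse(t > 0, t * log(t), 0)
                exp(-tl - u) * sin(pi * t) / xi
            }, 0, Inf, rel.tol = 1e-10, subdivisions = 2000L,
                stop.on.error = FALSE)
            return(max(res$value / pi, 0))
        }
        ## Bromwich form p(x) = (1/pi) Int_0^infty Re exp(s log s + x s) dy
        ## with s = c + iy; the contour through the real saddle point
        ## c = e^(-1-x) is non-oscillatory and decays like e^(-pi y / 2)
        cc <- exp(-1 - xi)
        f <- function(y) {
            s <- complex(real = cc, imaginary = y)
            Re(exp(s * log(s) + xi * s))
        }
        res <- stats::integrate(f, 0, Inf, rel.tol = 1e-9,
                                abs.tol = 1e-15, subdivisions = 2000L,
                                stop.on.error = FALSE)
        if (!res$message %in% c("OK", "roundoff error was detected"))
            stop("Landau quadrature failed at x = ", xi, ": ", res$message)
        max(res$value / pi, 0)
    }, numeric(1))
}

#' @rdname dlandau
#' @export
plandau <- function(q) {
    vapply(q, function(qi) {
        if (qi <= -6) return(0)
        if (!is.finite(qi)) return(1)
        v <- stats::integrate(function(u) dlandau(u), -6, qi,
                              rel.tol = 1e-7, subdivisions = 500L)$value
        min(max(v, 0), 1)
    }, numeric(1))
}

#' @rdname dlandau
#' @export
qlandau <- function(p) {
    vapply(p, function(pi_) {
        if (pi_ <= 0 || pi_ >= 1) stop("p must be in (0, 1)")
        ## expanding upper bracket for the heavy right tail
        hi <- 10
        while (plandau(hi) < pi_ && hi < 1e9) hi <- hi * 4
        stats::uniroot(function(x) plandau(x) - pi_, c(-6, hi),
                       tol = 1e-8)$root
    }, numeric(1))
}
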