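#' Zero-truncated negative binomial distribution
#'
#' Log probability mass of the negative binomial distribution conditioned
#' on a strictly positive count — the natural size distribution for tumor
#' lesions, which contain at least one cell. With
#' \eqn{NB(y; \mu, \theta) = \frac{\Gamma(y+\theta)}{\Gamma(\theta)\,y!}
#' \left(\frac{\theta}{\theta+\mu}\right)^\theta
#' \left(\frac{\mu}{\theta+\mu}\right)^y}
#' the truncated mass is \eqn{NB(y)/(1 - NB(0))} for \eqn{y \ge 1}.
#' Everything is computed in log space; the zero mass is evaluated as
#' \eqn{\exp(-\theta \log(1+\mu/\theta))} so the function stays stable up to
#' \eqn{\theta = 10^6}, where it converges to the zero-truncated Poisson.
#'
#' @param y integer counts, all \eqn{\ge 1}.
#' @param mu positive NB mean (before truncation).
#' @param theta positive NB dispersion.
#' @return log pmf values, recycled over the longest argument.
#' @examples
#' ztnbLogPmf(1, 1, 1)  # log(1/2): zero-truncated geometric
#' @export
ztnbLogPmf <- function(y, mu, theta) {
    if (any(y < 1) || any(y != floor(y)))
        stop("y must be integer counts >= 1 (0 is outside the support)",
             call. = FALSE)
    stopIfNot(all(mu > 0) && all(theta > 0), "mu and theta must be positive")
    logp0 <- -theta * log1p(mu / theta)
    lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        logp0 + y * (log(mu) - log(theta + mu)) - log1mexp(logp0)
}

#' @describeIn ztnbLogPmf mean of the zero-truncated distribution,
#'   \eqn{\mu / (1 - (\theta/(\theta+\mu))^\theta)}.
#' @export
ztnbMean <- function(mu, theta) {
    mu / (1 - exp(-theta * log1p(mu / theta)))
}

#' @describeIn ztnbLogPmf draw zero-truncated NB deviates (rejection of
#'   zeros; uses the current RNG state).
#' @param n number of draws.
#' @export
rztnb <- function(n, mu, theta) {
    x <- stats::rnbinom(n, mu = mu, size = theta)
    while (any(zero <- x == 0))
        x[zero] <- stats::rnbinom(sum(zero), mu = mu, size = theta)
    x
}
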