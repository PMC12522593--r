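# Zero-inflated negative binomial distribution utilities.
#
# Parameterization: structural-zero probability pi, NB mean mu and
# dispersion size, with variance mu + mu^2/size (size = Inf collapses the
# NB component to Poisson). pi = 0 gives plain NB/Poisson.

.dnb <- function(x, mu, size, log = FALSE) {
    if (is.infinite(size)) stats::dpois(x, mu, log = log)
    else stats::dnbinom(x, mu = mu, size = size, log = log)
}

.pnb <- function(q, mu, size) {
    if (is.infinite(size)) stats::ppois(q, mu)
    else stats::pnbinom(q, mu = mu, size = size)
}

.qnb <- function(p, mu, size) {
    if (mu == 0) return(rep(0, length(p)))
    if (is.infinite(size)) stats::qpois(p, mu)
    else stats::qnbinom(p, mu = mu, size = size)
}

#' Zero-inflated negative binomial distribution
#'
#' Density, distribution function and quantile function for the
#' zero-inflated negative binomial with structural-zero probability
#' \code{pi}, mean \code{mu} and dispersion \code{size}
#' (variance = mu + mu^2/size). \code{size = Inf} gives the zero-inflated
#' Poisson; \code{pi = 0} the plain NB/Poisson.
#'
#' @param x,q non-negative integer quantiles.
#' @param p probabilities.
#' @param pi structural-zero probability in [0, 1].
#' @param mu mean of the count component (>= 0).
#' @param size dispersion (> 0, may be Inf).
#' @param log log-density flag.
#' @return numeric vector.
#' @name ZINB
NULL

#' @rdname ZINB
#' @export
dzinb <- function(x, pi, mu, size, log = FALSE) {
    d <- (1 - pi) * .dnb(x, mu, size)
    d[x == 0] <- d[x == 0] + pi
    if (log) base::log(d) else d
}

#' @rdname ZINB
#' @export
pzinb <- function(q, pi, mu, size) {
    out <- numeric(length(q))
    neg <- q < 0
    out[!neg] <- pi + (1 - pi) * .pnb(q[!neg], mu, size)
    out
}

#' @rdname ZINB
#' @export
qzinb <- function(p, pi, mu, size) {
    out <- numeric(length(p))
    pos <- p > pi
    if (any(pos))
        out[pos] <- .qnb((p[pos] - pi) / (1 - pi), mu, size)
    out
}

# Weighted ZINB/NB negative log-likelihoods on the value/count summary of a
# gene (counts collapse ties; crucial for speed on thousands of cells).
.negll_zinb <- function(par, vals, wts) {
    pi <- stats::plogis(par[1L]); mu <- exp(par[2L]); size <- exp(par[3L])
    if (!is.finite(mu) || !is.finite(size) || size > 1e8) return(1e10)
    ll <- sum(wts * dzinb(vals, pi, mu, size, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
}

.negll_nb <- function(par, vals, wts) {
    mu <- exp(par[1L]); size <- exp(par[2L])
    if (!is.finite(mu) || !is.finite(size) || size > 1e8) return(1e10)
    ll <- sum(wts * .dnb(vals, mu, size, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
}

.negll_zip <- function(par, vals, wts) {
    pi <- stats::plogis(par[1L]); mu <- exp(par[2L])
    if (!is.finite(mu)) return(1e10)
    ll <- sum(wts * dzinb(vals, pi, mu, Inf, log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
}

#' Fit a count marginal with the ZINB fallback ladder
#'
#' Maximum-likelihood fit of a zero-inflated negative binomial to one
#' gene's counts, with a fallback ladder ZINB -> NB -> ZIP -> Poisson when
#' a component is unidentifiable: the zero-inflation component is dropped
#' when the data contain no excess zeros, and the dispersion component
#' when the variance is indistinguishable from the mean. Identifiability is
#' adjudicated by BIC among the candidate families (so the extra parameter
#' must earn its keep), which collapses to the simpler family for Poisson
#' or NB data. An all-zero gene is recorded as ZIP with pi = 1 and mean 0.
#'
#' @param y non-negative integer vector (length >= 2).
#' @return one-row data.frame with columns \code{family} (\code{"zinb"},
#'   \code{"nb"}, \code{"zip"}, \code{"poisson"}), \code{pi}, \code{mu},
#'   \code{size}.
#' @examples
#' set.seed(1)
#' y <- ifelse(runif(2000) < 0.3, 0L, rnbinom(2000, mu = 5, size = 2))
#' fitMarginal(y)
#' @export
fitMarginal <- function(y) {
    .assert(length(y) >= 2L, "need at least 2 observations")
    .assert(all(y >= 0) && all(y == round(y)), "counts must be non-negative integers")
    tab <- table(y)
    vals <- as.numeric(names(tab)); wts <- as.numeric(tab)
    n <- length(y)
    m <- mean(y); v <- stats::var(y); zf <- mean(y == 0)
    if (m == 0)
        return(data.frame(family = "zip", pi = 1, mu = 0, size = Inf))
    size0 <- if (v > m) min(max(m^2 / (v - m), 1e-2), 1e3) else 1e3
    cand <- list()
    # poisson: closed-form MLE
    ll_pois <- sum(wts * stats::dpois(vals, m, log = TRUE))
    cand$poisson <- list(par = data.frame(family = "poisson", pi = 0,
                                          mu = m, size = Inf),
                         ll = ll_pois, k = 1L)
    fit_nb <- stats::optim(c(log(m), log(size0)), .negll_nb,
                           vals = vals, wts = wts,
                           control = list(maxit = 1000L))
    cand$nb <- list(par = data.frame(family = "nb", pi = 0,
                                     mu = exp(fit_nb$par[1L]),
                                     size = min(exp(fit_nb$par[2L]), 1e6)),
                    ll = -fit_nb$value, k = 2L)
    if (zf > 0) {
        p0 <- .dnb(0, m, size0)
        pi0 <- min(max((zf - p0) / (1 - p0 + 1e-12), 1e-3), 0.95)
        fit_zip <- stats::optim(c(stats::qlogis(max(zf / 2, 1e-3)),
                                  log(m / (1 - zf / 2))), .negll_zip,
                                vals = vals, wts = wts,
                                control = list(maxit = 1000L))
        cand$zip <- list(par = data.frame(
            family = "zip", pi = stats::plogis(fit_zip$par[1L]),
            mu = exp(fit_zip$par[2L]), size = Inf),
            ll = -fit_zip$value, k = 2L)
        fit_zinb <- stats::optim(c(stats::qlogis(pi0),
                                   log(m / (1 - pi0)), log(size0)),
                                 .negll_zinb, vals = vals, wts = wts,
                                 control = list(maxit = 1000L))
        cand$zinb <- list(par = data.frame(
            family = "zinb", pi = stats::plogis(fit_zinb$par[1L]),
            mu = exp(fit_zinb$par[2L]),
            size = min(exp(fit_zinb$par[3L]), 1e6)),
            ll = -fit_zinb$value, k = 3L)
    }
    bic <- vapply(cand, function(cc) cc$k * log(n) - 2 * cc$ll, numeric(1))
    cand[[which.min(bic)]]$par
}
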