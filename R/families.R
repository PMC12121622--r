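#' Count distribution families
#'
#' Constructor for the count families used throughout the package: Poisson,
#' negative binomial (NB2) and the restricted generalized Poisson (GP-1).
#' All three are parameterized by their mean `mu` so that regression
#' coefficients are log risk ratios regardless of the family.
#'
#' The NB2 family has variance \eqn{\mu + \alpha\mu^2}; `alpha = 0` recovers
#' the Poisson. The generalized Poisson (Consul--Famoye, restricted form)
#' has pmf
#' \deqn{P(Y=y) = \theta(\theta+\delta y)^{y-1} e^{-\theta-\delta y}/y!}
#' with \eqn{\theta = \mu(1-\delta)}, giving mean \eqn{\mu} and variance
#' \eqn{\mu/(1-\delta)^2}; `delta = 0` recovers the Poisson, `delta > 0`
#' gives overdispersion and `delta < 0` underdispersion. The admissible
#' dispersion region is `max(-1, -mu/4) < delta < 1`; for negative `delta`
#' the support is finitely truncated and the pmf is only approximately
#' normalized, which is the standard behaviour of this family.
#'
#' @param name one of `"poisson"`, `"negbin"`, `"genpoisson"`.
#' @param mu positive mean (may be a vector; recycled against `y` in the
#'   pmf functions).
#' @param alpha NB2 dispersion, `>= 0`. Ignored by the other families.
#' @param delta GP dispersion in `(max(-1, -mu/4), 1)`. Ignored by the
#'   other families.
#' @return an object of class `count_family`.
#' @examples
#' fam <- count_family("negbin", mu = 1.72, alpha = 0.5)
#' zero_prob(fam)  # (1 + 0.5 * 1.72)^-2
#' @export
count_family <- function(name = c("poisson", "negbin", "genpoisson"),
                         mu, alpha = 0, delta = 0) {
  name <- match.arg(name)
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("'mu' must be finite and non-negative", call. = FALSE)
  if (name == "negbin" && (length(alpha) != 1L || !is.finite(alpha) || alpha < 0))
    stop("NB2 dispersion 'alpha' must be a single non-negative number",
         call. = FALSE)
  if (name == "genpoisson") {
    lo <- max(-1, -min(mu) / 4)
    if (length(delta) != 1L || !is.finite(delta) || delta <= lo || delta >= 1)
      stop(sprintf("GP dispersion 'delta' must lie in (%.4g, 1)", lo),
           call. = FALSE)
  }
  structure(list(name = name, mu = mu, alpha = alpha, delta = delta),
            class = "count_family")
}

#' @export
print.count_family <- function(x, ...) {
  disp <- switch(x$name,
    poisson    = "",
    negbin     = sprintf(", alpha = %g", x$alpha),
    genpoisson = sprintf(", delta = %g", x$delta))
  cat(sprintf("<count_family: %s, mu = %s%s>\n", x$name,
              paste(signif(utils::head(x$mu, 3), 4), collapse = ", "), disp))
  invisible(x)
}

## Vectorized log-pmf working directly on (name, mu, disp); the exported
## generic wraps this. Kept separate so the fitting code can call it with
## per-subject mu vectors without building family objects in hot loops.
.log_pmf <- function(name, y, mu, alpha = 0, delta = 0) {
  switch(name,
    poisson = stats::dpois(y, mu, log = TRUE),
    negbin  = {
      if (alpha < 1e-12) {
        stats::dpois(y, mu, log = TRUE)
      } else {
        stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)
      }
    },
    genpoisson = {
      n <- max(length(y), length(mu))
      y <- rep_len(y, n); mu <- rep_len(mu, n)
      theta <- mu * (1 - delta)
      lam <- theta + delta * y
      out <- rep(-Inf, n)
      ok <- theta > 0 & lam > 0
      out[ok] <- (log(theta[ok]) + (y[ok] - 1) * log(lam[ok]) -
                    lam[ok] - lgamma(y[ok] + 1))
      out[theta == 0 & y == 0] <- 0    # degenerate point mass at zero
      out
    },
    stop("unknown family '", name, "'", call. = FALSE))
}

#' Log probability mass function
#'
#' Evaluated in log space so that the deep tails and the zero cell of
#' zero-heavy data never underflow.
#'
#' @param family a [count_family()] object.
#' @param y vector of non-negative integer counts.
#' @return vector of log-probabilities.
#' @export
log_pmf <- function(family, y) {
  stopifnot(inherits(family, "count_family"))
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integers", call. = FALSE)
  .log_pmf(family$name, y, family$mu, family$alpha, family$delta)
}

#' Probability of a zero count
#'
#' `exp(log_pmf(family, 0))`: the sampling-zero probability of the count
#' component, used for hurdle truncation and for calibrating the
#' sampling-zero rate of simulated scenarios.
#'
#' @inheritParams log_pmf
#' @return probability (vector if `mu` is a vector).
#' @export
zero_prob <- function(family) {
  stopifnot(inherits(family, "count_family"))
  exp(.log_pmf(family$name, rep(0, length(family$mu)), family$mu,
               family$alpha, family$delta))
}

#' Zero-truncated log pmf
#'
#' Log of \eqn{f(y) / (1 - f(0))} for `y >= 1`, the count distribution of
#' the positive part of a hurdle model.
#'
#' @inheritParams log_pmf
#' @param y vector of positive integer counts.
#' @return vector of log-probabilities; the truncated pmf sums to one over
#'   `y >= 1`.
#' @export
log_pmf_truncated <- function(family, y) {
  stopifnot(inherits(family, "count_family"))
  if (any(y < 1) || any(y != floor(y)))
    stop("truncated pmf is defined for positive integers only", call. = FALSE)
  lp0 <- .log_pmf(family$name, rep(0, length(family$mu)), family$mu,
                  family$alpha, family$delta)
  if (any(lp0 >= -1e-12))
    stop("zero probability is 1: truncated distribution is degenerate",
         call. = FALSE)
  .log_pmf(family$name, y, family$mu, family$alpha, family$delta) -
    log1p(-exp(lp0))
}
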