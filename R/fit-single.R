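## Single-distribution models: logistic regression on polyp presence and
## the Poisson / negative-binomial / generalized-Poisson count regressions.

.li_logistic <- function(data) {
  Z <- data$Z
  b <- as.numeric(data$y > 0)
  s <- 2 * b - 1
  function(par) {
    eta <- drop(Z %*% par)
    stats::plogis(s * eta, log.p = TRUE)
  }
}

.gr_logistic <- function(data) {
  Z <- data$Z
  b <- as.numeric(data$y > 0)
  function(par) drop(crossprod(Z, b - stats::plogis(drop(Z %*% par))))
}

.li_poisson <- function(data) {
  X <- data$X
  y <- data$y
  lgy <- lgamma(y + 1)
  function(par) {
    eta <- drop(X %*% par)
    y * eta - exp(eta) - lgy
  }
}

.gr_poisson <- function(data) {
  X <- data$X
  y <- data$y
  function(par) drop(crossprod(X, y - exp(drop(X %*% par))))
}

## NB2: par = (beta, log alpha)
.li_negbin <- function(data) {
  X <- data$X
  y <- data$y
  k <- ncol(X)
  function(par) {
    mu <- exp(drop(X %*% par[seq_len(k)]))
    .log_pmf("negbin", y, mu, alpha = exp(par[k + 1]))
  }
}

.gr_negbin <- function(data) {
  X <- data$X
  y <- data$y
  k <- ncol(X)
  function(par) {
    a <- exp(par[k + 1])
    r <- 1 / a
    mu <- exp(drop(X %*% par[seq_len(k)]))
    gb <- drop(crossprod(X, (y - mu) / (1 + a * mu)))
    dr <- digamma(y + r) - digamma(r) + log(r) + 1 -
      log(r + mu) - (y + r) / (r + mu)
    c(gb, -r * sum(dr))
  }
}

## restricted GP: par = (beta, d) with delta = 2 plogis(d) - 1
.gp_delta <- function(d) 2 * stats::plogis(d) - 1

.li_genpois <- function(data) {
  X <- data$X
  y <- data$y
  k <- ncol(X)
  function(par) {
    mu <- exp(drop(X %*% par[seq_len(k)]))
    .log_pmf("genpoisson", y, mu, delta = .gp_delta(par[k + 1]))
  }
}

#' Logistic regression on polyp presence
#'
#' Fits the standard binary model for the polyp detection rate: the
#' outcome is dichotomized internally as `y > 0` and regressed on the
#' odds-component design. Exponentiated coefficients are odds ratios.
#'
#' @param data a [polyp_data()] object.
#' @return a `polyp_fit` of kind `"LR"`.
#' @export
fit_logistic <- function(data) {
  stopifnot(inherits(data, "polyp_data"))
  b <- as.numeric(data$y > 0)
  start <- suppressWarnings(
    stats::glm.fit(data$Z, b, family = stats::binomial())$coefficients)
  li <- .li_logistic(data)
  res <- .mle_fit(li, start, .gr_logistic(data))
  if (any(abs(res$par) > 15) || !res$converged) {
    off <- colnames(data$Z)[which.max(abs(res$par))]
    stop("logistic fit unstable (possible perfect separation); ",
         "largest coefficient on '", off, "', gradient norm ",
         format(res$gradient_norm), call. = FALSE)
  }
  names(res$par) <- colnames(data$Z)
  fit <- .make_fit("LR", res$par, li, data, res$info, res$loglik,
                   res$converged, res$gradient_norm,
                   n_count = 0L, n_zero = ncol(data$Z))
  fit$li_builder <- .li_logistic
  fit
}

#' Single-distribution count regression
#'
#' Maximum-likelihood Poisson, NB2 or generalized-Poisson regression of
#' the polyp count on the count-component design
#' (`log E(polyps) = X beta`). Exponentiated coefficients are risk
#' ratios. With `robust = TRUE` the Poisson fit reports the Huber
#' sandwich variance (the "robust Poisson", RP); point estimates are
#' unchanged.
#'
#' @param data a [polyp_data()] object.
#' @param family `"poisson"`, `"negbin"` or `"genpoisson"`.
#' @param robust use [sandwich_vcov()] in place of the inverse observed
#'   information.
#' @return a `polyp_fit` of kind `"PR"`, `"RP"`, `"NB"` or `"GP"`.
#' @export
fit_count_glm <- function(data, family = c("poisson", "negbin", "genpoisson"),
                          robust = FALSE) {
  stopifnot(inherits(data, "polyp_data"))
  family <- match.arg(family)
  k <- ncol(data$X)
  pois_start <- suppressWarnings(
    stats::glm.fit(data$X, data$y, family = stats::poisson())$coefficients)

  if (family == "poisson") {
    li <- .li_poisson(data)
    res <- .mle_fit(li, pois_start, .gr_poisson(data))
    if (!res$converged)
      stop("Poisson fit did not converge; gradient norm ",
           format(res$gradient_norm), call. = FALSE)
    names(res$par) <- colnames(data$X)
    fit <- .make_fit(if (robust) "RP" else "PR", res$par, li, data,
                     res$info, res$loglik, res$converged, res$gradient_norm,
                     n_count = k, robust = robust)
    fit$li_builder <- .li_poisson
    return(fit)
  }

  mu0 <- exp(drop(data$X %*% pois_start))
  if (family == "negbin") {
    a0 <- max(sum((data$y - mu0)^2 - mu0) / sum(mu0^2), 1e-3)
    li <- .li_negbin(data)
    res <- .mle_fit(li, c(pois_start, log(a0)), .gr_negbin(data))
    if (.alpha_boundary(res$par[k + 1], res$converged)) {
      ## equidispersed data: the likelihood is flat towards alpha = 0;
      ## pin alpha and refit the Poisson counterpart for the coefficients
      warning("NB dispersion at the zero boundary; alpha reported as 0",
              call. = FALSE)
      li_p <- .li_poisson(data)
      res <- .mle_fit(li_p, pois_start, .gr_poisson(data))
      names(res$par) <- colnames(data$X)
      fit <- .make_fit("NB", res$par, li_p, data, res$info, res$loglik,
                       res$converged, res$gradient_norm, n_count = k,
                       dispersion = 0, dispersion_name = "alpha",
                       robust = robust)
      fit$n_params <- k + 1L            # alpha was estimated (boundary)
      fit$li_builder <- .li_poisson
      return(fit)
    }
    if (!res$converged)
      stop("NB fit did not converge; gradient norm ",
           format(res$gradient_norm), call. = FALSE)
    names(res$par) <- c(colnames(data$X), "log(alpha)")
    fit <- .make_fit("NB", res$par, li, data, res$info, res$loglik,
                     res$converged, res$gradient_norm, n_count = k,
                     dispersion = unname(exp(res$par[k + 1])),
                     dispersion_name = "alpha", robust = robust)
    fit$li_builder <- .li_negbin
    return(fit)
  }

  disp <- stats::var(data$y) / max(mean(data$y), 1e-8)
  delta0 <- 1 - 1 / sqrt(max(disp, 0.3))
  d0 <- stats::qlogis((min(max(delta0, -0.9), 0.9) + 1) / 2)
  li <- .li_genpois(data)
  res <- .mle_fit(li, c(pois_start, d0))
  if (!res$converged)
    stop("GP fit did not converge; gradient norm ",
         format(res$gradient_norm), call. = FALSE)
  names(res$par) <- c(colnames(data$X), "link(delta)")
  fit <- .make_fit("GP", res$par, li, data, res$info, res$loglik,
                   res$converged, res$gradient_norm, n_count = k,
                   dispersion = unname(.gp_delta(res$par[k + 1])),
                   dispersion_name = "delta", robust = robust)
  fit$li_builder <- .li_genpois
  fit
}

#' Fit any of the ten model kinds by name
#'
#' Dispatcher over [fit_logistic()], [fit_count_glm()],
#' [fit_zero_inflated()] and [fit_hurdle()], used by the model selector,
#' the Monte Carlo engine, the bootstrap and the command line.
#'
#' @param data a [polyp_data()] object.
#' @param kind one of `"LR"`, `"PR"`, `"RP"`, `"NB"`, `"GP"`, `"ZIP"`,
#'   `"ZIRP"`, `"ZINB"`, `"ZIGP"`, `"ZHP"`, `"ZHNB"`.
#' @return a `polyp_fit`.
#' @export
fit_model <- function(data, kind) {
  switch(kind,
    LR   = fit_logistic(data),
    PR   = fit_count_glm(data, "poisson"),
    RP   = fit_count_glm(data, "poisson", robust = TRUE),
    NB   = fit_count_glm(data, "negbin"),
    GP   = fit_count_glm(data, "genpoisson"),
    ZIP  = fit_zero_inflated(data, "poisson"),
    ZIRP = fit_zero_inflated(data, "poisson", robust = TRUE),
    ZINB = fit_zero_inflated(data, "negbin"),
    ZIGP = fit_zero_inflated(data, "genpoisson"),
    ZHP  = fit_hurdle(data, "poisson"),
    ZHNB = fit_hurdle(data, "negbin"),
    stop("unknown model kind '", kind, "'; valid kinds: LR, PR, RP, NB, ",
         "GP, ZIP, ZIRP, ZINB, ZIGP, ZHP, ZHNB", call. = FALSE))
}

.model_kinds <- c("LR", "PR", "RP", "NB", "GP", "ZIP", "ZIRP", "ZINB",
                  "ZIGP", "ZHP", "ZHNB")

## NB2 boundary: below ~1e-4 the dispersion is indistinguishable from 0 at
## these sample sizes and the log-alpha profile goes flat, so a fit that
## either lands there or stalls on its way down is treated as the boundary
.alpha_boundary <- function(log_alpha, converged = TRUE)
  exp(log_alpha) < 1e-4
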