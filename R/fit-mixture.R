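## Two-part models: zero-inflated mixtures (ZIP/ZIRP/ZINB/ZIGP) and
## zero-hurdle models (ZHP/ZHNB).
##
## Parameter layout for all two-part fits: count coefficients first, then
## inflation/hurdle coefficients, then the (transformed) dispersion. The
## inflation part models the odds of an EXCESS zero, so an inflation OR
## below one means the exposed group has fewer structural zeros; its
## inverse reads as the effect on the presence of detected polyps. The
## hurdle zero part instead models the odds of presence (y > 0), which
## makes its coefficients identical to plain logistic regression.

.zi_dispersion_len <- function(family)
  if (family == "poisson") 0L else 1L

## per-subject log-likelihood of the zero-inflated mixture, log-sum-exp in
## the zero cell so that pi ~ 1 or f(0) ~ 0 never underflows
.li_zeroinfl <- function(data, family) {
  X <- data$X; Z <- data$Z; y <- data$y
  k <- ncol(X); m <- ncol(Z)
  zero <- y == 0
  function(par) {
    mu <- exp(drop(X %*% par[seq_len(k)]))
    eta_z <- drop(Z %*% par[k + seq_len(m)])
    disp <- if (family == "negbin") exp(par[k + m + 1]) else
      if (family == "genpoisson") .gp_delta(par[k + m + 1]) else 0
    lpy <- switch(family,
      poisson    = .log_pmf("poisson", y, mu),
      negbin     = .log_pmf("negbin", y, mu, alpha = disp),
      genpoisson = .log_pmf("genpoisson", y, mu, delta = disp))
    lpi <- stats::plogis(eta_z, log.p = TRUE)        # log pi
    lqi <- stats::plogis(-eta_z, log.p = TRUE)       # log(1 - pi)
    li <- lqi + lpy
    if (any(zero)) {
      a <- lpi[zero]
      b <- li[zero]
      mx <- pmax(a, b)
      li[zero] <- mx + log1p(exp(pmin(a, b) - mx))
    }
    li
  }
}

## analytic gradient, ZIP only (the Monte Carlo hot path)
.gr_zip <- function(data) {
  X <- data$X; Z <- data$Z; y <- data$y
  k <- ncol(X); m <- ncol(Z)
  zero <- y == 0
  function(par) {
    mu <- exp(drop(X %*% par[seq_len(k)]))
    eta_z <- drop(Z %*% par[k + seq_len(m)])
    pi <- stats::plogis(eta_z)
    lpi <- stats::plogis(eta_z, log.p = TRUE)
    lqi <- stats::plogis(-eta_z, log.p = TRUE)
    l2 <- lqi - mu                                   # log((1-pi) f(0))
    mx <- pmax(lpi, l2)
    li0 <- mx + log1p(exp(pmin(lpi, l2) - mx))       # log P(Y=0)
    w_count <- exp(l2 - li0)                         # (1-pi)f0 / P(0)
    w_pi <- exp(lpi - li0)                           # pi / P(0)
    gb <- ifelse(zero, -w_count * mu, y - mu)
    gz <- ifelse(zero, w_pi * (1 - pi) * (-expm1(-mu)), -pi)
    c(drop(crossprod(X, gb)), drop(crossprod(Z, gz)))
  }
}

#' Zero-inflated count regression
#'
#' Joint maximum-likelihood fit of the two-part mixture
#' \deqn{P(Y=y) = \pi + (1-\pi) f(0) \;\; (y=0), \qquad
#'       (1-\pi) f(y) \;\; (y>0),}
#' where the excess-zero probability \eqn{\pi} follows a logistic model on
#' the inflation design and the count component \eqn{f} is Poisson, NB2 or
#' generalized Poisson on the count design. Exponentiated count
#' coefficients are risk ratios for the number of detected polyps given no
#' excess zero; exponentiated inflation coefficients are odds ratios for
#' an excess (structural) zero. `robust = TRUE` gives the sandwich
#' variance over the full parameter vector (the ZIRP estimator for the
#' Poisson family); point estimates are identical to the model-based fit.
#'
#' @param data a [polyp_data()] object. The inflation design may differ
#'   from the count design (see [polyp_data()]'s `zero_covariates`).
#' @param family count-component family.
#' @param robust use the Huber sandwich variance.
#' @return a `polyp_fit` of kind `"ZIP"`, `"ZIRP"`, `"ZINB"` or `"ZIGP"`.
#' @export
fit_zero_inflated <- function(data,
                              family = c("poisson", "negbin", "genpoisson"),
                              robust = FALSE) {
  stopifnot(inherits(data, "polyp_data"))
  family <- match.arg(family)
  k <- ncol(data$X); m <- ncol(data$Z)
  y <- data$y

  ## starts: truncated-data Poisson seeds the count part; the excess-zero
  ## fraction relative to the Poisson prediction seeds the inflation
  ## intercept; everything else starts at zero
  pos <- y > 0
  cnt_start <- suppressWarnings(stats::glm.fit(
    data$X[pos, , drop = FALSE], y[pos],
    family = stats::poisson())$coefficients)
  pois_fit <- suppressWarnings(
    stats::glm.fit(data$X, y, family = stats::poisson()))
  p0_hat <- mean(exp(-pois_fit$fitted.values))
  excess <- max(0.05, mean(y == 0) - p0_hat)
  zero_start <- c(stats::qlogis(excess), rep(0, m - 1))
  disp_start <- switch(family, poisson = NULL, negbin = log(0.1),
                       genpoisson = 0)
  start <- c(cnt_start, zero_start, disp_start)

  li <- .li_zeroinfl(data, family)
  gr <- if (family == "poisson") .gr_zip(data) else NULL
  res <- .mle_fit(li, start, gr)

  if (family == "negbin" && .alpha_boundary(res$par[k + m + 1])) {
    warning("ZINB dispersion at the zero boundary; alpha reported as 0",
            call. = FALSE)
    li_p <- .li_zeroinfl(data, "poisson")
    res_p <- .mle_fit(li_p, res$par[seq_len(k + m)], .gr_zip(data))
    names(res_p$par) <- c(colnames(data$X),
                          paste0("zero_", colnames(data$Z)))
    fit <- .make_fit("ZINB", res_p$par, li_p, data, res_p$info,
                     res_p$loglik, res_p$converged, res_p$gradient_norm,
                     n_count = k, n_zero = m, dispersion = 0,
                     dispersion_name = "alpha", robust = robust)
    fit$n_params <- k + m + 1L          # alpha was estimated (boundary)
    fit$family <- "poisson"
    fit$li_builder <- function(d) .li_zeroinfl(d, "poisson")
    return(fit)
  }

  infl <- res$par[k + seq_len(m)]
  ## a converged fit with a hugely negative inflation intercept is the
  ## degenerate no-excess-zero boundary (pi -> 0), which is legitimate;
  ## large logit coefficients WITHOUT convergence signal real instability
  if (!res$converged && any(y == 0))
    stop("zero-inflated ", family, " fit unstable (|logit coefficient| > ",
         "15 or non-convergence, gradient norm ",
         format(res$gradient_norm),
         "); consider a hurdle model instead", call. = FALSE)

  kind <- if (family == "poisson") (if (robust) "ZIRP" else "ZIP")
    else if (family == "negbin") "ZINB" else "ZIGP"
  dn <- switch(family, poisson = NULL, negbin = "alpha",
               genpoisson = "delta")
  disp <- switch(family, poisson = NULL,
                 negbin = unname(exp(res$par[k + m + 1])),
                 genpoisson = unname(.gp_delta(res$par[k + m + 1])))
  names(res$par) <- c(colnames(data$X),
                      paste0("zero_", colnames(data$Z)),
                      if (family == "negbin") "log(alpha)"
                      else if (family == "genpoisson") "link(delta)")
  fit <- .make_fit(kind, res$par, li, data, res$info, res$loglik,
                   res$converged, res$gradient_norm, n_count = k,
                   n_zero = m, dispersion = disp, dispersion_name = dn,
                   robust = robust)
  fit$family <- family
  fit$li_builder <- function(d) .li_zeroinfl(d, family)
  fit
}

## truncated count part of the hurdle model, positives only
.li_truncated <- function(data, family) {
  X <- data$X; y <- data$y
  k <- ncol(X)
  function(par) {
    mu <- exp(drop(X %*% par[seq_len(k)]))
    alpha <- if (family == "negbin") exp(par[k + 1]) else 0
    lpy <- .log_pmf(family, y, mu, alpha = alpha)
    lp0 <- .log_pmf(family, rep(0L, length(y)), mu, alpha = alpha)
    lpy - log1p(-exp(lp0))
  }
}

.gr_truncated_pois <- function(data) {
  X <- data$X; y <- data$y
  function(par) {
    mu <- exp(drop(X %*% par))
    drop(crossprod(X, y - mu / (1 - exp(-mu))))
  }
}

#' Zero-hurdle count regression
#'
#' Two orthogonal maximum-likelihood fits: a logistic regression on polyp
#' presence (`y > 0`, identical to [fit_logistic()], so its odds ratios
#' match the plain LR row exactly) and a zero-truncated Poisson or NB2
#' regression on the positive counts. The total log-likelihood is the sum
#' of the two parts.
#'
#' @param data a [polyp_data()] object with at least one zero and one
#'   positive count.
#' @param family count-component family (`"poisson"` or `"negbin"`).
#' @return a `polyp_fit` of kind `"ZHP"` or `"ZHNB"`.
#' @export
fit_hurdle <- function(data, family = c("poisson", "negbin")) {
  stopifnot(inherits(data, "polyp_data"))
  family <- match.arg(family)
  if (!any(data$y == 0))
    stop("no zero counts: the hurdle part is degenerate", call. = FALSE)
  k <- ncol(data$X); m <- ncol(data$Z)

  requested <- family
  boundary_alpha <- FALSE
  zero_fit <- fit_logistic(data)
  pos <- subset_polyp_data(data, which(data$y > 0))
  cnt_start <- suppressWarnings(stats::glm.fit(
    pos$X, pos$y, family = stats::poisson())$coefficients)
  li_t <- .li_truncated(pos, family)
  if (family == "poisson") {
    res <- .mle_fit(li_t, cnt_start, .gr_truncated_pois(pos))
  } else {
    res <- .mle_fit(li_t, c(cnt_start, log(0.1)))
    if (.alpha_boundary(res$par[k + 1])) {
      warning("truncated NB dispersion at the zero boundary; ",
              "alpha reported as 0", call. = FALSE)
      family <- "poisson"
      boundary_alpha <- TRUE
      li_t <- .li_truncated(pos, "poisson")
      res <- .mle_fit(li_t, res$par[seq_len(k)], .gr_truncated_pois(pos))
    }
  }
  if (!res$converged)
    stop("truncated ", family, " fit did not converge; gradient norm ",
         format(res$gradient_norm), call. = FALSE)

  par <- c(res$par[seq_len(k)], zero_fit$coefficients,
           if (family == "negbin") res$par[k + 1])
  names(par) <- c(colnames(data$X),
                  paste0("hurdle_", colnames(data$Z)),
                  if (family == "negbin") "log(alpha)")

  ## joint per-subject likelihood: logistic part everywhere, truncated
  ## count part on the positives
  li_joint_builder <- function(d) {
    li_z <- .li_logistic(d)
    posi <- d$y > 0
    dpos <- subset_polyp_data(d, which(posi))
    li_tt <- .li_truncated(dpos, family)
    nc <- ncol(d$X); nz <- ncol(d$Z)
    function(p) {
      cnt_par <- c(p[seq_len(nc)],
                   if (family == "negbin") p[nc + nz + 1])
      li <- li_z(p[nc + seq_len(nz)])
      li[posi] <- li[posi] + li_tt(cnt_par)
      li
    }
  }
  li_joint <- li_joint_builder(data)
  nll <- function(p) -sum(li_joint(p))
  info <- stats::optimHess(par, nll)
  loglik <- zero_fit$loglik + res$loglik

  fit <- .make_fit(if (requested == "poisson") "ZHP" else "ZHNB",
                   par, li_joint, data, info, loglik,
                   zero_fit$converged && res$converged,
                   max(zero_fit$gradient_norm, res$gradient_norm),
                   n_count = k, n_zero = m,
                   dispersion = if (requested == "negbin")
                     (if (boundary_alpha) 0 else unname(exp(res$par[k + 1])))
                   else NULL,
                   dispersion_name = if (requested == "negbin") "alpha",
                   robust = FALSE)
  if (boundary_alpha) fit$n_params <- fit$n_params + 1L
  fit$family <- family
  fit$li_builder <- li_joint_builder
  fit$parts <- list(zero = zero_fit, count_loglik = res$loglik)
  fit
}

#' Per-subject component predictions
#'
#' Decomposes a fitted model into the quantities the diagnostics, the
#' goodness-of-fit test and the marginal standardization consume: the
#' structural-zero probability `pi`, the count-component mean `mu`, the
#' total zero probability, the detection probability `prob_pos`
#' (\eqn{P(Y>0)}), the expected count, and for observed zeros the
#' posterior probability that the zero is structural. For hurdle models
#' `pi` is the direct zero probability `P(Y=0)`; for single-distribution
#' count models `pi = 0`; for the logistic model only the zero/detection
#' probabilities are defined.
#'
#' @param model a converged [polyp_fit].
#' @param data a `polyp_data` whose design columns match the fitting
#'   data; defaults to the fitting data.
#' @return data frame of class `mixture_prediction` with columns `pi`,
#'   `mu`, `prob_zero`, `prob_pos`, `expected_count`,
#'   `structural_posterior`.
#' @export
predict_components <- function(model, data = NULL) {
  stopifnot(inherits(model, "polyp_fit"))
  if (!model$converged) stop("model did not converge", call. = FALSE)
  data <- data %||% model$data
  if (!identical(colnames(data$X), colnames(model$data$X)) ||
      !identical(colnames(data$Z), colnames(model$data$Z)))
    stop("design columns do not match the fitting data", call. = FALSE)
  k <- ncol(data$X)
  kind <- model$model_kind
  par <- model$coefficients

  if (kind == "LR") {
    p_pos <- stats::plogis(drop(data$Z %*% par))
    out <- data.frame(pi = 1 - p_pos, mu = NA_real_, prob_zero = 1 - p_pos,
                      prob_pos = p_pos, expected_count = NA_real_,
                      structural_posterior = 1)
  } else if (kind %in% c("PR", "RP", "NB", "GP")) {
    mu <- exp(drop(data$X %*% par[seq_len(k)]))
    f0 <- exp(.log_pmf(.fit_family(model), rep(0L, data$n), mu,
                       alpha = model$dispersion %||% 0,
                       delta = model$dispersion %||% 0))
    out <- data.frame(pi = 0, mu = mu, prob_zero = f0, prob_pos = 1 - f0,
                      expected_count = mu, structural_posterior = 0)
  } else if (kind %in% c("ZIP", "ZIRP", "ZINB", "ZIGP")) {
    mu <- exp(drop(data$X %*% par[seq_len(k)]))
    pi <- stats::plogis(drop(data$Z %*% model$inflate_coefficients))
    f0 <- exp(.log_pmf(model$family, rep(0L, data$n), mu,
                       alpha = model$dispersion %||% 0,
                       delta = model$dispersion %||% 0))
    prob_zero <- pi + (1 - pi) * f0
    out <- data.frame(pi = pi, mu = mu, prob_zero = prob_zero,
                      prob_pos = 1 - prob_zero,
                      expected_count = (1 - pi) * mu,
                      structural_posterior = pi / prob_zero)
  } else {  # hurdle
    mu <- exp(drop(data$X %*% par[seq_len(k)]))
    p_pos <- stats::plogis(drop(data$Z %*% model$inflate_coefficients))
    f0 <- exp(.log_pmf(model$family, rep(0L, data$n), mu,
                       alpha = model$dispersion %||% 0))
    out <- data.frame(pi = 1 - p_pos, mu = mu, prob_zero = 1 - p_pos,
                      prob_pos = p_pos,
                      expected_count = p_pos * mu / (1 - f0),
                      structural_posterior = 1)
  }
  class(out) <- c("mixture_prediction", "data.frame")
  out
}

## family name of a single-distribution count fit
.fit_family <- function(model) {
  switch(model$model_kind,
    PR = , RP = "poisson",
    NB = "negbin",
    GP = "genpoisson",
    model$family)
}
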