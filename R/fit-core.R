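## Shared maximum-likelihood machinery for all model families.
##
## Every model is expressed through one closure li_fun(par) returning the
## n-vector of per-subject log-likelihood contributions at a parameter
## vector on the estimation scale (dispersion parameters enter transformed:
## log(alpha) for NB2, a logistic map for GP delta). The optimizer, the
## observed information, the per-subject score matrix and the sandwich
## variance are all derived from that single definition, so ZIRP/robust
## variants share point estimates with their model-based counterparts by
## construction.

## central-difference step sized for ~cube-root machine precision
.fd_step <- function(p) 6e-6 * pmax(1, abs(p))

.num_grad <- function(f, p) {
  h <- .fd_step(p)
  vapply(seq_along(p), function(j) {
    pp <- pm <- p
    pp[j] <- p[j] + h[j]
    pm[j] <- p[j] - h[j]
    (f(pp) - f(pm)) / (2 * h[j])
  }, numeric(1))
}

## n x k matrix of per-subject scores by central differences of li_fun
.score_matrix <- function(li_fun, p) {
  h <- .fd_step(p)
  cols <- lapply(seq_along(p), function(j) {
    pp <- pm <- p
    pp[j] <- p[j] + h[j]
    pm[j] <- p[j] - h[j]
    (li_fun(pp) - li_fun(pm)) / (2 * h[j])
  })
  do.call(cbind, cols)
}

## BFGS with optional analytic gradient, Nelder-Mead fallback, and a short
## Newton polish so converged fits have score max-norm ~1e-8 even when the
## search gradient was finite-difference.
.mle_fit <- function(li_fun, start, gr = NULL, max_iter = 500L) {
  nll <- function(p) {
    v <- li_fun(p)
    if (any(!is.finite(v))) return(1e10)
    -sum(v)
  }
  ngr <- if (!is.null(gr)) function(p) -gr(p) else NULL
  ctrl <- list(maxit = max_iter, reltol = 1e-12)
  if (is.null(gr)) ctrl$ndeps <- rep(1e-5, length(start))
  opt <- stats::optim(start, nll, ngr, method = "BFGS", control = ctrl)
  if (opt$convergence != 0 || !is.finite(opt$value) || opt$value >= 1e10) {
    warning("BFGS did not converge; falling back to Nelder-Mead",
            call. = FALSE)
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
  }
  p <- opt$par
  num_g <- function(p) if (!is.null(gr)) -gr(p) else .num_grad(nll, p)
  g <- num_g(p)
  for (it in seq_len(25)) {
    if (max(abs(g)) < 1e-9) break
    H <- try(stats::optimHess(p, nll, ngr), silent = TRUE)
    step <- try(solve(H, g), silent = TRUE)
    if (inherits(H, "try-error") || inherits(step, "try-error")) break
    accepted <- FALSE
    for (t in 2^-(0:5)) {            # damped Newton near flat boundaries
      cand <- p - t * step
      v <- nll(cand)
      if (!is.finite(v) || v > opt$value + 1e-10) next
      gc_ <- num_g(cand)
      if (v < opt$value - 1e-12 || max(abs(gc_)) < max(abs(g))) {
        p <- cand
        opt$value <- v
        g <- gc_
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  info <- stats::optimHess(p, nll, ngr)
  ## practical tolerance: analytic-gradient fits polish to ~1e-9; fits
  ## with finite-difference gradients (GP and dispersion boundaries) are
  ## limited by the difference-quotient noise floor
  list(par = p, loglik = -opt$value, gradient_norm = max(abs(g)),
       info = info, converged = max(abs(g)) < 1e-4)
}

## Assemble the common fitted-model object.
.make_fit <- function(kind, par, li_fun, data, info, loglik, converged,
                      gradient_norm, n_count, n_zero = 0L,
                      dispersion = NULL, dispersion_name = NULL,
                      robust = FALSE) {
  vc_model <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc_model)) {
    ## boundary fits (e.g. an empty inflation component) leave a flat
    ## direction in the information; invert on the non-degenerate subspace
    eg <- eigen(info, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-12
    if (!any(keep))
      stop("observed information is singular; check design matrix rank",
           call. = FALSE)
    vc_model <- eg$vectors[, keep, drop = FALSE] %*%
      (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
    warning("observed information is singular in ", sum(!keep),
            " direction(s); variance from the non-degenerate subspace",
            call. = FALSE)
  }
  dimnames(vc_model) <- list(names(par), names(par))
  fit <- structure(list(
    model_kind = kind,
    coefficients = par,
    count_coefficients = par[seq_len(n_count)],
    inflate_coefficients = if (n_zero > 0)
      par[n_count + seq_len(n_zero)] else numeric(0),
    dispersion = dispersion,
    dispersion_name = dispersion_name,
    vcov = vc_model,
    vcov_model = vc_model,
    robust = robust,
    loglik = loglik,
    loglik_i = li_fun(par),
    n_params = length(par),
    n = data$n,
    converged = converged,
    gradient_norm = gradient_norm,
    info = info,
    li_fun = li_fun,
    data = data), class = "polyp_fit")
  if (robust) fit$vcov <- sandwich_vcov(fit)
  fit
}

#' Huber sandwich (robust) variance
#'
#' Computes \eqn{A^{-1} B A^{-1}} where \eqn{A} is the observed
#' information and \eqn{B = \sum_i s_i s_i^\top} the outer product of the
#' per-subject score vectors, evaluated at the maximum-likelihood
#' estimate. Valid under variance misspecification, e.g. a Poisson count
#' part fitted to over- or underdispersed data (the robust Poisson and
#' zero-inflated robust Poisson estimators).
#'
#' @param model a converged [polyp_fit] object.
#' @param data optional `polyp_data`; defaults to the data the model was
#'   fitted to (supplying other data is only meaningful for identically
#'   structured designs).
#' @return symmetric positive-semidefinite matrix on the estimation scale.
#' @export
sandwich_vcov <- function(model, data = NULL) {
  stopifnot(inherits(model, "polyp_fit"))
  if (!model$converged)
    stop("model did not converge; sandwich variance undefined", call. = FALSE)
  li_fun <- model$li_fun
  info <- model$info
  if (!is.null(data) && !identical(data, model$data)) {
    if (is.null(model$li_builder))
      stop("model cannot be re-evaluated on new data", call. = FALSE)
    li_fun <- model$li_builder(data)
    nll <- function(p) -sum(li_fun(p))
    info <- stats::optimHess(model$coefficients, nll)
  }
  S <- .score_matrix(li_fun, model$coefficients)
  A_inv <- tryCatch(solve(info), error = function(e)
    stop("observed information is singular; check design matrix rank",
         call. = FALSE))
  V <- A_inv %*% crossprod(S) %*% A_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(model$vcov_model)
  V
}

#' Information criteria of a fitted model
#'
#' `AIC = -2 LL + 2 k` and `BIC = -2 LL + k log(n)` with `k` the total
#' number of estimated parameters (both components plus any dispersion).
#' BIC is the primary ranking criterion used by the model selector.
#'
#' @param model a [polyp_fit] object.
#' @return list with elements `AIC`, `BIC`, `LL`.
#' @export
information_criteria <- function(model) {
  stopifnot(inherits(model, "polyp_fit"))
  list(AIC = -2 * model$loglik + 2 * model$n_params,
       BIC = -2 * model$loglik + model$n_params * log(model$n),
       LL = model$loglik)
}

#' @export
logLik.polyp_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
coef.polyp_fit <- function(object, ...) object$coefficients

#' @export
vcov.polyp_fit <- function(object, ...) object$vcov

#' @export
nobs.polyp_fit <- function(object, ...) object$n

## Coefficient table on the ratio scale: count rows exponentiate to risk
## ratios, zero/hurdle rows to odds ratios (Wald 95% CI, normal reference).
.coef_table <- function(fit, level = 0.95) {
  se <- sqrt(pmax(diag(fit$vcov), 0))
  est <- fit$coefficients
  z <- est / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  part <- c(rep("count", length(fit$count_coefficients)),
            rep("zero", length(fit$inflate_coefficients)))
  if (length(part) < length(est))
    part <- c(part, rep("dispersion", length(est) - length(part)))
  if (fit$model_kind == "LR") part[] <- "zero"
  data.frame(
    part = part, term = names(est), estimate = est, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ratio = exp(est), lcl = exp(est - q * se), ucl = exp(est + q * se),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Group effect of a fitted model on the ratio scale
#'
#' Convenience accessor for the exposure contrast: the exponentiated group
#' coefficient (risk ratio for count parts, odds ratio for logistic and
#' inflation parts) with its Wald confidence interval and p-value.
#'
#' @param model a [polyp_fit] object.
#' @param part `"count"` or `"zero"`.
#' @param level confidence level.
#' @return one-row data frame with `ratio`, `lcl`, `ucl`, `p`.
#' @export
group_effect <- function(model, part = c("count", "zero"), level = 0.95) {
  part <- match.arg(part)
  tab <- .coef_table(model, level)
  g <- model$data$group
  terms <- if (part == "zero") c(g, paste0("zero_", g), paste0("hurdle_", g))
    else g
  row <- tab[tab$part == part & tab$term %in% terms, , drop = FALSE]
  if (nrow(row) == 0)
    stop("model has no ", part, "-part term for group '",
         model$data$group, "'", call. = FALSE)
  row[, c("ratio", "lcl", "ucl", "p")]
}

#' @export
print.polyp_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<%s fit%s: n = %d, logLik = %.2f, %s>\n", x$model_kind,
              if (x$robust) " (sandwich variance)" else "",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  tab <- .coef_table(x)
  for (p in unique(tab$part)) {
    cat(sprintf("  [%s]\n", p))
    sub <- tab[tab$part == p, c("term", "estimate", "se", "ratio",
                                "lcl", "ucl", "p")]
    print(format(sub, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$dispersion))
    cat(sprintf("  %s = %.4g\n", x$dispersion_name, x$dispersion))
  invisible(x)
}

#' @export
summary.polyp_fit <- function(object, level = 0.95, ...) {
  structure(list(fit = object, table = .coef_table(object, level),
                 ic = information_criteria(object)),
            class = "summary.polyp_fit")
}

#' @export
print.summary.polyp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC %.2f  BIC %.2f  LL %.2f\n",
              x$ic$AIC, x$ic$BIC, x$ic$LL))
  invisible(x)
}

## htest-style wrapper used by the whole diagnostic battery
.test_result <- function(name, statistic, p_value, df = NULL,
                         direction = NULL, estimate = NULL, note = NULL) {
  structure(list(test_name = name, statistic = statistic, df = df,
                 p_value = p_value, direction = direction,
                 estimate = estimate, note = note),
            class = "polyp_test")
}

#' @export
print.polyp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g%s\n", x$test_name,
              x$statistic,
              if (!is.null(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value,
              if (!is.null(x$direction)) paste0(" [", x$direction, "]")
              else ""))
  if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}
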