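## Excess-zero tests, dispersion tests after excess-zero removal,
## goodness of fit, and the flowchart-driven model selector.

#' Score test for zero inflation
#'
#' van den Broek's score test of a zero-inflated alternative against a
#' fitted Poisson regression:
#' \deqn{S = \frac{\left[\sum_i (1\{y_i=0\} - \hat p_{0i})/\hat p_{0i}\right]^2}
#'            {\sum_i (1-\hat p_{0i})/\hat p_{0i} - n\bar y}}
#' with \eqn{\hat p_{0i} = e^{-\hat\mu_i}}, referred to a chi-square with
#' one degree of freedom. A significant result indicates an excess amount
#' of zero counts (no detected polyps) relative to the Poisson fit.
#'
#' @param poisson_fit a converged `"PR"`/`"RP"` fit on the same design.
#' @param data the `polyp_data` the Poisson model was fitted to.
#' @return a `polyp_test`.
#' @export
score_test_zero_inflation <- function(poisson_fit, data = NULL) {
  stopifnot(inherits(poisson_fit, "polyp_fit"),
            poisson_fit$model_kind %in% c("PR", "RP"))
  data <- data %||% poisson_fit$data
  mu <- exp(drop(data$X %*% poisson_fit$count_coefficients))
  p0 <- exp(-mu)
  num <- sum((as.numeric(data$y == 0) - p0) / p0)
  den <- sum((1 - p0) / p0) - data$n * mean(data$y)
  if (den <= 0) {
    warning("score-test denominator is non-positive (underdispersion); ",
            "test not applicable", call. = FALSE)
    return(.test_result("score test for zero inflation", NA_real_,
                        NA_real_, df = 1,
                        note = "denominator <= 0; not applicable"))
  }
  stat <- num^2 / den
  .test_result("score test for zero inflation", stat,
               stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1)
}

#' Bias-corrected Vuong test
#'
#' Vuong's non-nested comparison of a zero-inflated model against its
#' single-distribution counterpart, based on the per-subject
#' log-likelihood differences \eqn{m_i}. The AIC (default) or BIC
#' correction subtracts the per-observation parameter-count penalty from
#' each \eqn{m_i}. The statistic \eqn{Z = \sqrt{n}\,\bar m / s_m} is
#' referred to a standard normal, one-sided: large positive `Z` favours
#' the zero-inflated model.
#'
#' @param model_zi,model_plain two converged fits on the identical
#'   outcome vector.
#' @param correction `"AIC"`, `"BIC"` or `"none"`.
#' @return a `polyp_test`.
#' @export
vuong_test_corrected <- function(model_zi, model_plain,
                                 correction = c("AIC", "BIC", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(model_zi, "polyp_fit"),
            inherits(model_plain, "polyp_fit"))
  if (model_zi$n != model_plain$n)
    stop("models were fitted to different numbers of subjects",
         call. = FALSE)
  n <- model_zi$n
  dk <- model_zi$n_params - model_plain$n_params
  m <- model_zi$loglik_i - model_plain$loglik_i
  m <- m - switch(correction, none = 0, AIC = dk / n,
                  BIC = dk * log(n) / (2 * n))
  if (stats::sd(m) < 1e-12)
    return(.test_result("bias-corrected Vuong test", 0, 1,
                        note = "identical per-subject likelihoods"))
  z <- sqrt(n) * mean(m) / stats::sd(m)
  .test_result(sprintf("bias-corrected Vuong test (%s)", correction), z,
               stats::pnorm(z, lower.tail = FALSE))
}

#' Remove the excess zeros predicted by a zero-inflated fit
#'
#' Deletes `m = round(sum(pi_i))` zero-count records, chosen
#' deterministically as the observed zeros with the highest posterior
#' probability of being structural (ties broken by record order), so that
#' dispersion can be assessed on the remaining counts. The original
#' dataset is untouched.
#'
#' @param data a `polyp_data`.
#' @param zi_fit a converged zero-inflated fit on `data`.
#' @return a reduced `polyp_data`; the number of removed records is
#'   attached as attribute `n_removed`.
#' @export
remove_excess_zeros <- function(data, zi_fit) {
  stopifnot(inherits(data, "polyp_data"), inherits(zi_fit, "polyp_fit"))
  pc <- predict_components(zi_fit, data)
  m <- round(sum(pc$pi))
  zeros <- which(data$y == 0)
  if (m > length(zeros)) {
    warning("predicted structural zeros exceed observed zeros; ",
            "removing all ", length(zeros), " zeros", call. = FALSE)
    m <- length(zeros)
  }
  drop_idx <- if (m > 0)
    zeros[order(-pc$structural_posterior[zeros])][seq_len(m)]
  else integer(0)
  out <- subset_polyp_data(data, setdiff(seq_len(data$n), drop_idx))
  attr(out, "n_removed") <- m
  out
}

#' Dispersion tests
#'
#' Two complementary assessments of over/under/equidispersion, intended
#' for the counts remaining after [remove_excess_zeros()] (but defined on
#' any dataset): (a) the Cameron--Trivedi auxiliary regression of
#' \eqn{((y-\hat\mu)^2 - y)/\hat\mu} on \eqn{\hat\mu} (NB2 variance
#' function, no intercept) from a Poisson fit, with a two-sided t-test on
#' the slope whose sign gives the direction; and (b) the likelihood-ratio
#' boundary test of the NB2 dispersion, \eqn{2(LL_{NB} - LL_{P})} against
#' the 50:50 mixture of a point mass at zero and chi-square(1), reporting
#' the estimated alpha.
#'
#' @param data a `polyp_data` (original or excess-zero-reduced).
#' @return list with elements `auxiliary` and `nb_boundary` (both
#'   `polyp_test`), plus `mean` and `variance` of the outcome.
#' @export
dispersion_tests <- function(data) {
  stopifnot(inherits(data, "polyp_data"))
  pr <- fit_count_glm(data, "poisson")
  mu <- exp(drop(data$X %*% pr$count_coefficients))
  zz <- ((data$y - mu)^2 - data$y) / mu
  aux <- summary(stats::lm(zz ~ mu - 1))$coefficients
  slope <- aux[1, 1]
  p_aux <- aux[1, 4]
  dir <- if (p_aux >= 0.05) "equidispersion" else
    if (slope > 0) "overdispersion" else "underdispersion"
  auxiliary <- .test_result("auxiliary dispersion regression",
                            aux[1, 3], p_aux, direction = dir,
                            estimate = slope)

  nb <- withCallingHandlers(
    fit_count_glm(data, "negbin"),
    warning = function(w) invokeRestart("muffleWarning"))
  lr <- max(2 * (nb$loglik - pr$loglik), 0)
  p_lr <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  nb_boundary <- .test_result("NB dispersion boundary LR test", lr, p_lr,
                              estimate = nb$dispersion,
                              direction = if (p_lr < 0.05) "overdispersion"
                              else "equidispersion",
                              note = sprintf("alpha = %.4g", nb$dispersion))
  list(auxiliary = auxiliary, nb_boundary = nb_boundary,
       mean = mean(data$y), variance = stats::var(data$y))
}

#' Chi-square goodness of fit on observed vs expected counts
#'
#' Compares observed cell counts for \eqn{y = 0, 1, \ldots} (counts at or
#' above `max_cell` merged into one cell) with the model's expected cell
#' counts \eqn{E_c = \sum_i \hat P(Y_i \in c)}. Cells with expected count
#' below one are merged upward. Degrees of freedom are
#' `cells - 1 - df_adjust`; the adjustment is configurable because the
#' appropriate deduction for estimated parameters in this grouped test is
#' a convention, and it is always reported.
#'
#' @param model a converged count-model fit (not `"LR"`).
#' @param data a `polyp_data`; defaults to the fitting data.
#' @param max_cell topcode cell (default 6: cells 0..5 and 6+).
#' @param df_adjust degrees-of-freedom deduction (default 2).
#' @return a `polyp_test`.
#' @export
gof_chisq <- function(model, data = NULL, max_cell = 6, df_adjust = 2) {
  stopifnot(inherits(model, "polyp_fit"))
  if (model$model_kind == "LR")
    stop("goodness of fit on count cells is undefined for LR",
         call. = FALSE)
  data <- data %||% model$data
  k <- ncol(data$X)
  par <- model$coefficients
  mu <- exp(drop(data$X %*% par[seq_len(k)]))
  fam <- .fit_family(model)
  alpha <- if (!is.null(model$dispersion_name) &&
               identical(model$dispersion_name, "alpha"))
    model$dispersion else 0
  delta <- if (identical(model$dispersion_name, "delta"))
    model$dispersion else 0

  cell_prob <- function(c_val) {
    f <- exp(.log_pmf(fam, rep(c_val, data$n), mu,
                      alpha = alpha, delta = delta))
    kind <- model$model_kind
    if (kind %in% c("ZIP", "ZIRP", "ZINB", "ZIGP")) {
      pi <- stats::plogis(drop(data$Z %*% model$inflate_coefficients))
      if (c_val == 0) pi + (1 - pi) * f else (1 - pi) * f
    } else if (kind %in% c("ZHP", "ZHNB")) {
      p_pos <- stats::plogis(drop(data$Z %*% model$inflate_coefficients))
      f0 <- exp(.log_pmf(fam, rep(0L, data$n), mu, alpha = alpha))
      if (c_val == 0) 1 - p_pos else p_pos * f / (1 - f0)
    } else f
  }

  cells <- 0:(max_cell - 1)
  P <- vapply(cells, cell_prob, numeric(data$n))
  E <- c(colSums(P), sum(1 - rowSums(P)))            # last cell: max_cell+
  yy <- pmin(data$y, max_cell)
  O <- vapply(c(cells, max_cell), function(c_val) sum(yy == c_val),
              numeric(1))

  note <- NULL
  while (length(E) > 2 && any(E < 1)) {              # merge upward
    j <- which(E < 1)[1]
    tgt <- if (j == length(E)) j - 1 else j + 1
    E[tgt] <- E[tgt] + E[j]
    O[tgt] <- O[tgt] + O[j]
    E <- E[-j]; O <- O[-j]
    note <- "cells with expected count < 1 merged"
  }
  stat <- sum((O - E)^2 / E)
  df <- max(length(E) - 1 - df_adjust, 1)
  .test_result("chi-square goodness of fit", stat,
               stats::pchisq(stat, df = df, lower.tail = FALSE),
               df = df, note = note)
}

#' Flowchart-driven model selection
#'
#' Automates the step-by-step selection of a count model for zero-heavy
#' polyp data: (1) test for excess zeros (score test on the Poisson fit,
#' confirmed by the bias-corrected Vuong test of ZIP vs Poisson); if
#' absent, choose a single-distribution family from the dispersion tests
#' (equidispersion: Poisson with robust variance; overdispersion: NB;
#' underdispersion: GP). (2) With excess zeros, the declared zero type
#' decides the branch: purely structural zeros lead to hurdle models,
#' mixed structural and sampling zeros to zero-inflated models --- the
#' zero type is a substantive judgment about the data-generating process
#' (can a polyp be missed at colonoscopy?) and is required as input, not
#' inferred. (3) Within the branch, dispersion after excess-zero removal
#' picks the family (over: NB count part; otherwise Poisson with robust
#' variance). (4) Candidates are ranked by BIC with the goodness of fit
#' as a tie-break.
#'
#' @param data a `polyp_data`.
#' @param zero_type `"mixed"` or `"structural_only"`.
#' @param fit_all also fit and tabulate the full model battery (default
#'   `TRUE`); otherwise only the models on the chosen branch.
#' @return an object of class `selection_report`: list with the test
#'   results, the per-model fit table, `recommended_model`, and the
#'   `rationale` trail of branch decisions.
#' @export
select_model_flowchart <- function(data,
                                   zero_type = c("mixed", "structural_only"),
                                   fit_all = TRUE) {
  stopifnot(inherits(data, "polyp_data"))
  zero_type <- match.arg(zero_type)
  if (!any(data$y == 0))
    stop("data contain no zero counts; declared zero_type is ",
         "contradictory and zero-modified models do not apply",
         call. = FALSE)
  rationale <- character(0)
  note <- function(...) rationale <<- c(rationale, sprintf(...))

  pr <- fit_count_glm(data, "poisson")
  zip <- fit_zero_inflated(data, "poisson")
  score <- score_test_zero_inflation(pr, data)
  vuong <- vuong_test_corrected(zip, pr, "AIC")
  excess <- is.finite(score$p_value) && score$p_value < 0.05 &&
    vuong$p_value < 0.05
  note("excess zeros: score p = %.3g, Vuong p = %.3g -> %s",
       score$p_value, vuong$p_value,
       if (excess) "present" else "absent")

  if (!excess) {
    dt <- dispersion_tests(data)
    dir <- dt$auxiliary$direction
    branch <- switch(dir, overdispersion = "NB",
                     underdispersion = "GP", "RP")
    note("no excess zeros; dispersion on full data: %s -> %s", dir, branch)
    candidates <- if (fit_all) c("PR", "RP", "NB", "GP") else branch
    dispersion_after <- dt
  } else {
    reduced <- remove_excess_zeros(data, zip)
    note("removed %d excess zeros (predicted by ZIP)",
         attr(reduced, "n_removed"))
    dt <- dispersion_tests(reduced)
    dir <- dt$auxiliary$direction
    over <- dir == "overdispersion" &&
      dt$nb_boundary$p_value < 0.05
    if (zero_type == "structural_only") {
      branch <- if (over) "ZHNB" else "ZHP"
      note("structural zeros only -> hurdle family; dispersion after removal: %s -> %s",
           dir, branch)
      candidates <- if (fit_all) c("ZHP", "ZHNB") else branch
    } else {
      branch <- if (over) "ZINB" else "ZIRP"
      note("mixed zeros -> zero-inflated family; dispersion after removal: %s -> %s",
           dir, branch)
      candidates <- if (fit_all)
        c("ZIP", "ZIRP", "ZINB", "ZIGP", "ZHP", "ZHNB") else branch
    }
    dispersion_after <- dt
  }

  fits <- list()
  rows <- list()
  for (kind in candidates) {
    f <- tryCatch(fit_model(data, kind), error = function(e) e)
    if (inherits(f, "error")) {
      note("%s failed to fit: %s", kind, conditionMessage(f))
      next
    }
    fits[[kind]] <- f
    ic <- information_criteria(f)
    g <- tryCatch(gof_chisq(f, data), error = function(e) NULL)
    rows[[kind]] <- data.frame(
      model = kind, AIC = ic$AIC, BIC = ic$BIC, LL = ic$LL,
      GOF = if (is.null(g)) NA_real_ else g$statistic,
      GOF_p = if (is.null(g)) NA_real_ else g$p_value,
      stringsAsFactors = FALSE)
  }
  fit_table <- do.call(rbind, rows)
  row.names(fit_table) <- NULL

  ## rank by BIC; a model whose GOF clearly rejects (p < 0.05) yields to
  ## the next-best BIC whose GOF does not, when one exists
  ord <- order(fit_table$BIC)
  ranked <- fit_table$model[ord]
  ok <- which(!is.na(fit_table$GOF_p[ord]) & fit_table$GOF_p[ord] >= 0.05)
  recommended <- if (length(ok)) ranked[ok[1]] else ranked[1]
  if (recommended %in% c("PR", "ZIP") && branch %in% c("RP", "ZIRP")) {
    recommended <- branch                       # same fit, robust variance
    note("robust variance preferred for inference -> %s", branch)
  }
  note("BIC ranking: %s; recommended: %s",
       paste(ranked, collapse = " < "), recommended)

  structure(list(excess_zero_tests = list(score = score, vuong = vuong),
                 zero_type = zero_type,
                 dispersion_after_removal = dispersion_after,
                 fit_table = fit_table, fits = fits,
                 recommended_model = recommended,
                 rationale = rationale),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Model selection report\n")
  cat("  zero type (declared):", x$zero_type, "\n")
  for (r in x$rationale) cat("  -", r, "\n")
  cat("\n")
  print(format(x$fit_table, digits = 6), row.names = FALSE)
  cat("\nRecommended model:", x$recommended_model, "\n")
  invisible(x)
}
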