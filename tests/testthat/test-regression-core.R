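test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # margins of the cap-assisted vs standard colonoscopy arms:
  # 87/211 vs 92/214 subjects with a polyp
  d <- data_from_2x2(87, 211, 92, 214)
  fit <- fit_logistic(d)
  or_hand <- (87 * 122) / (92 * 124)
  expect_equal(unname(exp(fit$coefficients["group"])), or_hand,
               tolerance = 1e-8)

  # identical outcome rates per group -> OR exactly 1
  d_sym <- data_from_2x2(30, 100, 30, 100)
  expect_equal(unname(exp(fit_logistic(d_sym)$coefficients["group"])), 1,
               tolerance = 1e-8)
})

test_that("perfect separation raises an informative error", {
  df <- data.frame(polyps = c(rep(0L, 20), rep(3L, 20)),
                   group = c(rep(0L, 20), rep(1L, 20)))
  d <- polyp_data(df, "polyps", "group")
  expect_error(fit_logistic(d), "group")
})

test_that("intercept-only fits reproduce the observed mean for every family", {
  d <- sim_count_data(300, mu0 = 1.3, beta = 0, family = "negbin",
                      alpha = 0.4, seed = 3)
  d0 <- polyp_data(data.frame(polyps = d$y, group = rep(0:1, length.out = d$n)),
                   outcome = "polyps", group = "group")
  # drop the group column to get a true intercept-only design
  d0$X <- d0$X[, 1, drop = FALSE]
  d0$Z <- d0$Z[, 1, drop = FALSE]
  for (fam in c("poisson", "negbin", "genpoisson")) {
    fit <- suppressWarnings(fit_count_glm(d0, fam))
    expect_equal(unname(exp(fit$coefficients[1])), mean(d0$y),
                 tolerance = 1e-5, label = fam)
  }
})

test_that("Poisson regression recovers a known coefficient at large n", {
  d <- sim_count_data(5000, mu0 = 1.2, beta = 0.4, seed = 7)
  fit <- fit_count_glm(d, "poisson")
  se <- sqrt(diag(fit$vcov))["group"]
  expect_lt(abs(fit$coefficients["group"] - 0.4), 3 * se)
})

test_that("NB2 fit agrees with the independent glm.nb implementation", {
  d <- sim_count_data(1500, mu0 = 1.5, beta = 0.3, family = "negbin",
                      alpha = 0.6, seed = 11, covariate = TRUE)
  fit <- fit_count_glm(d, "negbin")
  ref <- MASS::glm.nb(y ~ x + z,
                      data = data.frame(y = d$y, x = d$X[, "group"],
                                        z = d$X[, "age"]))
  expect_equal(unname(fit$count_coefficients),
               unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$dispersion, 1 / ref$theta, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("sandwich variance matches the sandwich package on a Poisson glm", {
  d <- sim_count_data(800, mu0 = 1.4, beta = 0.3, family = "negbin",
                      alpha = 0.5, seed = 13)
  fit <- fit_count_glm(d, "poisson", robust = TRUE)
  ref <- glm(y ~ x, family = poisson(),
             data = data.frame(y = d$y, x = d$X[, "group"]))
  vr <- sandwich::vcovHC(ref, type = "HC0")
  expect_equal(unname(fit$vcov), unname(vr), tolerance = 1e-3)
})

test_that("duplicating the data exactly halves the sandwich variance", {
  d <- sim_count_data(300, seed = 17)
  fit <- fit_count_glm(d, "poisson")
  v1 <- sandwich_vcov(fit)
  d2 <- polyp_data(
    data.frame(polyps = rep(d$y, 2), group = rep(d$X[, "group"], 2)),
    outcome = "polyps", group = "group")
  fit2 <- fit_count_glm(d2, "poisson")
  v2 <- sandwich_vcov(fit2)
  expect_equal(v2, v1 / 2, tolerance = 1e-6)
})

test_that("robust SEs exceed model SEs under overdispersion", {
  d <- sim_count_data(2000, mu0 = 1.5, beta = 0.4, family = "negbin",
                      alpha = 0.8, seed = 19)
  pr <- fit_count_glm(d, "poisson")
  rp <- fit_count_glm(d, "poisson", robust = TRUE)
  expect_identical(pr$coefficients, rp$coefficients)
  expect_gt(sqrt(diag(rp$vcov))["group"], sqrt(diag(pr$vcov))["group"])
})

test_that("converged analytic-gradient fits have near-zero score", {
  d <- sim_zi_data(400, seed = 23)
  fits <- list(fit_logistic(d), fit_count_glm(d, "poisson"),
               fit_zero_inflated(d, "poisson"), fit_hurdle(d, "poisson"))
  for (f in fits) {
    expect_true(f$converged)
    expect_lt(f$gradient_norm, 1e-6)
  }
})

test_that("information criteria follow their defining formulas", {
  d <- sim_zi_data(200, seed = 29)
  f <- fit_zero_inflated(d, "poisson")
  ic <- information_criteria(f)
  expect_equal(ic$AIC, -2 * f$loglik + 2 * f$n_params)
  expect_equal(ic$BIC, -2 * f$loglik + f$n_params * log(f$n))
  expect_equal(ic$LL, as.numeric(logLik(f)))
})
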