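test_that("hurdle zero part is the logistic fit, and likelihoods add", {
  d <- sim_zi_data(500, seed = 1)
  h <- fit_hurdle(d, "poisson")
  lr <- fit_logistic(d)
  expect_equal(unname(h$inflate_coefficients),
               unname(lr$coefficients), tolerance = 1e-8)
  expect_equal(h$loglik, lr$loglik + h$parts$count_loglik)
  # per-subject contributions also add up to the totals
  expect_equal(sum(h$loglik_i), h$loglik, tolerance = 1e-8)
})

test_that("with no zeros the ZIP count part collapses to the Poisson GLM", {
  set.seed(5)
  df <- data.frame(polyps = rpois(300, 4) + 1L, group = rbinom(300, 1, 0.5))
  d <- polyp_data(df, "polyps", "group")
  zf <- fit_zero_inflated(d, "poisson")
  pr <- fit_count_glm(d, "poisson")
  expect_equal(unname(zf$count_coefficients),
               unname(pr$count_coefficients), tolerance = 1e-4)
  expect_lt(max(plogis(d$Z %*% zf$inflate_coefficients)), 1e-3)
})

test_that("all counts positive makes the hurdle degenerate", {
  df <- data.frame(polyps = c(1L, 2L, 3L, 1L), group = c(0, 1, 0, 1))
  d <- polyp_data(df, "polyps", "group")
  expect_error(fit_hurdle(d, "poisson"), "degenerate")
})

test_that("ZIP log-likelihood dominates Poisson on the same design", {
  for (seed in c(2, 3, 4)) {
    d <- sim_zi_data(400, pi0 = 0.35, seed = seed)
    zf <- fit_zero_inflated(d, "poisson")
    pr <- fit_count_glm(d, "poisson")
    expect_gte(zf$loglik, pr$loglik)
  }
})

test_that("mixture likelihood equals the latent-class log-sum-exp", {
  d <- sim_zi_data(60, seed = 6)
  li_fun <- polypcount:::.li_zeroinfl(d, "poisson")
  set.seed(7)
  for (r in 1:100) {
    par <- c(rnorm(2, 0, 0.8), rnorm(2, 0, 1.2))
    mu <- exp(drop(d$X %*% par[1:2]))
    pi <- plogis(drop(d$Z %*% par[3:4]))
    # oracle: enumerate the latent class directly
    oracle <- log(pi * (d$y == 0) + (1 - pi) * dpois(d$y, mu))
    expect_equal(li_fun(par), oracle, tolerance = 1e-10)
  }
})

test_that("ZINB at the dispersion boundary reproduces ZIP coefficients", {
  d <- sim_zi_data(1500, pi0 = 0.3, family = "poisson", seed = 8)
  zip <- fit_zero_inflated(d, "poisson")
  zinb <- suppressWarnings(fit_zero_inflated(d, "negbin"))
  expect_equal(zinb$dispersion, 0)
  expect_equal(unname(zinb$coefficients[1:4]),
               unname(zip$coefficients), tolerance = 1e-3)
  expect_equal(zinb$n_params, zip$n_params + 1L)
})

test_that("component predictions satisfy the mixture identities", {
  d <- sim_zi_data(400, pi0 = 0.45, seed = 9)
  zf <- fit_zero_inflated(d, "poisson")
  pc <- predict_components(zf)
  expect_equal(pc$prob_zero + pc$prob_pos, rep(1, d$n))
  expect_equal(pc$expected_count, (1 - pc$pi) * pc$mu)
  expect_true(all(pc$structural_posterior >= 0 &
                    pc$structural_posterior <= 1))
  f0 <- exp(-pc$mu)
  expect_equal(pc$prob_zero, pc$pi + (1 - pc$pi) * f0)

  # MLE moment identity for an intercept-only ZIP
  d0 <- d
  d0$X <- d0$X[, 1, drop = FALSE]
  d0$Z <- d0$Z[, 1, drop = FALSE]
  zf0 <- fit_zero_inflated(d0, "poisson")
  expect_equal(sum(predict_components(zf0)$expected_count), sum(d0$y),
               tolerance = 1e-6)
})

test_that("hurdle predictions treat every zero as a hurdle zero", {
  d <- sim_zi_data(300, seed = 10)
  h <- fit_hurdle(d, "poisson")
  pc <- predict_components(h)
  expect_equal(pc$pi, pc$prob_zero)
  expect_equal(pc$prob_pos,
               unname(plogis(drop(d$Z %*% h$inflate_coefficients))))
  expect_equal(pc$structural_posterior, rep(1, d$n))
  # truncated mean: E[Y] = P(Y>0) * mu / (1 - e^-mu)
  expect_equal(pc$expected_count,
               pc$prob_pos * pc$mu / (1 - exp(-pc$mu)))
})

test_that("posterior structural-zero probabilities track the generator labels", {
  sc <- scenario_presets()$s1
  d <- generate_dataset(sc, seed = 12)
  lab <- attr(d, "latent")
  zf <- fit_zero_inflated(d, "poisson")
  pc <- predict_components(zf)
  zeros <- d$y == 0
  frac_structural <- mean(lab$structural[zeros])
  expect_equal(mean(pc$structural_posterior[zeros]), frac_structural,
               tolerance = 0.05)
})

test_that("ZIP estimates agree with the independent glmmTMB fit", {
  d <- sim_zi_data(600, mu0 = 1.8, beta = 0.4, pi0 = 0.4, gamma = -0.3,
                   seed = 14)
  zf <- fit_zero_inflated(d, "poisson")
  ref <- suppressWarnings(glmmTMB::glmmTMB(
    y ~ x, ziformula = ~x, family = poisson(),
    data = data.frame(y = d$y, x = d$X[, "group"])))
  expect_equal(unname(zf$count_coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(unname(zf$inflate_coefficients),
               unname(glmmTMB::fixef(ref)$zi), tolerance = 1e-3)
  expect_equal(zf$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("a design mismatch between fit and prediction data is caught", {
  d <- sim_zi_data(200, seed = 15)
  zf <- fit_zero_inflated(d, "poisson")
  d2 <- sim_count_data(200, covariate = TRUE, seed = 15)
  expect_error(predict_components(zf, d2), "design columns")
})
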