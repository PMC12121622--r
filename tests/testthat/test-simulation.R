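test_that("intercept calibration matches the closed forms", {
  # no group effect: Poisson mu = -log(SZ)
  sc <- scenario(structural_zero_prob = 0.5, sampling_zero_target = 0.18,
                 true_beta = 0)
  expect_equal(exp(calibrate_count_intercept(sc)), -log(0.18),
               tolerance = 1e-8)
  expect_equal(exp(calibrate_count_intercept(
    scenario(structural_zero_prob = 0.5, sampling_zero_target = 0.01,
             true_beta = 0))), 4.6052, tolerance = 1e-4)

  # NB2 with alpha = 0.5: (1 + 0.5 mu)^-2 = 0.289  =>  mu ~ 1.72
  sc_nb <- scenario(structural_zero_prob = 0.5,
                    sampling_zero_target = 0.289, true_beta = 0,
                    count_family = "negbin", alpha = 0.5)
  mu <- exp(calibrate_count_intercept(sc_nb))
  expect_equal((1 + 0.5 * mu)^(-2), 0.289, tolerance = 1e-8)
  expect_equal(mu, 1.72, tolerance = 0.01)

  # with a group effect the marginal zero probability hits the target
  sc2 <- scenario_presets()$s2
  b0 <- calibrate_count_intercept(sc2)
  marg <- 0.5 * exp(-exp(b0)) + 0.5 * exp(-exp(b0 + 0.4))
  expect_equal(marg, 0.01, tolerance = 1e-8)

  expect_error(calibrate_count_intercept(
    scenario(structural_zero_prob = 0.1,
             sampling_zero_target = 1 - 1e-12)),
    "unattainable")
})

test_that("generated zero fractions match the scenario arithmetic", {
  sc <- scenario_presets()$s2
  zf <- vapply(1:100, function(s) {
    mean(generate_dataset(sc, seed = s)$y == 0)
  }, numeric(1))
  # overall zero proportion TZ + (1 - TZ) SZ = 0.16 + 0.84 * 0.01
  expect_equal(mean(zf), 0.16 + 0.84 * 0.01, tolerance = 0.02)

  sc1 <- scenario_presets()$s1
  zf1 <- vapply(1:60, function(s) {
    mean(generate_dataset(sc1, seed = s)$y == 0)
  }, numeric(1))
  expect_equal(mean(zf1), 0.525 + 0.475 * 0.18, tolerance = 0.02)
})

test_that("degenerate scenarios behave as declared", {
  sc <- scenario(structural_zero_prob = 1e-9,
                 sampling_zero_target = 1e-6, n_subjects = 400)
  d <- generate_dataset(sc, seed = 1)
  expect_lte(mean(d$y == 0), 0.005)

  sc0 <- scenario(structural_zero_prob = 0.3, sampling_zero_target = 0.2,
                  true_beta = 0, n_subjects = 50000)
  d0 <- generate_dataset(sc0, seed = 2)
  g <- d0$X[, "group"]
  expect_equal(mean(d0$y[g == 1]), mean(d0$y[g == 0]), tolerance = 0.05)
})

test_that("latent labels reproduce the outcome product structure", {
  d <- generate_dataset(scenario_presets()$s1, seed = 3)
  lab <- attr(d, "latent")
  expect_identical(d$y, as.integer((1 - lab$structural) * lab$count))
  expect_equal(mean(lab$structural), 0.525, tolerance = 0.08)
})

test_that("a single replication yields degenerate coverage", {
  sc <- scenario_presets()$s2
  mc <- run_monte_carlo(sc, "ZIP", n_replications = 1, seed = 5)
  expect_true(mc$coverage %in% c(0, 1))
  expect_equal(mc$relative_bias, mc$bias / sc$true_beta)
  expect_equal(mc$n_failed, 0)
})

test_that("identical master seeds give bit-identical summaries", {
  sc <- scenario_presets()$s2
  m1 <- run_monte_carlo(sc, c("PR", "ZIP"), n_replications = 15, seed = 6)
  m2 <- run_monte_carlo(sc, c("PR", "ZIP"), n_replications = 15, seed = 6)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("doubling the sample size shrinks confidence width like 1/sqrt(2)", {
  sc <- scenario_presets()$s2
  sc_big <- sc
  sc_big$n_subjects <- 850L
  m_small <- run_monte_carlo(sc, "ZIP", n_replications = 60, seed = 7)
  m_big <- run_monte_carlo(sc_big, "ZIP", n_replications = 60, seed = 7)
  ratio <- m_big$confidence_width / m_small$confidence_width
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.08)
})

test_that("the scenario-3 condition generates overdispersed confounded counts", {
  sc <- scenario_presets()$s3
  d <- generate_dataset(sc, seed = 8)
  expect_true("confounder" %in% colnames(d$X))
  expect_false("confounder" %in% colnames(d$Z))
  expect_equal(mean(d$y == 0), 0.526 + 0.474 * 0.289, tolerance = 0.07)
})
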