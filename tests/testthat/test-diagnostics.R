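test_that("score statistic grows when zeros are injected", {
  d <- sim_zi_data(400, pi0 = 0.2, seed = 1)
  s1 <- score_test_zero_inflation(fit_count_glm(d, "poisson"), d)
  extra <- polyp_data(
    data.frame(polyps = c(d$y, rep(0L, 150)),
               group = c(d$X[, "group"], rbinom(150, 1, 0.5))),
    outcome = "polyps", group = "group")
  s2 <- score_test_zero_inflation(fit_count_glm(extra, "poisson"), extra)
  expect_gt(s2$statistic, s1$statistic)
  expect_lt(s1$p_value, 0.05)
})

test_that("Vuong test degenerates to zero for identical models", {
  d <- sim_zi_data(300, seed = 2)
  pr <- fit_count_glm(d, "poisson")
  out <- vuong_test_corrected(pr, pr)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("the AIC correction penalizes the larger model", {
  d <- sim_zi_data(400, pi0 = 0.35, seed = 3)
  zf <- fit_zero_inflated(d, "poisson")
  pr <- fit_count_glm(d, "poisson")
  z_none <- vuong_test_corrected(zf, pr, "none")
  z_aic <- vuong_test_corrected(zf, pr, "AIC")
  z_bic <- vuong_test_corrected(zf, pr, "BIC")
  expect_lt(z_aic$statistic, z_none$statistic)
  expect_lt(z_bic$statistic, z_aic$statistic)
  expect_lt(z_aic$p_value, 0.05)
  d2 <- polypcount:::subset_polyp_data(d, 1:100)
  expect_error(vuong_test_corrected(zf, fit_count_glm(d2, "poisson")),
               "different numbers")
})

test_that("excess-zero removal is deterministic and tracks the generator", {
  sc <- scenario_presets()$s1
  d <- generate_dataset(sc, seed = 4)
  zf <- fit_zero_inflated(d, "poisson")
  r1 <- remove_excess_zeros(d, zf)
  r2 <- remove_excess_zeros(d, zf)
  expect_identical(r1, r2)
  removed_frac <- attr(r1, "n_removed") / d$n
  expect_equal(removed_frac, sc$structural_zero_prob, tolerance = 0.06)
  # the original object is untouched
  expect_equal(d$n, sc$n_subjects)

  # a fit with (numerically) no structural zeros removes nothing
  zf0 <- zf
  zf0$coefficients[grep("^zero_", names(zf0$coefficients))] <- c(-30, 0)
  zf0$inflate_coefficients <- c(-30, 0)
  r0 <- remove_excess_zeros(d, zf0)
  expect_equal(attr(r0, "n_removed"), 0)
  expect_identical(r0$y, d$y)
})

test_that("dispersion tests point in the right direction", {
  d_over <- sim_count_data(2500, mu0 = 1.5, beta = 0.3, family = "negbin",
                           alpha = 0.8, seed = 5)
  dt <- dispersion_tests(d_over)
  expect_equal(dt$auxiliary$direction, "overdispersion")
  expect_lt(dt$nb_boundary$p_value, 0.05)
  expect_gt(dt$nb_boundary$estimate, 0.4)

  d_equi <- sim_count_data(2500, mu0 = 1.5, beta = 0.3, seed = 6)
  dt2 <- suppressWarnings(dispersion_tests(d_equi))
  expect_equal(dt2$auxiliary$direction, "equidispersion")
  expect_gt(dt2$nb_boundary$p_value, 0.05)
})

test_that("goodness of fit separates the right and wrong model", {
  d <- sim_zi_data(800, mu0 = 1.8, pi0 = 0.4, seed = 7)
  zf <- fit_zero_inflated(d, "poisson")
  pr <- fit_count_glm(d, "poisson")
  g_zip <- gof_chisq(zf, d)
  g_pr <- gof_chisq(pr, d)
  expect_gt(g_zip$p_value, 0.05)
  expect_lt(g_pr$p_value, 0.001)
  expect_gt(g_pr$statistic, g_zip$statistic)

  # record order is irrelevant
  perm <- polypcount:::subset_polyp_data(d, rev(seq_len(d$n)))
  zf_perm <- fit_zero_inflated(perm, "poisson")
  expect_equal(gof_chisq(zf_perm, perm)$statistic, g_zip$statistic,
               tolerance = 1e-6)
})

test_that("the flowchart takes the single-distribution branch without excess zeros", {
  d <- sim_count_data(800, mu0 = 1.2, beta = 0.3, seed = 8)
  rep <- suppressWarnings(select_model_flowchart(d, "mixed"))
  expect_true(rep$recommended_model %in% c("PR", "RP", "NB", "GP"))
  expect_match(paste(rep$rationale, collapse = " "), "absent")
})

test_that("the flowchart recommends inflated or hurdle models per zero type", {
  d <- sim_zi_data(800, mu0 = 1.8, pi0 = 0.4, seed = 9)
  rep_mixed <- suppressWarnings(select_model_flowchart(d, "mixed"))
  expect_true(rep_mixed$recommended_model %in%
                c("ZIP", "ZIRP", "ZINB", "ZIGP"))
  rep_struct <- suppressWarnings(
    select_model_flowchart(d, "structural_only"))
  expect_true(rep_struct$recommended_model %in% c("ZHP", "ZHNB"))
  expect_true(rep_mixed$recommended_model %in% rep_mixed$fit_table$model)

  # deterministic given (data, zero_type)
  rep2 <- suppressWarnings(select_model_flowchart(d, "mixed"))
  expect_identical(rep_mixed$recommended_model, rep2$recommended_model)
  expect_identical(rep_mixed$fit_table, rep2$fit_table)
})

test_that("contradictory zero declarations are rejected", {
  set.seed(10)
  df <- data.frame(polyps = rpois(100, 3) + 1L, group = rbinom(100, 1, 0.5))
  d <- polyp_data(df, "polyps", "group")
  expect_error(select_model_flowchart(d, "mixed"), "no zero counts")
})
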