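# Fixture builders: everything is generated in code at test time.

# zero-inflated data with explicit two-part parameters
sim_zi_data <- function(n, mu0 = 1.5, beta = 0.4, pi0 = 0.4, gamma = 0,
                        family = "poisson", alpha = 0.5, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  pi <- plogis(qlogis(pi0) + gamma * x)
  mu <- mu0 * exp(beta * x)
  cnt <- if (family == "poisson") rpois(n, mu)
    else rnbinom(n, size = 1 / alpha, mu = mu)
  y <- ifelse(rbinom(n, 1, pi) == 1, 0L, cnt)
  polyp_data(data.frame(polyps = y, group = x),
             outcome = "polyps", group = "group")
}

# plain count data (no inflation), optionally with a covariate
sim_count_data <- function(n, mu0 = 2, beta = 0.4, family = "poisson",
                           alpha = 0.5, seed = 1, covariate = FALSE) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  z <- if (covariate) rnorm(n) else NULL
  mu <- mu0 * exp(beta * x + if (covariate) 0.2 * z else 0)
  y <- if (family == "poisson") rpois(n, mu)
    else rnbinom(n, size = 1 / alpha, mu = mu)
  df <- data.frame(polyps = y, group = x)
  covs <- character(0)
  if (covariate) {
    df$age <- z
    covs <- "age"
  }
  polyp_data(df, outcome = "polyps", group = "group", covariates = covs)
}

# expand a 2x2 table (events / totals per group) into subject-level data
data_from_2x2 <- function(pos1, n1, pos0, n0) {
  polyp_data(data.frame(
    polyps = c(rep(1L, pos1), rep(0L, n1 - pos1),
               rep(1L, pos0), rep(0L, n0 - pos0)),
    group = c(rep(1L, n1), rep(0L, n0))),
    outcome = "polyps", group = "group")
}
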