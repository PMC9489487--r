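test_that("prior specifications expose the documented defaults", {
  p <- prior_spec()
  expect_equal(p$slope_location, 0)
  expect_equal(p$slope_scale, 1)
  expect_equal(p$sigma_rate, 1)
  v <- prior_spec("vague")
  expect_equal(v$slope_scale, 10)
  expect_equal(v$sigma_rate, 0.1)
  i <- prior_spec("informative")
  expect_null(i$slope_location)   # resolved from truth at fit time
  expect_equal(i$slope_scale, 0.1)
  expect_error(prior_spec(slope_scale = -1), "positive")
  s <- sampler_config()
  expect_equal(c(s$n_chains, s$n_warmup, s$n_sampling), c(4L, 1000L, 1000L))
})

test_that("sampling an empty dataset reproduces the prior", {
  empty <- data.frame(body = numeric(0), z = numeric(0))
  fit <- fit_bayes_linear(empty, "z", "body",
                          sampler = sampler_config(n_chains = 2,
                                                   n_warmup = 200,
                                                   n_sampling = 2000,
                                                   base_seed = 4))
  # slopes/intercept ~ N(0,1), sigma ~ Exp(1): mean 1, sd 1
  expect_equal(unname(fit$posterior_mean[c("intercept", "body")]),
               c(0, 0), tolerance = 0.1)
  expect_equal(unname(fit$posterior_sd[c("intercept", "body")]),
               c(1, 1), tolerance = 0.1)
  expect_equal(unname(fit$posterior_mean["sigma"]), 1, tolerance = 0.1)
  expect_true(all(fit$draws[, "sigma"] > 0))
})

test_that("posterior summaries are exact functions of the draws", {
  sc <- sim_scenario("case1", n_species = 60, base_seed = 2)
  d <- simulate_case1(sc, 1)
  fit <- fit_bayes_linear(d, "brain", c("body", "z"),
                          sampler = fast_sampler(7))
  expect_equal(nrow(fit$draws), 2L * 500L)  # n_chains x n_sampling
  expect_equal(unname(fit$posterior_mean), unname(colMeans(fit$draws)))
  expect_equal(unname(fit$posterior_sd),
               unname(apply(fit$draws, 2, sd)))
  dg <- fit$diagnostics
  expect_true(all(dg$effective_sample_size > 0))
  expect_true(all(dg$rhat >= 1 - 1e-3, na.rm = TRUE))
  expect_identical(dg$n_divergent, integer(2))
})

test_that("Bayesian and frequentist linear fits agree on large data", {
  sc <- sim_scenario("case1", n_species = 10000L, base_seed = 6)
  d <- simulate_case1(sc, 1)
  ols <- fit_linear(d$data$brain, d$data[c("body", "z")])
  fit <- fit_bayes_linear(d, "brain", c("body", "z"),
                          sampler = fast_sampler(9))
  for (nm in c("body", "z")) {
    cf <- coef_linear(ols, nm)
    expect_lt(abs(fit$posterior_mean[nm] - cf$estimate),
              3 * fit$posterior_sd[nm])
    expect_equal(unname(fit$posterior_sd[nm]), cf$se, tolerance = 0.2)
  }
})

test_that("with sigma fixed and flat-limit priors the posterior mean is OLS", {
  sc <- sim_scenario("case1", n_species = 1000L, base_seed = 14)
  d <- simulate_case1(sc, 1)
  ols <- fit_linear(d$data$brain, d$data[c("body", "z")])
  fit <- fit_bayes_linear(
    d, "brain", c("body", "z"),
    priors = prior_spec("custom", slope_scale = 100, intercept_scale = 100),
    sampler = sampler_config(n_chains = 4, n_warmup = 500,
                             n_sampling = 2500, base_seed = 15),
    sigma_fixed = 1)
  for (nm in c("body", "z"))
    expect_equal(unname(fit$posterior_mean[nm]),
                 coef_linear(ols, nm)$estimate, tolerance = 1e-3)
})

test_that("pooled posterior means are stable across sampler seeds", {
  sc <- sim_scenario("case2", n_species = 100, base_seed = 3)
  d <- simulate_case2(sc, 1)
  f1 <- fit_sem(d, sampler = fast_sampler(101))
  f2 <- fit_sem(d, sampler = fast_sampler(202))
  mcse <- fit_mcse <- f1$posterior_sd /
    sqrt(pmax(f1$diagnostics$effective_sample_size, 1))
  expect_true(all(abs(f1$posterior_mean - f2$posterior_mean) <
                    6 * mcse + 1e-3))
})

test_that("SEM joint log-density equals the sum of the three Normal densities", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    df <- data.frame(body = rnorm(n), brain = rnorm(n), z = rnorm(n))
    pars <- c(alpha_body = rnorm(1), alpha_brain = rnorm(1),
              alpha_z = rnorm(1), beta_body = rnorm(1),
              gamma_body = rnorm(1), gamma_brain = rnorm(1),
              sigma_body = rexp(1) + 0.1, sigma_brain = rexp(1) + 0.1,
              sigma_z = rexp(1) + 0.1)
    # independent hand-written Gaussian log-density
    ld <- function(x, mu, s) -0.5 * log(2 * pi) - log(s) -
      0.5 * ((x - mu) / s)^2
    mub <- pars["alpha_brain"] + pars["beta_body"] * df$body
    muz <- pars["alpha_z"] + pars["gamma_body"] * df$body +
      pars["gamma_brain"] * (df$brain - mub)
    want <- sum(ld(df$body, pars["alpha_body"], pars["sigma_body"])) +
      sum(ld(df$brain, mub, pars["sigma_brain"])) +
      sum(ld(df$z, muz, pars["sigma_z"]))
    expect_equal(sem_loglik(pars, df), unname(want), tolerance = 1e-8)
  }
})

test_that("the SEM recovers the case 2 generating parameters", {
  sc <- sim_scenario("case2", n_species = 100, base_seed = 5)
  d <- simulate_case2(sc, 1)
  fit <- fit_sem(d, sampler = fast_sampler(55))
  for (nm in c("beta_body", "gamma_body", "gamma_brain"))
    expect_lt(abs(fit$posterior_mean[nm] - 1), 3 * fit$posterior_sd[nm])
  # the brain submodel's residual SD is the SD of latent relative brain
  # size, 1 by construction
  expect_lt(abs(fit$posterior_mean["sigma_brain"] - 1),
            3 * fit$posterior_sd["sigma_brain"])
})

test_that("with gamma_brain = 0 the SEM body effect matches a plain regression", {
  sc <- sim_scenario("case2", n_species = 200, gamma_brain = 0,
                     base_seed = 23)
  d <- simulate_case2(sc, 1)
  sem <- fit_sem(d, sampler = fast_sampler(31))
  lin <- fit_bayes_linear(d, "z", "body", sampler = fast_sampler(32))
  expect_lt(abs(sem$posterior_mean["gamma_body"] -
                  lin$posterior_mean["body"]),
            3 * sem$posterior_sd["gamma_body"])
})

test_that("informative priors cannot rescue the collider-biased body slope", {
  sc <- sim_scenario("case2", n_species = 100, base_seed = 44)
  d <- simulate_case2(sc, 1)
  fit <- fit_bayes_linear(d, "z", c("body", "brain"),
                          priors = prior_spec("informative"),
                          sampler = fast_sampler(45))
  m <- fit$posterior_mean["body"]; s <- fit$posterior_sd["body"]
  expect_gt(abs(1 - m), 2 * s)  # true value excluded despite the prior
})

test_that("informative priors without recorded truth are an error", {
  df <- data.frame(body = rnorm(10), brain = rnorm(10), z = rnorm(10))
  expect_error(fit_bayes_linear(df, "z", c("body", "brain"),
                                priors = prior_spec("informative"),
                                sampler = fast_sampler()),
               "truth|slope_location")
})
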