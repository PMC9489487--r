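test_that("bias uses the truth-minus-estimate convention", {
  expect_equal(bias(1.0, 1.0), 0.0)
  expect_equal(bias(0.0, 1.0), 1.0)   # collider-biased body estimate
  expect_equal(bias(1.02, 1.0), -0.02)
})

test_that("coverage is the 2-SE/2-SD interval indicator", {
  expect_true(covered(1.0, 0.1, 1.15))
  expect_false(covered(1.0, 0.1, 1.25))
  # a near-zero estimate with small SE can never cover a truth of 1
  expect_false(covered(0.0, 0.16, 1.0))
  expect_error(covered(1, 0, 1), "positive")
})

test_that("single-replicate coverage is exactly 0 or 1", {
  sc <- sim_scenario("case2", n_species = 50, n_replicates = 1,
                     base_seed = 9)
  ex <- run_experiment(sc, models = "linear")
  expect_true(all(ex$summary$coverage %in% c(0, 1)))
  expect_true(all(ex$summary$n_replicates == 1L))
})

test_that("summary is a pure function of the persisted replicate table", {
  sc <- sim_scenario("case1", n_species = 60, n_replicates = 5,
                     base_seed = 12)
  dir <- withr::local_tempdir()
  ex <- run_experiment(sc, models = "linear", out_dir = dir)
  expect_true(file.exists(file.path(dir, "replicates.csv")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "run_log.txt")))
  back <- read.csv(file.path(dir, "replicates.csv"))
  expect_equal(summarize_replicates(back), ex$summary, tolerance = 1e-12)
  # coverage granularity: multiples of 1/R
  expect_true(all(abs(ex$summary$coverage * 5 -
                        round(ex$summary$coverage * 5)) < 1e-12))
})

test_that("truth in replicate rows comes from the datasets", {
  sc <- sim_scenario("case2", n_species = 50, n_replicates = 2,
                     gamma_body = 2, gamma_brain = 0.5, base_seed = 7)
  ex <- run_experiment(sc, models = "linear")
  expect_equal(unique(ex$replicates$truth[ex$replicates$parameter == "body"]), 2)
  expect_equal(unique(ex$replicates$truth[ex$replicates$parameter == "brain"]), 0.5)
})

test_that("failed fits are excluded with an explicit record", {
  # n = 3 species cannot support a 3-coefficient regression: every
  # linear fit fails and is logged
  sc <- sim_scenario("case1", n_species = 3, n_replicates = 2,
                     base_seed = 1)
  ex <- run_experiment(sc, models = "linear")
  expect_equal(nrow(ex$failures), 2L)
  expect_equal(nrow(ex$replicates), 0L)
  expect_match(ex$failures$message[1], "observations")
  expect_equal(nrow(ex$summary), 0L)
})

test_that("the SEM is refused outside its causal structure", {
  sc <- sim_scenario("case1", n_species = 50, base_seed = 2)
  expect_error(run_experiment(sc, models = c("linear", "sem")), "case2")
})

test_that("correlation_summary averages the body-brain correlation", {
  sc <- sim_scenario("case2", n_species = 100000L, base_seed = 19)
  d <- simulate_case2(sc, 1)
  expect_equal(correlation_summary(list(d)), 1 / sqrt(2), tolerance = 0.005)
  # brain identical to body
  ident <- d
  ident$data$brain <- ident$data$body
  expect_equal(correlation_summary(list(ident)), 1.0)
  flat <- d
  flat$data$body <- rep(0, nrow(flat$data))
  expect_error(correlation_summary(list(flat)), "zero-variance")
})

test_that("presets encode the reported analysis conditions", {
  t1 <- preset_experiment("table1", base_seed = 1)
  expect_length(t1, 2)
  expect_equal(vapply(t1, function(x) x$scenario$case_id, ""),
               c("case1", "case2"))
  expect_true(all(vapply(t1, function(x) x$scenario$n_species, 1L) == 100L))
  expect_true(all(vapply(t1, function(x) x$scenario$n_replicates, 1L) == 20L))

  n20 <- preset_experiment("appendix-n20")
  expect_true(all(vapply(n20, function(x) x$scenario$n_species, 1L) == 20L))

  sb <- preset_experiment("appendix-strong-body")[[1]]
  expect_equal(sb$scenario$gamma_body, 2)
  expect_equal(sb$scenario$gamma_brain, 0.5)
  sbr <- preset_experiment("appendix-strong-brain")[[1]]
  expect_equal(sbr$scenario$gamma_body, 0.5)
  expect_equal(sbr$scenario$gamma_brain, 2)

  inf <- preset_experiment("appendix-informative")[[1]]
  expect_equal(inf$priors$label, "informative")
  conf <- preset_experiment("appendix-case1-confounded")[[1]]
  expect_equal(conf$scenario$case_id, "case1_confounded")
  # two presets with the same base seed build identical scenarios
  expect_identical(preset_experiment("table1", 5), preset_experiment("table1", 5))
})

test_that("strong-effect scenarios show the predicted attenuation and sign flip", {
  # strong body effect: OLS body coefficient positive but pulled toward
  # gamma_body - gamma_brain = 1.5; strong brain effect: negative, -1.5
  sc_sb <- sim_scenario("case2", n_species = 1000, n_replicates = 5,
                        gamma_body = 2, gamma_brain = 0.5, base_seed = 61)
  ex_sb <- run_experiment(sc_sb, models = "linear")
  est <- with(ex_sb$replicates, point_estimate[parameter == "body"])
  expect_true(all(est > 0))
  expect_equal(mean(est), 1.5, tolerance = 0.1)

  sc_br <- sim_scenario("case2", n_species = 1000, n_replicates = 5,
                        gamma_body = 0.5, gamma_brain = 2, base_seed = 62)
  ex_br <- run_experiment(sc_br, models = "linear")
  est <- with(ex_br$replicates, point_estimate[parameter == "body"])
  expect_true(all(est < 0))
  expect_equal(mean(est), -1.5, tolerance = 0.1)
})
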