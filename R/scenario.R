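#' Define a simulation scenario
#'
#' A `sim_scenario` is the full generative specification of one simulation
#' condition: which causal structure to simulate, how many species and
#' replicate datasets, the effect sizes on every causal path, the residual
#' standard deviations, and the base seed from which every replicate's
#' stream is derived.
#'
#' Three causal structures are supported:
#' \describe{
#'   \item{`case1`}{Brain size is the response. `body ~ N(0,1)`,
#'     `z ~ N(0,1)` independent of body, and
#'     `brain ~ N(beta_body * body + beta_z * z, sigma_brain)`.}
#'   \item{`case1_confounded`}{As `case1`, but with an additional causal
#'     path from body size to z: `z ~ N(gamma_body * body, sigma_z)`, so
#'     body size confounds the z–brain relationship.}
#'   \item{`case2`}{Relative brain size is a predictor. `body ~ N(0,1)`,
#'     latent relative brain size `rel ~ N(0,1)` independent of body,
#'     absolute brain size is the exact sum
#'     `brain = beta_body * body + rel` (no residual noise), and
#'     `z ~ N(gamma_body * body + gamma_brain * rel, sigma_z)`. Absolute
#'     brain size is a collider: conditioning on it in a regression of z
#'     opens a back-door path through body size.}
#' }
#'
#' All variables live on a standardized (log) scale with mean 0 and unit
#' SD by construction; no further standardization is applied.
#'
#' @param case_id one of `"case1"`, `"case1_confounded"`, `"case2"`.
#' @param n_species number of species per dataset (at least 3, so a
#'   two-predictor regression is estimable).
#' @param n_replicates number of replicate datasets.
#' @param beta_body allometric slope of brain on body (both cases).
#' @param beta_z slope of z in the brain equation (case 1 only).
#' @param gamma_body direct effect of body on z (case 2 and confounded
#'   case 1).
#' @param gamma_brain effect of relative brain size on z (case 2 only).
#' @param sigma_brain residual SD of brain (case 1 only; case 2 brain is
#'   an exact sum).
#' @param sigma_z residual SD of z (case 2 and confounded case 1).
#' @param base_seed integer seed; each replicate's seed is a deterministic
#'   function of `base_seed` and the replicate index.
#'
#' @return an object of class `sim_scenario`.
#' @examples
#' sc <- sim_scenario("case2", n_species = 100, n_replicates = 20)
#' sc
#' @export
sim_scenario <- function(case_id = c("case1", "case1_confounded", "case2"),
                         n_species = 100L,
                         n_replicates = 20L,
                         beta_body = 1,
                         beta_z = 1,
                         gamma_body = 1,
                         gamma_brain = 1,
                         sigma_brain = 1,
                         sigma_z = 1,
                         base_seed = 1L) {
  case_id <- match.arg(case_id)
  n_species <- as.integer(n_species)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_species) || n_species < 3L)
    stop("`n_species` must be an integer >= 3 (regression with two predictors must be estimable)",
         call. = FALSE)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  for (nm in c("beta_body", "beta_z", "gamma_body", "gamma_brain")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  if (!is.numeric(sigma_brain) || sigma_brain <= 0)
    stop("`sigma_brain` must be strictly positive", call. = FALSE)
  if (!is.numeric(sigma_z) || sigma_z <= 0)
    stop("`sigma_z` must be strictly positive", call. = FALSE)
  base_seed <- as.integer(base_seed)
  if (is.na(base_seed)) stop("`base_seed` must be an integer", call. = FALSE)

  structure(
    list(case_id = case_id,
         n_species = n_species,
         n_replicates = n_replicates,
         beta_body = beta_body,
         beta_z = beta_z,
         gamma_body = gamma_body,
         gamma_brain = gamma_brain,
         sigma_brain = sigma_brain,
         sigma_z = sigma_z,
         base_seed = base_seed),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario <", x$case_id, ">\n", sep = "")
  cat("  species per dataset: ", x$n_species,
      ",  replicates: ", x$n_replicates,
      ",  base seed: ", x$base_seed, "\n", sep = "")
  eff <- switch(x$case_id,
    case1 = sprintf("beta_body = %g, beta_z = %g, sigma_brain = %g",
                    x$beta_body, x$beta_z, x$sigma_brain),
    case1_confounded = sprintf(
      "beta_body = %g, beta_z = %g, gamma_body = %g, sigma_brain = %g, sigma_z = %g",
      x$beta_body, x$beta_z, x$gamma_body, x$sigma_brain, x$sigma_z),
    case2 = sprintf("beta_body = %g, gamma_body = %g, gamma_brain = %g, sigma_z = %g",
                    x$beta_body, x$gamma_body, x$gamma_brain, x$sigma_z))
  cat("  effects: ", eff, "\n", sep = "")
  invisible(x)
}

#' Derive a deterministic per-replicate seed
#'
#' Pure function of `(base_seed, replicate_index)`, kept inside
#' `[1, 2^31 - 2]` so [set.seed()] behaves identically on every
#' platform. Every source of randomness in the package (simulator
#' replicates, MCMC chains) derives its seed through this function, so
#' replicates are mutually independent streams yet each one can be
#' regenerated in isolation.
#'
#' @param base_seed integer base seed.
#' @param replicate_index non-negative integer stream index.
#' @return a single integer seed.
#' @export
replicate_seed <- function(base_seed, replicate_index) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(base_seed) %% m + as.numeric(replicate_index) * 1000003) %% m
  as.integer(s %% (m - 1) + 1)
}

# truth: the generating parameter values the evaluate module scores
scenario_truth <- function(scenario) {
  switch(scenario$case_id,
    case1 = c(beta_body = scenario$beta_body, beta_z = scenario$beta_z),
    case1_confounded = c(beta_body = scenario$beta_body,
                         beta_z = scenario$beta_z,
                         gamma_body = scenario$gamma_body),
    case2 = c(beta_body = scenario$beta_body,
              gamma_body = scenario$gamma_body,
              gamma_brain = scenario$gamma_brain))
}
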