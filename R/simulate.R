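#' Simulate one replicate dataset
#'
#' `simulate_dataset()` dispatches on `scenario$case_id`;
#' `simulate_case1()`, `simulate_case1_confounded()` and
#' `simulate_case2()` implement the three generative structures directly.
#' Each call is fully deterministic given `(scenario$base_seed,
#' replicate_index)`: the replicate seed is derived as a pure function of
#' both, so replicates are mutually independent streams and any replicate
#' can be regenerated in isolation.
#'
#' Under `case2` the absolute brain size is constructed as the exact,
#' noise-free sum `brain = beta_body * body + rel`, so the identity
#' `brain - beta_body * body - rel == 0` holds to machine precision in
#' every simulated dataset.
#'
#' @param scenario a [sim_scenario()].
#' @param replicate_index which replicate to generate, in
#'   `1:scenario$n_replicates`.
#'
#' @return an object of class `brain_dataset`: a list with
#'   \describe{
#'     \item{data}{data.frame with columns `species_index`, `body`,
#'       `brain`, `z` and, for simulated case 2, `rel_true` (the latent
#'       relative brain size).}
#'     \item{truth}{named numeric vector of the generating parameter
#'       values scored by the evaluation module.}
#'     \item{case_id, replicate_index, seed_used}{provenance fields.}
#'   }
#' @examples
#' sc <- sim_scenario("case2", n_species = 50, base_seed = 42)
#' d <- simulate_dataset(sc, 1)
#' identical(d$data$brain, d$data$body + d$data$rel_true)  # TRUE, bit-exact
#' @export
simulate_dataset <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  switch(scenario$case_id,
    case1 = simulate_case1(scenario, replicate_index),
    case1_confounded = simulate_case1_confounded(scenario, replicate_index),
    case2 = simulate_case2(scenario, replicate_index))
}

check_replicate_index <- function(scenario, replicate_index) {
  replicate_index <- as.integer(replicate_index)
  if (is.na(replicate_index) || replicate_index < 1L ||
      replicate_index > scenario$n_replicates)
    stop("`replicate_index` must be in 1:", scenario$n_replicates, call. = FALSE)
  replicate_index
}

new_brain_dataset <- function(df, truth, case_id, replicate_index, seed_used) {
  df$species_index <- seq_len(nrow(df))
  cols <- intersect(c("species_index", "body", "brain", "z", "rel_true"),
                    names(df))
  structure(
    list(data = df[, cols, drop = FALSE],
         truth = truth,
         case_id = case_id,
         replicate_index = replicate_index,
         seed_used = seed_used),
    class = "brain_dataset")
}

#' @rdname simulate_dataset
#' @export
simulate_case1 <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$case_id != "case1")
    stop("scenario$case_id must be 'case1'", call. = FALSE)
  replicate_index <- check_replicate_index(scenario, replicate_index)
  seed <- replicate_seed(scenario$base_seed, replicate_index)
  set.seed(seed)
  n <- scenario$n_species
  body <- stats::rnorm(n)
  z <- stats::rnorm(n)
  brain <- stats::rnorm(n,
    mean = scenario$beta_body * body + scenario$beta_z * z,
    sd = scenario$sigma_brain)
  new_brain_dataset(
    data.frame(body = body, brain = brain, z = z),
    truth = scenario_truth(scenario),
    case_id = scenario$case_id,
    replicate_index = replicate_index,
    seed_used = seed)
}

#' @rdname simulate_dataset
#' @export
simulate_case1_confounded <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$case_id != "case1_confounded")
    stop("scenario$case_id must be 'case1_confounded'", call. = FALSE)
  replicate_index <- check_replicate_index(scenario, replicate_index)
  seed <- replicate_seed(scenario$base_seed, replicate_index)
  set.seed(seed)
  n <- scenario$n_species
  body <- stats::rnorm(n)
  # body now causes z as well as brain, opening a confounding path
  z <- stats::rnorm(n, mean = scenario$gamma_body * body, sd = scenario$sigma_z)
  brain <- stats::rnorm(n,
    mean = scenario$beta_body * body + scenario$beta_z * z,
    sd = scenario$sigma_brain)
  new_brain_dataset(
    data.frame(body = body, brain = brain, z = z),
    truth = scenario_truth(scenario),
    case_id = scenario$case_id,
    replicate_index = replicate_index,
    seed_used = seed)
}

#' @rdname simulate_dataset
#' @export
simulate_case2 <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$case_id != "case2")
    stop("scenario$case_id must be 'case2'", call. = FALSE)
  replicate_index <- check_replicate_index(scenario, replicate_index)
  seed <- replicate_seed(scenario$base_seed, replicate_index)
  set.seed(seed)
  n <- scenario$n_species
  body <- stats::rnorm(n)
  rel <- stats::rnorm(n)
  brain <- scenario$beta_body * body + rel  # exact sum, no residual noise
  z <- stats::rnorm(n,
    mean = scenario$gamma_body * body + scenario$gamma_brain * rel,
    sd = scenario$sigma_z)
  new_brain_dataset(
    data.frame(body = body, brain = brain, z = z, rel_true = rel),
    truth = scenario_truth(scenario),
    case_id = scenario$case_id,
    replicate_index = replicate_index,
    seed_used = seed)
}

#' Generate all replicate datasets of a scenario
#'
#' Replicate r is seeded deterministically from
#' `(scenario$base_seed, r)`; calling `make_replicates()` twice with the
#' same scenario yields element-wise identical datasets, and each element
#' equals `simulate_dataset(scenario, r)` called on its own.
#'
#' @param scenario a [sim_scenario()].
#' @return list of `brain_dataset`, length `scenario$n_replicates`.
#' @export
make_replicates <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  lapply(seq_len(scenario$n_replicates),
         function(r) simulate_dataset(scenario, r))
}

#' @export
print.brain_dataset <- function(x, ...) {
  cat("<brain_dataset> case ", x$case_id,
      ", replicate ", x$replicate_index,
      ", n = ", nrow(x$data), "\n", sep = "")
  if (length(x$truth))
    cat("  truth: ",
        paste(names(x$truth), signif(x$truth, 4), sep = " = ", collapse = ", "),
        "\n", sep = "")
  print(utils::head(x$data, 4))
  if (nrow(x$data) > 4) cat("  ... ", nrow(x$data) - 4, " more rows\n", sep = "")
  invisible(x)
}

#' Write / read a dataset as delimited text plus JSON metadata
#'
#' The species table is written as `<stem>.csv` (columns
#' `species_index, body, brain, z[, rel_true]`) and the provenance
#' (truth, case, replicate index, seed) as a `<stem>.json` sidecar, so a
#' simulated dataset round-trips losslessly and user-supplied species
#' tables (a plain CSV with `body`, `brain`, `z` columns, no sidecar)
#' can be read the same way.
#'
#' @param dataset a `brain_dataset`.
#' @param stem file path without extension.
#' @return `write_dataset()` returns `stem` invisibly; `read_dataset()`
#'   returns a `brain_dataset` (with empty truth if no sidecar exists).
#' @export
write_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "brain_dataset"))
  utils::write.csv(dataset$data, paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(case_id = dataset$case_id,
               replicate_index = dataset$replicate_index,
               seed_used = dataset$seed_used,
               truth = as.list(dataset$truth))
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(stem) {
  csv <- if (file.exists(stem)) stem else paste0(stem, ".csv")
  if (!file.exists(csv)) stop("no such file: ", csv, call. = FALSE)
  df <- utils::read.csv(csv)
  need <- c("body", "brain", "z")
  if (!all(need %in% names(df)))
    stop("dataset file must have columns body, brain, z", call. = FALSE)
  side <- paste0(sub("\\.csv$", "", csv), ".json")
  truth <- numeric(0); case_id <- "user"; rep_idx <- NA_integer_; seed <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    truth <- unlist(meta$truth)
    case_id <- meta$case_id %||% "user"
    rep_idx <- meta$replicate_index %||% NA_integer_
    seed <- meta$seed_used %||% NA_integer_
  }
  new_brain_dataset(df, truth = truth, case_id = case_id,
                    replicate_index = rep_idx, seed_used = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
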