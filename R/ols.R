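#' Frequentist multiple regression with classical standard errors
#'
#' Fits the ordinary least-squares regression of `response` on the named
#' `predictors` via [stats::lm()] and returns the point estimates and
#' classical standard errors (residual variance with n - p denominator
#' times the diagonal of the inverse Gram matrix). These are the point
#' estimates and the +/- 2 SE intervals the coverage evaluation uses.
#'
#' A rank-deficient design is an error, never a silent column drop:
#' collinear predictors would mask exactly the collider structure this
#' package studies, so the offending columns are named instead.
#'
#' @param response numeric response vector.
#' @param predictors named list or data.frame of numeric predictor
#'   vectors, each the same length as `response`.
#' @param include_intercept include an intercept column (default TRUE).
#' @param design_label free-text label recording which regression this
#'   fit encodes.
#'
#' @return object of class `linear_fit` with fields
#'   `coefficient_names`, `estimates`, `standard_errors`, `residual_sd`,
#'   `n_obs`, `design_label`.
#' @examples
#' sc <- sim_scenario("case1", n_species = 100, base_seed = 7)
#' d <- simulate_case1(sc, 1)
#' fit_linear(d$data$brain, d$data[c("body", "z")])
#' @export
fit_linear <- function(response, predictors, include_intercept = TRUE,
                       design_label = NULL) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    stop("all predictors must be named", call. = FALSE)
  n <- length(response)
  if (any(vapply(predictors, length, 1L) != n))
    stop("response and predictors must have equal length", call. = FALSE)
  if (anyNA(response) || anyNA(predictors))
    stop("missing values are not supported", call. = FALSE)
  p <- ncol(predictors) + as.integer(include_intercept)
  if (n <= p)
    stop("need more observations than coefficients (n = ", n,
         ", coefficients = ", p, ")", call. = FALSE)

  X <- as.matrix(predictors)
  if (include_intercept) X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  df <- data.frame(.response = response, predictors, check.names = FALSE)
  fml <- if (include_intercept) .response ~ . else .response ~ . - 1
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)

  structure(
    list(coefficient_names = rownames(sm$coefficients),
         estimates = unname(sm$coefficients[, "Estimate"]),
         standard_errors = unname(sm$coefficients[, "Std. Error"]),
         residual_sd = sm$sigma,
         n_obs = n,
         design_label = design_label %||%
           paste("response ~", paste(names(predictors), collapse = " + "))),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit> ", x$design_label, "  (n = ", x$n_obs, ")\n", sep = "")
  tab <- data.frame(estimate = x$estimates, se = x$standard_errors,
                    row.names = x$coefficient_names)
  print(signif(tab, 4))
  cat("residual SD:", signif(x$residual_sd, 4), "\n")
  invisible(x)
}

#' Extract a named coefficient (and its SE) from a linear_fit
#' @param fit a `linear_fit`.
#' @param name coefficient name.
#' @return named list with `estimate` and `se`.
#' @export
coef_linear <- function(fit, name) {
  stopifnot(inherits(fit, "linear_fit"))
  i <- match(name, fit$coefficient_names)
  if (is.na(i)) stop("no coefficient named '", name, "'", call. = FALSE)
  list(estimate = fit$estimates[i], se = fit$standard_errors[i])
}

#' OLS fit of the case-relevant regression for a dataset
#'
#' Case 1 (and its confounded variant): brain regressed on body and z.
#' Case 2: z regressed on body and absolute brain size — the regression
#' whose body coefficient is collider-biased.
#'
#' @param dataset a `brain_dataset`.
#' @return a `linear_fit`.
#' @export
fit_dataset_ols <- function(dataset) {
  stopifnot(inherits(dataset, "brain_dataset"))
  d <- dataset$data
  if (dataset$case_id %in% c("case1", "case1_confounded"))
    fit_linear(d$brain, d[c("body", "z")],
               design_label = "brain ~ body + z")
  else
    fit_linear(d$z, d[c("body", "brain")],
               design_label = "z ~ body + brain")
}

#' Probability limits of the collider-biased OLS coefficients
#'
#' Under the case-2 generative structure `brain = beta_body * body + rel`
#' with body and rel independent standard normals and
#' `E[z] = gamma_body * body + gamma_brain * rel`, substituting
#' `rel = brain - beta_body * body` gives
#' `E[z] = (gamma_body - beta_body * gamma_brain) * body + gamma_brain * brain`.
#' The OLS regression of z on `{body, brain}` therefore converges to a
#' body coefficient of `gamma_body - beta_body * gamma_brain` — not
#' `gamma_body` — while the brain coefficient converges to `gamma_brain`.
#' With all unit effects the body coefficient limit is 0; with a strong
#' brain effect it is negative.
#'
#' @param gamma_body true direct effect of body on z.
#' @param gamma_brain true effect of relative brain size on z.
#' @param beta_body allometric slope used in the brain construction
#'   (default 1).
#' @return named numeric vector `c(body = ..., brain = ...)`: the large-n
#'   limits of the two OLS coefficients.
#' @examples
#' case2_collider_expectation(1, 1)      # body -> 0: effect vanishes
#' case2_collider_expectation(0.5, 2)    # body -> -1.5: sign flips
#' @export
case2_collider_expectation <- function(gamma_body, gamma_brain, beta_body = 1) {
  c(body = gamma_body - beta_body * gamma_brain, brain = gamma_brain)
}
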