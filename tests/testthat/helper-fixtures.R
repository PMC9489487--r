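# small shared fixtures: fast sampler settings for unit tests (the
# acceptance checks use the full 4 x 1000+1000 protocol)
fast_sampler <- function(base_seed = 1L, n_chains = 2L) {
  sampler_config(n_chains = n_chains, n_warmup = 400L, n_sampling = 500L,
                 base_seed = base_seed)
}

# independent closed-form OLS: solve the normal equations directly and
# form classical SEs from the inverse Gram matrix
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  list(estimates = drop(beta),
       se = sqrt(s2 * diag(solve(XtX))),
       residual_sd = sqrt(s2))
}
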