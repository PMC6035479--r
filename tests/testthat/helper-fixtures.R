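# Shared fixtures, built once per test run.

# small two-level logistic dataset with known parameters
small_sim <- make_dataset(simulation_design(
  n_clusters = 20, cluster_size = 25,
  beta = c("(Intercept)" = -1, x = 0.5),
  covariates = list(x = cov_normal()),
  sigma_u = 0.6, seed = 5))

small_fit <- fit_random_intercept(small_sim$dataset, n_quad = 15)

# brute-force marginal log-likelihood by dense trapezoid integration of each
# cluster's likelihood integral over +/- 8 sigma; independent of the
# quadrature path (dbinom/dpois + dnorm only)
brute_force_loglik <- function(data, beta, sigma_u, n_grid = 10000,
                               half_width = 8) {
  d <- data$data
  covs <- c(data$subject_covs, data$cluster_covs)
  X <- if (length(covs)) {
    stats::model.matrix(stats::reformulate(covs), data = d)
  } else matrix(1, nrow(d), 1)
  eta0 <- drop(X %*% beta)
  y <- d[[data$outcome]]
  u <- seq(-half_width * sigma_u, half_width * sigma_u,
           length.out = n_grid + 1)
  du <- u[2] - u[1]
  ll <- 0
  for (cl in unique(d[[data$cluster]])) {
    i <- d[[data$cluster]] == cl
    lg <- vapply(u, function(uu) {
      eta <- eta0[i] + uu
      cond <- switch(data$family,
        binomial = sum(stats::dbinom(y[i], 1, stats::plogis(eta),
                                     log = TRUE)),
        poisson = sum(stats::dpois(y[i], exp(eta), log = TRUE)))
      cond + stats::dnorm(uu, 0, sigma_u, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    w <- rep(1, length(u)); w[c(1, length(u))] <- 0.5   # trapezoid
    ll <- ll + m + log(sum(w * exp(lg - m)) * du)
  }
  ll
}
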