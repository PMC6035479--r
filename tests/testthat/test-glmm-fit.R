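test_that("marginal log-likelihood agrees with dense brute-force integration", {
  ll_brute <- brute_force_loglik(small_sim$dataset, small_fit$beta,
                                 small_fit$sigma_u)
  expect_lt(abs(small_fit$loglik - ll_brute) / abs(ll_brute), 1e-4)

  # and away from the optimum too
  beta_off <- small_fit$beta + c(0.2, -0.1)
  ll_agq <- marginal_loglik(small_sim$dataset, beta_off, 0.4, n_quad = 15)
  ll_bf <- brute_force_loglik(small_sim$dataset, beta_off, 0.4)
  expect_lt(abs(ll_agq - ll_bf) / abs(ll_bf), 1e-4)
})

test_that("quadrature order converges: 15 and 25 nodes agree to 5 sig digits", {
  ll <- vapply(c(7, 15, 25), function(q) {
    marginal_loglik(small_sim$dataset, small_fit$beta, small_fit$sigma_u,
                    n_quad = q)
  }, numeric(1))
  expect_lt(abs(ll[2] - ll[3]), abs(ll[1] - ll[2]) + 1e-12)
  expect_lt(abs(ll[2] - ll[3]) / abs(ll[3]), 1e-6)
})

test_that("homogeneous data gives a boundary sigma and the pooled glm fit", {
  sim0 <- make_dataset(simulation_design(
    n_clusters = 30, cluster_size = 60,
    beta = c("(Intercept)" = -0.5, x = 0.8),
    covariates = list(x = cov_normal()),
    sigma_u = 0, seed = 17))
  f0 <- fit_random_intercept(sim0$dataset, n_quad = 7)
  expect_lt(f0$sigma_u, 0.08)
  g <- glm(y ~ x, data = sim0$dataset$data, family = binomial)
  expect_lt(max(abs(f0$beta - coef(g))), 0.02)
  # with sigma exactly 0 the marginal likelihood is the pooled one
  expect_equal(marginal_loglik(sim0$dataset, coef(g), 0),
               as.numeric(logLik(g)), tolerance = 1e-10)
})

test_that("permuting cluster membership removes the estimated heterogeneity", {
  d <- small_sim$dataset$data
  set.seed(99)
  d$cluster <- sample(d$cluster)
  mdp <- multilevel_data(d, "y", "cluster", subject_covs = "x")
  fp <- fit_random_intercept(mdp, n_quad = 7)
  expect_lt(fp$sigma_u, 0.15)
})

test_that("estimates match an independent AGQ implementation", {
  skip_if_not_installed("lme4")
  g <- lme4::glmer(y ~ x + (1 | cluster), data = small_sim$dataset$data,
                   family = binomial, nAGQ = 15)
  expect_equal(unname(small_fit$beta), unname(lme4::fixef(g)),
               tolerance = 1e-4)
  expect_equal(small_fit$sigma_u,
               sqrt(unname(unlist(lme4::VarCorr(g)))), tolerance = 1e-4)
  expect_equal(small_fit$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(unname(small_fit$se_beta),
               unname(coef(summary(g))[, "Std. Error"]), tolerance = 0.02)
})

test_that("poisson family fits and matches the reference implementation", {
  simp <- make_dataset(simulation_design(
    n_clusters = 25, cluster_size = 30,
    beta = c("(Intercept)" = 0.5, x = 0.3),
    covariates = list(x = cov_normal()),
    sigma_u = 0.4, family = "poisson", seed = 8))
  fp <- fit_random_intercept(simp$dataset, n_quad = 11)
  expect_true(fp$converged)
  ll_bf <- brute_force_loglik(simp$dataset, fp$beta, fp$sigma_u)
  expect_lt(abs(fp$loglik - ll_bf) / abs(ll_bf), 1e-4)
  skip_if_not_installed("lme4")
  g <- lme4::glmer(y ~ x + (1 | cluster), data = simp$dataset$data,
                   family = poisson, nAGQ = 11)
  expect_equal(unname(fp$beta), unname(lme4::fixef(g)), tolerance = 1e-4)
  expect_equal(fp$sigma_u, sqrt(unname(unlist(lme4::VarCorr(g)))),
               tolerance = 1e-3)
})

test_that("gaussian family matches the closed-form marginal likelihood", {
  simg <- make_dataset(simulation_design(
    n_clusters = 20, cluster_size = 15,
    beta = c("(Intercept)" = 1, x = 0.5),
    covariates = list(x = cov_normal()),
    sigma_u = 0.7, family = "gaussian", sigma_e = 1.2, seed = 3))
  fg <- fit_random_intercept(simg$dataset, n_quad = 11)
  # analytic marginal: y_i ~ N(X_i beta, sigma_e^2 I + sigma_u^2 J)
  d <- simg$dataset$data
  ll <- 0
  for (cl in unique(d$cluster)) {
    i <- d$cluster == cl
    mu <- fg$beta[1] + fg$beta[2] * d$x[i]
    V <- diag(fg$sigma_e^2, sum(i)) + fg$sigma_u^2
    r <- d$y[i] - mu
    ll <- ll - 0.5 * (sum(i) * log(2 * pi) + determinant(V)$modulus[1] +
                        drop(r %*% solve(V, r)))
  }
  expect_equal(fg$loglik, ll, tolerance = 1e-6)
  skip_if_not_installed("lme4")
  m <- lme4::lmer(y ~ x + (1 | cluster), data = d, REML = FALSE)
  expect_equal(unname(fg$beta), unname(lme4::fixef(m)), tolerance = 1e-3)
})

test_that("degenerate designs are rejected informatively", {
  d <- small_sim$dataset$data
  d$x2 <- 2 * d$x
  md <- multilevel_data(d, "y", "cluster", subject_covs = c("x", "x2"))
  expect_error(fit_random_intercept(md), "collinear.*x2|x2")
})

test_that("the coefficient table exponentiates to odds ratios", {
  tab <- model_table(small_fit)
  i <- match("x", tab$term)
  expect_equal(tab$effect[i], exp(small_fit$beta[["x"]]))
  expect_equal(tab$estimate[nrow(tab)], small_fit$sigma_u)
  expect_true(all(tab$conf_low[i] < tab$effect[i],
                  tab$effect[i] < tab$conf_high[i]))
})
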