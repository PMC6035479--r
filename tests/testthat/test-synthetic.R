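test_that("generation is reproducible and honest about the truth", {
  s1 <- make_dataset(simulation_design(n_clusters = 10, cluster_size = 20,
                                       seed = 4))
  s2 <- make_dataset(simulation_design(n_clusters = 10, cluster_size = 20,
                                       seed = 4))
  expect_identical(s1$dataset$data, s2$dataset$data)
  expect_identical(s1$u, s2$u)
  # true random effects never enter the analysis table
  expect_false("u" %in% names(s1$dataset$data))

  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(make_af_like_fixture(123), f1)
  write_dataset(make_af_like_fixture(123), f2)
  expect_identical(readLines(paste0(f1, ".csv")),
                   readLines(paste0(f2, ".csv")))
  unlink(c(paste0(f1, c(".csv", "_truth.json")),
           paste0(f2, c(".csv", "_truth.json"))))
})

test_that("the generator honors its design parameters", {
  # empirical SD of u converges to sigma_u
  big <- make_dataset(simulation_design(n_clusters = 4000, cluster_size = 2,
                                        sigma_u = 0.5, seed = 9))
  expect_equal(sd(big$u), 0.5, tolerance = 0.03)

  # prevalence is monotone in the intercept
  rates <- vapply(c(-2, -1, 0), function(b0) {
    s <- make_dataset(simulation_design(
      n_clusters = 50, cluster_size = 40,
      beta = c("(Intercept)" = b0), sigma_u = 0.3, seed = 31))
    mean(s$dataset$data$y)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))

  # cluster-level covariates are constant within cluster
  sim <- make_dataset(simulation_design(
    n_clusters = 15, cluster_size = 12,
    beta = c("(Intercept)" = -1, w = 0.2),
    covariates = list(w = cov_normal(level = "cluster")),
    sigma_u = 0.4, seed = 2))
  per_cl <- tapply(sim$dataset$data$w, sim$dataset$data$cluster,
                   function(v) length(unique(v)))
  expect_true(all(per_cl == 1))

  # heavily skewed log-Gamma intercepts still have median near zero
  lg <- make_dataset(simulation_design(
    n_clusters = 3000, cluster_size = 2,
    random_effect = ranef_loggamma(0.8), seed = 12))
  expect_equal(median(lg$u), 0, tolerance = 0.05)
  expect_gt(abs(mean(lg$u)), 0.01)   # skew: mean well away from median

  expect_error(simulation_design(n_clusters = 10, cluster_size = 5),
               "seed")
  expect_error(simulation_design(n_clusters = 10, cluster_size = 5,
                                 beta = c("(Intercept)" = 0, q = 1),
                                 seed = 1),
               "q")
})

test_that("homogeneous clusters show only binomial noise between clusters", {
  s0 <- make_dataset(simulation_design(
    n_clusters = 40, cluster_size = 200,
    beta = c("(Intercept)" = -1), sigma_u = 0, seed = 6))
  p_cl <- tapply(s0$dataset$data$y, s0$dataset$data$cluster, mean)
  p <- mean(s0$dataset$data$y)
  # observed between-cluster variance of proportions vs binomial expectation
  expect_lt(var(p_cl), 3 * p * (1 - p) / 200)
})

test_that("the built-in fixture has the designed variation structure", {
  sim <- make_af_like_fixture(20180706)
  md <- sim$dataset
  expect_equal(md$n_clusters, 60L)
  expect_lt(abs(mean(md$data$y) - 0.146), 0.02)
  expect_true(sd(md$n_i) > 0)   # unbalanced sizes
  fit <- fit_random_intercept(md, n_quad = 7)
  pat <- rem_empirical_range(model_risk_dist(fit, "subject"))
  sit <- rem_empirical_range(model_risk_dist(fit, "cluster"))
  expect_gt(pat[["high"]] - pat[["low"]], sit[["high"]] - sit[["low"]])
  # known-truth recovery within Monte-Carlo tolerance
  expect_equal(fit$sigma_u, 0.5, tolerance = 0.35)
  expect_true(abs(fit$sigma_u - 0.5) < 3 * fit$se_sigma_u + 0.1)
})
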