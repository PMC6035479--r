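test_that("delta-method CI evaluates the transformed Wald interval", {
  # hospital SD 0.511 (SE 0.040): direct evaluation of the formula
  ci <- delta_ci_rem(0.511, 0.040, 0.975)
  z <- qnorm(0.975)
  expect_equal(ci$low, exp((0.511 - z * 0.040) * z))
  expect_equal(ci$high, exp((0.511 + z * 0.040) * z))
  expect_equal(ci$point, exp(0.511 * z))
  expect_lte(ci$low, ci$point); expect_lte(ci$point, ci$high)

  # SE = 0 degenerates to the point estimate
  ci0 <- delta_ci_rem(0.5, 0, 0.8)
  expect_equal(c(ci0$low, ci0$high), rep(ci0$point, 2))

  # a and 1-a intervals are reciprocal pairs; endpoints swap below the median
  up <- delta_ci_rem(0.511, 0.040, 0.975)
  dn <- delta_ci_rem(0.511, 0.040, 0.025)
  expect_equal(dn$low, 1 / up$high)
  expect_equal(dn$high, 1 / up$low)
  expect_lte(dn$low, dn$high)

  # lower sigma bound truncates at zero before transforming
  tr <- delta_ci_rem(0.05, 0.1, 0.975)
  expect_equal(tr$low, exp(0))

  # widening the level widens the interval
  w90 <- delta_ci_rem(0.5, 0.05, 0.975, level = 0.90)
  w99 <- delta_ci_rem(0.5, 0.05, 0.975, level = 0.99)
  expect_lt(w99$low, w90$low); expect_gt(w99$high, w90$high)
})

test_that("cluster bootstrap is deterministic given a seed and handles edge cases", {
  md <- small_sim$dataset
  stat <- function(f) rem_random(f$sigma_u, 0.75)
  b1 <- suppressWarnings(cluster_bootstrap(md, stat, n_boot = 30, seed = 7,
                                           n_quad = 5, fit = small_fit))
  b2 <- suppressWarnings(cluster_bootstrap(md, stat, n_boot = 30, seed = 7,
                                           n_quad = 5, fit = small_fit))
  expect_identical(b1$low, b2$low)
  expect_identical(b1$high, b2$high)
  expect_equal(b1$point, rem_random(small_fit$sigma_u, 0.75))
  expect_lte(b1$low, b1$high)

  # a constant statistic gives a zero-width interval at that constant
  bc <- suppressWarnings(cluster_bootstrap(md, function(f) 3.5, n_boot = 30,
                                           seed = 1, n_quad = 5,
                                           fit = small_fit))
  expect_equal(c(bc$low, bc$point, bc$high), rep(3.5, 3))

  expect_warning(cluster_bootstrap(md, stat, n_boot = 20, seed = 1,
                                   n_quad = 5, fit = small_fit),
                 "n_boot < 50")
  expect_error(cluster_bootstrap(md, stat, n_boot = 100, n_quad = 5,
                                 fit = small_fit),
               "seed")
})

test_that("percentile bootstrap intervals are transformation-equivariant", {
  md <- small_sim$dataset
  log_stat <- function(f) 0.75 * f$sigma_u   # arbitrary smooth statistic
  exp_stat <- function(f) exp(0.75 * f$sigma_u)
  b_log <- suppressWarnings(cluster_bootstrap(md, log_stat, n_boot = 40,
                                              seed = 3, n_quad = 5,
                                              fit = small_fit))
  b_exp <- suppressWarnings(cluster_bootstrap(md, exp_stat, n_boot = 40,
                                              seed = 3, n_quad = 5,
                                              fit = small_fit))
  expect_equal(b_exp$low, exp(b_log$low), tolerance = 1e-12)
  expect_equal(b_exp$high, exp(b_log$high), tolerance = 1e-12)
})

test_that("percentile-equivalent intervals bracket the truth on a known fixture", {
  # design with beta_x = sigma_u so the true percentile is Phi(1)
  sim <- make_dataset(simulation_design(
    n_clusters = 40, cluster_size = 40,
    beta = c("(Intercept)" = -1, x = 0.5),
    covariates = list(x = cov_normal()),
    sigma_u = 0.5, seed = 21))
  f <- fit_random_intercept(sim$dataset, n_quad = 7)
  del <- percentile_equivalent_ci(f, "x", method = "delta")
  expect_lt(del$low, pnorm(1)); expect_gt(del$high, pnorm(1))
  boot <- percentile_equivalent_ci(f, "x", method = "bootstrap",
                                   n_boot = 60, seed = 11, n_quad = 5)
  expect_lt(boot$low, pnorm(1)); expect_gt(boot$high, pnorm(1))
  # the two methods agree to within a few percentiles on this fixture
  expect_lt(abs(boot$low - del$low), 0.06)
  expect_lt(abs(boot$high - del$high), 0.06)
})
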