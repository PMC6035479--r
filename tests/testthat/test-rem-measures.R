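test_that("random-effect REM reproduces the published worked example", {
  # sigma_u = 0.511 from the rhythm-control model
  expect_equal(round(rem_random(0.511, 0.025), 3), 0.367)
  expect_equal(round(rem_random(0.511, 0.75), 2), 1.41)
  expect_equal(round(rem_range(0.511, 0.95), 2),
               c(low = 0.37, high = 2.72))
  expect_equal(rem_random(0.7, 0.5), 1)   # median vs median, any sigma
  expect_equal(rem_range(0, 0.95), c(low = 1, high = 1))
  # closed form at another level
  expect_equal(rem_range(0.3, 0.80),
               c(low = exp(-0.3 * qnorm(0.90)), high = exp(0.3 * qnorm(0.90))))
  expect_error(rem_random(0.5, 1.2), "0, 1")
})

test_that("normal REM is symmetric and monotone in the percentile", {
  for (s in c(0.05, 0.3, 1.2)) {
    a <- seq(0.05, 0.95, by = 0.05)
    v <- rem_random(s, a)
    expect_true(all(diff(v) > 0))
    expect_equal(rem_random(s, a) * rem_random(s, 1 - a), rep(1, length(a)))
  }
})

test_that("percentile equivalence maps covariate effects onto the random scale", {
  expect_equal(round(100 * percentile_equivalent(0.409, 0.511)), 79)
  expect_equal(percentile_equivalent(0, 0.511), 0.5)
  expect_equal(percentile_equivalent(0.3, 0.3), pnorm(1))
  expect_lt(percentile_equivalent(-0.2, 0.5), 0.5)
  fl <- percentile_equivalent(0.409, 0.511, flip = TRUE)
  expect_equal(unname(sum(fl)), 1)
  expect_error(percentile_equivalent(0.4, 0), "undefined")
  # numeric inversion for non-normal families round-trips
  d <- ranef_loggamma(2)
  a0 <- 0.8
  expect_equal(percentile_equivalent(d$quantile(a0), d), a0,
               tolerance = 1e-8)
  expect_error(percentile_equivalent(1e6, d), "outside")
})

test_that("empirical REM centers at the median under the type-7 estimator", {
  toy <- risk_dist(c(0, 0, log(2), log(2)))
  # independent hand computation: type-7 q(.975) = log 2, q(.5) = log(2)/2
  expect_equal(rem_empirical(toy, 0.975), exp(log(2) - log(2) / 2))
  expect_equal(rem_empirical(toy, 0.5), 1)
  expect_equal(rem_empirical(risk_dist(rep(1.7, 10)), c(0.1, 0.5, 0.9)),
               rep(1, 3))
  v5 <- risk_dist(c(-1, -0.5, 0, 0.5, 1))
  # order statistics interpolation computed by hand: q(.025)=-0.95, q(.975)=0.95
  expect_equal(rem_empirical_range(v5, 0.95),
               c(low = exp(-0.95), high = exp(0.95)))
  expect_error(risk_dist(numeric(0)), "non-empty")
  expect_error(risk_dist(c(1, Inf)), "finite")
})

test_that("empirical REM of a large normal sample matches the closed form", {
  set.seed(42)
  s <- 0.7
  v <- risk_dist(rnorm(1e5, sd = s))
  for (a in c(0.1, 0.75, 0.975)) {
    expect_equal(rem_empirical(v, a), exp(s * qnorm(a)), tolerance = 0.03)
  }
})

test_that("IOM gives outcome probabilities across the cluster distribution", {
  # median-age CHF patient, all else zero: intercept + CHF coefficient
  expect_equal(round(100 * iom(-2.292 + 0.409, 0.511, 0.025), 1), 5.3)
  expect_equal(iom(0, 0.5, 0.5), 0.5)
  a <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(iom(-1, 0.5, a)) > 0))
  expect_error(iom(0, 0.5, 0.5, family = "poisson"), "logit")
})

test_that("MOR, PerSD and ICC match their closed forms and identities", {
  expect_equal(round(mor(0.511), 2), 1.63)
  expect_equal(mor(0), 1)
  expect_equal(round(per_sd(0.511), 2), 1.67)
  expect_equal(per_sd(0), 1)
  expect_equal(round(icc_latent(0.511), 3), 0.074)
  expect_equal(icc_latent(0), 0)
  expect_error(mor(-0.1), "non-negative")
  expect_error(per_sd(-1), "non-negative")

  # identities: MOR = REM at Phi(sqrt2 * Phi^-1(.75)); PerSD = REM at Phi(1)
  expect_equal(round(mor_percentile(), 2), 0.83)
  for (s in c(0.01, 0.1, 0.5, 1, 2)) {
    expect_equal(mor(s), rem_random(s, mor_percentile()), tolerance = 1e-12)
    expect_equal(per_sd(s), rem_random(s, pnorm(1)), tolerance = 1e-12)
  }
  # icc strictly increasing, bounded
  ss <- seq(0, 3, by = 0.1)
  expect_true(all(diff(icc_latent(ss)) > 0))
  expect_true(all(icc_latent(ss) >= 0 & icc_latent(ss) < 1))
})

test_that("sigma recovery from a reported REM round-trips", {
  expect_equal(sigma_from_rem(1.29, 0.975), log(1.29) / qnorm(0.975))
  expect_equal(sigma_from_rem(1, 0.8), 0)
  # round-trips (REM > 1 above the median, REM < 1 below it)
  for (v in c(1.2, 3)) {
    for (a in c(0.75, 0.975)) {
      expect_equal(rem_random(sigma_from_rem(v, a), a), v,
                   tolerance = 1e-12)
      expect_equal(rem_random(sigma_from_rem(1 / v, 1 - a), 1 - a), 1 / v,
                   tolerance = 1e-12)
    }
  }
  expect_error(sigma_from_rem(1.3, 0.5), "0.5")
  # the implied mortality-model sigma reproduces its reported MOR and ICC
  s2 <- sigma_from_rem(1.29, 0.975)
  expect_equal(round(mor(s2), 2), 1.13)
  expect_equal(round(icc_latent(s2), 3), 0.005)
})

test_that("non-normal random-effect families are median-centered", {
  d <- ranef_loggamma(1.5)
  expect_equal(d$quantile(0.5), 0)
  a <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(d$quantile(a)) > 0))
  # user-supplied quantile functions are centered automatically
  dq <- ranef_quantile(function(a) qexp(a, rate = 2))
  expect_equal(dq$quantile(0.5), 0)
  expect_equal(rem_random(dq, 0.5), 1)
})

test_that("difference scale returns identity-scale contrasts", {
  expect_equal(rem_random(ranef_normal(0.5), 0.975, scale = "difference"),
               0.5 * qnorm(0.975))
  expect_equal(rem_empirical(risk_dist(c(-1, 0, 1)), 0.5,
                             scale = "difference"), 0)
})

test_that("a boundary sigma collapses the measures to their null values", {
  expect_warning(v <- rem_random(ranef_normal(1e-9), 0.975), "boundary")
  expect_equal(v, 1)
  expect_equal(rem_random(ranef_normal(0), 0.975), 1)
})
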