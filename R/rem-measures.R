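# Reference effect measures: effect-scale summaries of cluster random-effect
# variation (general contextual effects) and of empirical covariate-set
# risk distributions, plus the comparison measures MOR, PerSD, IOM and the
# latent-scale ICC.

#' Random-effect distributions for reference effect measures
#'
#' A random-effect distribution is represented by its (median-centered)
#' quantile function, so that reference effect measures generalize beyond the
#' normal case by replacing \eqn{\sigma_u \Phi^{-1}(a)} with the percentile
#' of whichever distribution is specified. Every family is centered so that
#' `quantile(0.5) == 0`: a median cluster is the reference.
#'
#' `ranef_normal(sigma_u)` is the standard normal random intercept
#' \eqn{u \sim N(0, \sigma_u^2)}. `ranef_loggamma(shape)` is
#' \eqn{u = \log G} with \eqn{G \sim Gamma(k, k)} (mean 1), median-centered;
#' log-Gamma intercepts arise naturally in Poisson models where the marginal
#' is negative binomial. `ranef_quantile(qfun)` wraps an arbitrary
#' non-decreasing quantile function, which is median-centered automatically.
#'
#' @param sigma_u Standard deviation of the normal random intercept (>= 0).
#' @param shape Gamma shape parameter \eqn{k > 0}.
#' @param qfun A function of a single probability returning a quantile.
#' @param label Optional label used in reports.
#' @return An object of class `ranef_dist` with fields `kind`, `params`,
#'   and `quantile` (vectorized, median-centered).
#' @examples
#' d <- ranef_normal(0.5)
#' d$quantile(0.975)   # 0.5 * qnorm(0.975)
#' @name ranef_dist
NULL

new_ranef_dist <- function(kind, params, quantile, label) {
  structure(list(kind = kind, params = params, quantile = quantile,
                 label = label),
            class = "ranef_dist")
}

#' @rdname ranef_dist
#' @export
ranef_normal <- function(sigma_u, label = "normal random intercept") {
  stopifnot(is.numeric(sigma_u), length(sigma_u) == 1L, sigma_u >= 0)
  new_ranef_dist("normal", list(sigma_u = sigma_u),
                 function(a) sigma_u * stats::qnorm(a), label)
}

#' @rdname ranef_dist
#' @export
ranef_loggamma <- function(shape, label = "log-Gamma random intercept") {
  stopifnot(shape > 0)
  med <- log(stats::qgamma(0.5, shape = shape, rate = shape))
  new_ranef_dist("log-gamma", list(shape = shape),
                 function(a) log(stats::qgamma(a, shape = shape,
                                               rate = shape)) - med,
                 label)
}

#' @rdname ranef_dist
#' @export
ranef_quantile <- function(qfun, label = "user-specified random effect") {
  stopifnot(is.function(qfun))
  med <- qfun(0.5)
  new_ranef_dist("user-quantile", list(),
                 function(a) qfun(a) - med, label)
}

#' @export
print.ranef_dist <- function(x, ...) {
  cat("Random-effect distribution:", x$kind)
  if (x$kind == "normal") cat(" (sigma_u =", x$params$sigma_u, ")")
  if (x$kind == "log-gamma") cat(" (shape =", x$params$shape, ")")
  cat("\n")
  invisible(x)
}

# coerce a bare SD or a fitted model to a ranef_dist
as_ranef_dist <- function(dist) {
  if (inherits(dist, "ranef_dist")) return(dist)
  if (inherits(dist, "rem_glmm")) return(ranef_normal(dist$sigma_u))
  if (is.numeric(dist) && length(dist) == 1L) return(ranef_normal(dist))
  stop("expected a ranef_dist, a fitted rem_glmm, or a numeric sigma_u")
}

check_prob <- function(a) {
  if (!is.numeric(a) || any(a <= 0) || any(a >= 1)) {
    stop("percentile 'a' must lie strictly inside (0, 1)")
  }
}

apply_scale <- function(x, scale) {
  switch(match.arg(scale, c("ratio", "difference")),
         ratio = exp(x), difference = x)
}

# near-zero variance component: all measures collapse to their null values
is_null_sigma <- function(sigma_u) sigma_u < 1e-6

#' Reference effect measure for the random-effect distribution
#'
#' Compares a subject in a cluster at the `100 * a` percentile of the
#' random-effect distribution to the same subject in a median ("reference")
#' cluster, all measured covariates held equal. For a normal random intercept
#' on the ratio (odds-ratio) scale this is
#' \deqn{REM_u(a) = \exp(\sigma_u \Phi^{-1}(a)).}
#'
#' @param dist A [ranef_dist], a fitted `rem_glmm`, or a bare numeric
#'   `sigma_u` (interpreted as a normal random intercept).
#' @param a Percentile(s) in (0, 1).
#' @param scale `"ratio"` (exponentiate: odds/rate ratios) or
#'   `"difference"` (identity: mean differences, normal outcome models).
#' @return Effect value(s), same length as `a`.
#' @examples
#' rem_random(0.511, 0.975)   # upper end of a 95% REM range
#' @export
rem_random <- function(dist, a, scale = "ratio") {
  check_prob(a)
  dist <- as_ranef_dist(dist)
  if (dist$kind == "normal" && is_null_sigma(dist$params$sigma_u)) {
    # boundary estimate: no cluster variation, measure is null at every a
    if (dist$params$sigma_u > 0) {
      warning("sigma_u is at the zero boundary; REM collapses to its ",
              "null value")
    }
    return(apply_scale(rep(0, length(a)), scale))
  }
  apply_scale(dist$quantile(a), scale)
}

#' Central range of reference effect measures
#'
#' The `level` (default 95%) REM range
#' \eqn{[REM_u((1-level)/2),\ REM_u(1-(1-level)/2)]} describes unexplained
#' cluster variation as a range of effect values relative to a median
#' cluster — it encloses the middle `level` of the distribution of effects
#' and is not a confidence interval.
#'
#' @inheritParams rem_random
#' @param level Coverage of the range, in (0, 1).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' rem_range(0.511, 0.95)   # approximately c(0.37, 2.72)
#' @export
rem_range <- function(dist, level = 0.95, scale = "ratio") {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  lo <- rem_random(dist, (1 - level) / 2, scale)
  hi <- rem_random(dist, 1 - (1 - level) / 2, scale)
  c(low = min(lo, hi), high = max(lo, hi))
}

#' Percentile of the random-effect distribution equivalent to a covariate
#' effect
#'
#' Expresses a fixed-effect coefficient \eqn{\beta_k} as the percentile of
#' the random-effect distribution at which the reference effect measure
#' equals the covariate's effect: \eqn{\Phi(\beta_k / \sigma_u)} for normal
#' random intercepts, or a numerical inversion of the quantile function for
#' other families.
#'
#' @param beta_k Coefficient (log effect) for a one-unit covariate change.
#' @inheritParams rem_random
#' @param flip Also return the complementary presentation
#'   `1 - percentile` used when quoting "the X% highest-risk clusters".
#' @return The percentile (in (0,1)); with `flip = TRUE`, a named vector
#'   with both presentations.
#' @examples
#' percentile_equivalent(0.409, 0.511)   # about 0.79
#' @export
percentile_equivalent <- function(beta_k, dist, flip = FALSE) {
  dist <- as_ranef_dist(dist)
  if (dist$kind == "normal") {
    sigma_u <- dist$params$sigma_u
    if (is_null_sigma(sigma_u)) {
      stop("percentile equivalence is undefined when sigma_u is 0")
    }
    p <- stats::pnorm(beta_k / sigma_u)
  } else {
    p <- vapply(beta_k, function(b) {
      lo <- dist$quantile(1e-12); hi <- dist$quantile(1 - 1e-12)
      if (b < lo || b > hi) {
        stop("effect ", format(b), " lies outside the range of the ",
             "random-effect distribution; no equivalent percentile exists")
      }
      stats::uniroot(function(a) dist$quantile(a) - b,
                     lower = 1e-12, upper = 1 - 1e-12,
                     tol = 1e-12)$root
    }, numeric(1))
  }
  if (flip) c(percentile = p, flipped = 1 - p) else p
}

#' Empirical risk distribution of a covariate subset
#'
#' Represents the observed multiset of linear-predictor contributions
#' \eqn{\{x_{sij}'\hat\beta_s\}} (or any declared covariate subset) across
#' all subjects, with its empirical quantile function. Reference effect
#' measures of this distribution quantify how much outcome variation a set
#' of measured factors carries, on the same effect scale as the
#' random-effect measures.
#'
#' @param values Numeric vector of per-subject linear-predictor
#'   contributions.
#' @param label Name of the subset (used in reports and plots).
#' @param type Quantile estimator type passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics).
#' @return An object of class `risk_dist` with fields `values`, `label`,
#'   and `quantile` (vectorized empirical quantile function).
#' @examples
#' rd <- risk_dist(c(0, 0, log(2), log(2)), label = "toy")
#' rd$quantile(0.975)
#' @export
risk_dist <- function(values, label = "covariate set", type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("risk distribution values must be non-empty and finite")
  }
  structure(
    list(values = values, label = label, type = type,
         quantile = function(a) unname(stats::quantile(values, probs = a,
                                                       type = type))),
    class = "risk_dist")
}

#' Extract a covariate subset's risk distribution from a fitted model
#'
#' Builds the [risk_dist] of \eqn{\{x'\hat\beta\}} contributions for the
#' declared subject-level columns, cluster-level columns, their union, or an
#' arbitrary set of covariate names.
#'
#' @param fit A fitted `rem_glmm`.
#' @param which `"subject"`, `"cluster"`, `"all"`, or a character vector of
#'   covariate names (intercept never included).
#' @param label Optional label; defaults to a description of `which`.
#' @inheritParams risk_dist
#' @return A [risk_dist] object.
#' @export
model_risk_dist <- function(fit, which = "subject", label = NULL, type = 7) {
  stopifnot(inherits(fit, "rem_glmm"))
  if (length(which) == 1L && which %in% c("subject", "cluster", "all")) {
    vals <- switch(which,
      subject = fit$linpred_parts$subject_part,
      cluster = fit$linpred_parts$cluster_part,
      all = fit$linpred_parts$subject_part + fit$linpred_parts$cluster_part)
    if (is.null(label)) {
      label <- switch(which, subject = "all subject factors",
                      cluster = "all cluster factors",
                      all = "all measured factors")
    }
  } else {
    md <- glmm_prepare(fit$data)
    cols <- unlist(lapply(which, function(v) {
      hit <- grep(paste0("^", v), colnames(md$X), value = TRUE)
      if (length(hit) == 0L) stop("covariate '", v, "' not in the model")
      hit
    }))
    cols <- setdiff(cols, "(Intercept)")
    vals <- drop(md$X[, cols, drop = FALSE] %*% fit$beta[cols])
    if (is.null(label)) label <- paste(which, collapse = " + ")
  }
  risk_dist(vals, label = label, type = type)
}

#' Reference effect measure of an empirical risk distribution
#'
#' Centers the empirical distribution at its median (comparison with a
#' median-risk subject) and returns the effect value at percentile `a`:
#' \deqn{REM_{\{x'\beta\}}(a) =
#'   \exp(F^{-1}(a) - F^{-1}(0.5))}
#' on the ratio scale, where \eqn{F^{-1}} is the empirical quantile
#' function.
#'
#' @param riskdist A [risk_dist] object (or numeric vector of values).
#' @inheritParams rem_random
#' @return Effect value(s).
#' @examples
#' rem_empirical(risk_dist(c(0, 0, log(2), log(2))), 0.975)   # 2
#' @export
rem_empirical <- function(riskdist, a, scale = "ratio") {
  check_prob(a)
  if (!inherits(riskdist, "risk_dist")) riskdist <- risk_dist(riskdist)
  apply_scale(riskdist$quantile(a) - riskdist$quantile(0.5), scale)
}

#' Central REM range of an empirical risk distribution
#'
#' @inheritParams rem_empirical
#' @inheritParams rem_range
#' @return Named numeric vector `c(low, high)`.
#' @export
rem_empirical_range <- function(riskdist, level = 0.95, scale = "ratio") {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  lo <- rem_empirical(riskdist, (1 - level) / 2, scale)
  hi <- rem_empirical(riskdist, 1 - (1 - level) / 2, scale)
  c(low = min(lo, hi), high = max(lo, hi))
}

#' Individual outcome measure (IOM)
#'
#' Predicted outcome probability for a fixed covariate pattern as the
#' cluster random effect ranges over its distribution:
#' \deqn{IOM_u(x, a) = logit^{-1}(x'\beta + \sigma_u \Phi^{-1}(a)).}
#' Defined here on the probability scale for the logit link only; the width
#' of an IOM range depends on the covariate pattern, which is why the
#' covariate-pattern-free REM is usually preferred for comparisons.
#'
#' @param linpred Linear predictor value \eqn{x'\beta} of the covariate
#'   pattern.
#' @inheritParams rem_random
#' @param family Outcome family; only `"binomial"` (logit) is supported.
#' @return Probability in (0, 1).
#' @examples
#' iom(-2.292 + 0.409, 0.511, 0.025)   # about 0.053
#' @export
iom <- function(linpred, dist, a, family = "binomial") {
  if (family != "binomial") {
    stop("IOM is defined here on the probability scale of the logit link ",
         "only")
  }
  check_prob(a)
  dist <- as_ranef_dist(dist)
  stats::plogis(linpred + dist$quantile(a))
}

#' Median odds ratio (MOR)
#'
#' The median of the distribution of odds ratios comparing the higher- to
#' the lower-risk subject across two randomly sampled clusters with the same
#' covariates: \eqn{MOR = \exp(\sqrt{2}\,\sigma_u\,\Phi^{-1}(0.75))} for a
#' normal random intercept. MOR coincides with the reference effect measure
#' at the \eqn{\Phi(\sqrt{2}\,\Phi^{-1}(0.75)) \approx 0.83} percentile.
#'
#' @param sigma_u Random-intercept SD (>= 0).
#' @return Odds ratio >= 1.
#' @examples
#' mor(0.511)   # 1.63
#' @export
mor <- function(sigma_u) {
  if (any(sigma_u < 0)) stop("sigma_u must be non-negative")
  exp(sqrt(2) * sigma_u * stats::qnorm(0.75))
}

#' Percentile at which MOR equals the reference effect measure
#'
#' @return \eqn{\Phi(\sqrt{2}\,\Phi^{-1}(0.75))}, about 0.83.
#' @export
mor_percentile <- function() {
  stats::pnorm(sqrt(2) * stats::qnorm(0.75))
}

#' Per-SD effect (PerSD)
#'
#' Effect value for a one-SD shift: \eqn{\exp(\sigma)} on the ratio scale.
#' Applicable to the random-intercept SD (\eqn{PerSD_u}), where it equals
#' the reference effect measure at the \eqn{\Phi(1) \approx 0.84}
#' percentile, or to the SD of an empirical covariate distribution.
#'
#' @param sigma A standard deviation (>= 0).
#' @inheritParams rem_random
#' @return Effect value.
#' @examples
#' per_sd(0.511)   # 1.67
#' @export
per_sd <- function(sigma, scale = "ratio") {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  apply_scale(sigma, scale)
}

#' Latent-scale intraclass correlation for logistic models
#'
#' \deqn{ICC = \sigma_u^2 / (\sigma_u^2 + \pi^2/3),} the share of
#' latent-variable variance attributable to clusters when subject-level
#' errors follow a standard logistic distribution.
#'
#' @param sigma_u Random-intercept SD (>= 0).
#' @return Proportion in [0, 1).
#' @examples
#' icc_latent(0.511)   # 0.074
#' @export
icc_latent <- function(sigma_u) {
  if (any(sigma_u < 0)) stop("sigma_u must be non-negative")
  sigma_u^2 / (sigma_u^2 + pi^2 / 3)
}

#' Recover sigma_u from a reported reference effect measure
#'
#' Inverts \eqn{REM_u(a) = \exp(\sigma_u \Phi^{-1}(a))}:
#' \eqn{\sigma_u = \log(REM) / \Phi^{-1}(a)}. Useful when only a REM value
#' at a known percentile is reported.
#'
#' @param rem_value Positive effect value.
#' @param a The percentile at which it was computed (not 0.5).
#' @param scale Scale on which `rem_value` is expressed: `"ratio"` or
#'   `"difference"`.
#' @return The implied sigma_u.
#' @examples
#' sigma_from_rem(1.29, 0.975)   # about 0.13
#' @export
sigma_from_rem <- function(rem_value, a, scale = "ratio") {
  check_prob(a)
  if (any(a == 0.5)) stop("a = 0.5 carries no information about sigma_u")
  x <- switch(match.arg(scale, c("ratio", "difference")),
              ratio = {
                if (any(rem_value <= 0)) stop("ratio-scale REM must be > 0")
                log(rem_value)
              },
              difference = rem_value)
  x / stats::qnorm(a)
}
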