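# Confidence intervals for REM-family measures: delta method on the
# fitted sigma_u, and the cluster (case) bootstrap that respects the
# two-level dependence structure.

new_interval <- function(point, low, high, level, method,
                         n_boot = NA_integer_, seed = NA_integer_,
                         n_failed = 0L, reps = NULL) {
  stopifnot(low <= high)
  structure(list(point = point, low = low, high = high, level = level,
                 method = method, n_boot = n_boot, seed = seed,
                 n_failed = n_failed, reps = reps),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4g (%.4g, %.4g)  [%s, %d%% CI]\n", x$point, x$low, x$high,
              x$method, round(100 * x$level)))
  if (!is.na(x$n_boot)) {
    cat("  bootstrap replicates:", x$n_boot,
        if (x$n_failed > 0) paste0("(", x$n_failed, " non-converged, ",
                                   "dropped)"), "\n")
  }
  invisible(x)
}

#' Delta-method confidence interval for a reference effect measure
#'
#' Propagates the standard error of \eqn{\hat\sigma_u} through
#' \eqn{REM_u(a) = \exp(\sigma_u \Phi^{-1}(a))}, giving the interval
#' \deqn{\exp\{(\hat\sigma_u \pm z\,SE(\hat\sigma_u))\,\Phi^{-1}(a)\}.}
#' The lower \eqn{\sigma_u} bound is truncated at 0 before transforming.
#' For `a < 0.5` the transform is decreasing in \eqn{\sigma_u}, so the raw
#' endpoints are swapped to keep `low <= high`. Intervals at `a` and `1 - a`
#' are reciprocal pairs.
#'
#' @param sigma_u Estimated random-intercept SD.
#' @param se_sigma_u Its standard error (>= 0).
#' @param a Percentile of the REM (in (0,1)).
#' @param level Nominal coverage.
#' @return An `interval_estimate`.
#' @examples
#' delta_ci_rem(0.511, 0.040, 0.975)
#' @export
delta_ci_rem <- function(sigma_u, se_sigma_u, a, level = 0.95) {
  stopifnot(sigma_u >= 0, se_sigma_u >= 0, level > 0, level < 1)
  check_prob(a)
  z <- stats::qnorm(1 - (1 - level) / 2)
  q <- stats::qnorm(a)
  s_lo <- max(sigma_u - z * se_sigma_u, 0)
  s_hi <- sigma_u + z * se_sigma_u
  ends <- sort(exp(c(s_lo * q, s_hi * q)))
  new_interval(point = exp(sigma_u * q), low = ends[1], high = ends[2],
               level = level, method = "delta")
}

#' Cluster bootstrap for any model-based statistic
#'
#' Resamples whole clusters with replacement (each sampled cluster keeps all
#' of its subjects; duplicated clusters are relabeled with fresh unique ids),
#' refits the random-intercept model on every replicate, evaluates the
#' statistic, and returns a percentile interval. Resampling at the cluster
#' level is what respects the two-level dependence structure; an iid subject
#' bootstrap would understate uncertainty in \eqn{\sigma_u}.
#'
#' Non-converged replicates are dropped and counted; more than 20% failures
#' is an error. Replicate refits start from the full-data estimates, which
#' speeds convergence considerably.
#'
#' @param data A [multilevel_data] object.
#' @param statistic Function of one argument (a fitted `rem_glmm`) returning
#'   a numeric scalar.
#' @param n_boot Number of bootstrap replicates (default 1000; fewer than 50
#'   draws a warning).
#' @param level Nominal coverage of the percentile interval.
#' @param seed Integer RNG seed (mandatory: bootstrap results must be
#'   reproducible).
#' @param n_quad Quadrature nodes for the replicate refits (fewer nodes than
#'   the headline fit is usually adequate here).
#' @param fit Optional pre-computed full-data fit (avoids refitting).
#' @param keep_reps Keep the replicate statistics (for audit / export).
#' @return An `interval_estimate`; the point estimate is the statistic on
#'   the full data.
#' @export
cluster_bootstrap <- function(data, statistic, n_boot = 1000, level = 0.95,
                              seed, n_quad = 7, fit = NULL,
                              keep_reps = FALSE) {
  stopifnot(inherits(data, "multilevel_data"), is.function(statistic),
            level > 0, level < 1)
  if (missing(seed)) stop("a seed is required for reproducible bootstrap")
  if (n_boot < 50) warning("n_boot < 50: percentile intervals will be very ",
                           "unstable")
  if (is.null(fit)) fit <- fit_random_intercept(data, n_quad = n_quad)
  point <- statistic(fit)
  stopifnot(is.numeric(point), length(point) == 1L)
  start <- list(beta = unname(fit$beta), sigma_u = max(fit$sigma_u, 0.05))

  d <- data$data
  idx_by_cluster <- split(seq_len(nrow(d)), data$cluster_f)
  n_cl <- data$n_clusters

  set.seed(seed)
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample.int(n_cl, n_cl, replace = TRUE)
    rows <- idx_by_cluster[take]
    db <- d[unlist(rows), , drop = FALSE]
    db[[data$cluster]] <- rep(seq_len(n_cl), lengths(rows))
    reps[b] <- tryCatch({
      mdb <- multilevel_data(db, outcome = data$outcome,
                             cluster = data$cluster,
                             subject_covs = data$subject_covs,
                             cluster_covs = data$cluster_covs,
                             family = data$family, offset = data$offset)
      fb <- fit_random_intercept(mdb, n_quad = n_quad, start = start)
      if (!fb$converged) NA_real_ else statistic(fb)
    }, error = function(e) NA_real_)
  }
  ok <- is.finite(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot) {
    stop("cluster bootstrap: ", n_failed, " of ", n_boot,
         " replicates failed to converge (> 20%); the model may be too ",
         "unstable for resampling at this size")
  }
  # order-statistic (type 1) percentile endpoints: keeps the interval
  # exactly equivariant under monotone transformations of the statistic
  qs <- stats::quantile(reps[ok], probs = c((1 - level) / 2,
                                            1 - (1 - level) / 2),
                        names = FALSE, type = 1)
  new_interval(point = point, low = qs[1], high = qs[2], level = level,
               method = "cluster-bootstrap", n_boot = n_boot, seed = seed,
               n_failed = n_failed,
               reps = if (keep_reps) reps[ok] else NULL)
}

#' Confidence interval for a percentile-equivalent
#'
#' Interval for \eqn{\Phi(\beta_k / \sigma_u)}, the percentile of the
#' random-effect distribution whose reference effect measure equals a
#' covariate's effect. The default is the cluster bootstrap; the delta
#' method propagates the joint covariance of \eqn{(\hat\beta_k,
#' \hat\sigma_u)} through the ratio.
#'
#' @param fit A fitted `rem_glmm`.
#' @param term Name of the coefficient.
#' @param method `"bootstrap"` or `"delta"`.
#' @param level Nominal coverage.
#' @param n_boot,seed,n_quad Passed to [cluster_bootstrap()] (bootstrap
#'   method only; `seed` is then required).
#' @return An `interval_estimate`.
#' @export
percentile_equivalent_ci <- function(fit, term,
                                     method = c("bootstrap", "delta"),
                                     level = 0.95, n_boot = 1000, seed = NULL,
                                     n_quad = 7) {
  stopifnot(inherits(fit, "rem_glmm"), term %in% names(fit$beta))
  method <- match.arg(method)
  if (is_null_sigma(fit$sigma_u)) {
    stop("percentile equivalence is undefined at the sigma_u = 0 boundary")
  }
  if (method == "delta") {
    b <- fit$beta[[term]]
    s <- fit$sigma_u
    r <- b / s
    grad <- stats::dnorm(r) * c(1 / s, -b / s^2)
    V <- fit$vcov[c(term, "sigma_u"), c(term, "sigma_u")]
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- stats::pnorm(r)
    new_interval(point = p, low = max(p - z * se, 0),
                 high = min(p + z * se, 1), level = level, method = "delta")
  } else {
    if (is.null(seed)) stop("seed is required for the bootstrap method")
    cluster_bootstrap(fit$data,
                      statistic = function(f) {
                        stats::pnorm(f$beta[[term]] / f$sigma_u)
                      },
                      n_boot = n_boot, level = level, seed = seed,
                      n_quad = n_quad, fit = fit)
  }
}
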