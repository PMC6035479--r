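# Random-intercept GLMM fitting by maximum marginal likelihood with
# adaptive Gauss-Hermite quadrature (per-cluster mode + curvature rescaling).

# Gauss-Hermite nodes/weights for weight function exp(-z^2), by Golub-Welsch:
# eigenvalues of the symmetric tridiagonal Jacobi matrix give the nodes, the
# squared first components of the eigenvectors (times sqrt(pi)) the weights.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

# Stable log(1 + exp(x))
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Per-row conditional log-likelihood, its derivative in eta, and the negative
# second derivative (conditional "weight"), for the canonical links used here.
ll_row <- function(y, eta, family, sigma_e = NULL) {
  switch(family,
    binomial = y * eta - log1pexp(eta),
    poisson  = y * eta - exp(eta) - lgamma(y + 1),
    gaussian = -0.5 * log(2 * pi * sigma_e^2) - (y - eta)^2 / (2 * sigma_e^2)
  )
}
ll_row_d1 <- function(y, eta, family, sigma_e = NULL) {
  switch(family,
    binomial = y - stats::plogis(eta),
    poisson  = y - exp(eta),
    gaussian = (y - eta) / sigma_e^2
  )
}
ll_row_d2neg <- function(y, eta, family, sigma_e = NULL) {
  switch(family,
    binomial = {p <- stats::plogis(eta); p * (1 - p)},
    poisson  = exp(eta),
    gaussian = rep.int(1 / sigma_e^2, length(eta))
  )
}

# Marginal log-likelihood of a random-intercept GLMM, integrating the cluster
# intercept out of each cluster's likelihood by adaptive GHQ. Vectorized over
# clusters: the Laplace mode search runs as one Newton iteration on the whole
# vector of cluster modes.
#
# y, eta0: subject-level outcome and fixed linear predictor (sorted by ci);
# ci: integer cluster index 1..N; returns sum over clusters (and per-cluster
# contributions) of log integral.
agq_marginal_ll <- function(y, eta0, ci, n_cl, sigma_u, family,
                            sigma_e = NULL, gh, u_start = NULL,
                            per_cluster = FALSE) {
  if (sigma_u < 1e-6) {
    llc <- drop(rowsum(ll_row(y, eta0, family, sigma_e), ci))
    return(if (per_cluster) list(ll = sum(llc), llc = llc, u_hat = rep(0, n_cl))
           else sum(llc))
  }
  u <- if (is.null(u_start)) rep(0, n_cl) else u_start
  # Newton for per-cluster posterior modes of u_i; if a warm start left us
  # too far away (damped steps cannot travel back), restart cold
  for (pass in 1:2) {
    if (pass == 2L) u <- rep(0, n_cl)
    for (iter in 1:100) {
      eta <- eta0 + u[ci]
      g1 <- drop(rowsum(ll_row_d1(y, eta, family, sigma_e), ci)) -
        u / sigma_u^2
      g2 <- -drop(rowsum(ll_row_d2neg(y, eta, family, sigma_e), ci)) -
        1 / sigma_u^2
      step <- g1 / g2
      # damp steps near the mode, but allow rapid return from far away
      cap <- pmax(4 * sigma_u + 1, abs(u) / 2)
      step <- sign(step) * pmin(abs(step), cap)
      u <- u - step
      if (max(abs(g1)) < 1e-9) break
    }
    if (max(abs(g1)) < 1e-6) break
  }
  eta <- eta0 + u[ci]
  h2 <- drop(rowsum(ll_row_d2neg(y, eta, family, sigma_e), ci)) + 1 / sigma_u^2
  tau <- 1 / sqrt(h2)
  g_mode <- drop(rowsum(ll_row(y, eta, family, sigma_e), ci)) +
    stats::dnorm(u, 0, sigma_u, log = TRUE)
  # sum_k w_k exp(g(u_hat + sqrt2*tau*z_k) - g(u_hat) + z_k^2), then restore
  acc <- numeric(n_cl)
  for (k in seq_along(gh$nodes)) {
    uk <- u + sqrt(2) * tau * gh$nodes[k]
    gk <- drop(rowsum(ll_row(y, eta0 + uk[ci], family, sigma_e), ci)) +
      stats::dnorm(uk, 0, sigma_u, log = TRUE)
    acc <- acc + gh$weights[k] * exp(gk - g_mode + gh$nodes[k]^2)
  }
  llc <- g_mode + log(sqrt(2) * tau * acc)
  if (per_cluster) list(ll = sum(llc), llc = llc, u_hat = u) else sum(llc)
}

#' Evaluate the marginal log-likelihood of a random-intercept model
#'
#' Computes the maximum-marginal-likelihood objective at user-supplied
#' parameter values, integrating the cluster random intercept out of each
#' cluster's likelihood with adaptive Gauss-Hermite quadrature. Mainly useful
#' for diagnostics and cross-checking against direct numerical integration.
#'
#' @param data A [multilevel_data] object.
#' @param beta Coefficient vector: intercept first, then subject-level then
#'   cluster-level covariates, in the order declared in `data`.
#' @param sigma_u Random-intercept standard deviation (>= 0).
#' @param n_quad Number of quadrature nodes.
#' @param sigma_e Residual SD, gaussian family only.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, beta, sigma_u, n_quad = 15,
                            sigma_e = NULL) {
  stopifnot(inherits(data, "multilevel_data"), sigma_u >= 0)
  md <- glmm_prepare(data)
  if (length(beta) != ncol(md$X)) {
    stop("beta must have length ", ncol(md$X))
  }
  eta0 <- drop(md$X %*% beta) + md$off
  agq_marginal_ll(md$y, eta0, md$ci, md$n_cl, sigma_u, md$family,
                  sigma_e = sigma_e, gh = gauss_hermite(n_quad))
}

# Build the design pieces shared by the fitter and marginal_loglik: rows
# sorted by cluster, model matrix with intercept, integer cluster index.
glmm_prepare <- function(data) {
  d <- data$data
  ord <- order(data$cluster_f)
  d <- d[ord, , drop = FALSE]
  ci <- as.integer(data$cluster_f)[ord]
  covs <- c(data$subject_covs, data$cluster_covs)
  X <- if (length(covs)) {
    stats::model.matrix(stats::reformulate(covs), data = d)
  } else {
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  }
  off <- if (!is.null(data$offset)) d[[data$offset]] else rep(0, nrow(d))
  list(y = d[[data$outcome]], X = X, ci = ci, n_cl = data$n_clusters,
       family = data$family, off = off, d = d,
       cluster_labels = levels(data$cluster_f))
}

#' Fit a two-level random-intercept generalized linear mixed model
#'
#' Maximum marginal-likelihood estimation of the model
#' \deqn{g(E[Y_{ij} \mid u_i]) = x_{ij}'\beta + u_i, \qquad
#'       u_i \sim N(0, \sigma_u^2),}
#' for subjects \eqn{j} nested in clusters \eqn{i}, with a logit link for
#' binary outcomes, a log link for counts, or an identity link for normal
#' outcomes. Each cluster's likelihood integral over \eqn{u_i} is
#' approximated by adaptive Gauss-Hermite quadrature: the integrand is
#' recentred at its per-cluster mode and rescaled by its curvature before the
#' quadrature rule is applied, which keeps a modest number of nodes accurate
#' even for large clusters.
#'
#' \eqn{\sigma_u} is optimized on the log scale to enforce positivity;
#' standard errors come from the inverse observed information at the optimum,
#' with the \eqn{\sigma_u} standard error back-transformed by the delta
#' method. Estimates with \eqn{\hat\sigma_u < 10^{-6}} are flagged as
#' boundary estimates; downstream reference-effect measures then collapse to
#' their null values.
#'
#' @param data A [multilevel_data] object.
#' @param n_quad Number of Gauss-Hermite nodes (default 15, a standard
#'   accuracy/cost balance for binary mixed models; must be >= 3).
#' @param start Optional starting values: list with `beta` (full coefficient
#'   vector, intercept first) and `sigma_u`. Defaults to a single-level GLM
#'   fit for `beta` and `sigma_u = 0.3`.
#' @param verbose Logical; print optimizer progress.
#'
#' @return An object of class `rem_glmm` with components `beta`, `sigma_u`,
#'   `se_beta`, `se_sigma_u`, `vcov` (joint covariance of
#'   \eqn{(\hat\beta, \hat\sigma_u)}), `loglik`, `converged`, `boundary`,
#'   `linpred_parts` (per-subject subject-level and cluster-level linear
#'   predictor contributions \eqn{x_{sij}'\hat\beta_s},
#'   \eqn{x_{cij}'\hat\beta_c}), `n_quad`, `family` and the input `data`.
#'
#' @examples
#' sim <- make_dataset(simulation_design(
#'   n_clusters = 30, cluster_size = 40, beta = c("(Intercept)" = -1, x = 0.5),
#'   covariates = list(x = cov_normal()), sigma_u = 0.5, seed = 42))
#' fit <- fit_random_intercept(sim$dataset, n_quad = 7)
#' fit$sigma_u
#' @export
fit_random_intercept <- function(data, n_quad = 15, start = NULL,
                                 verbose = FALSE) {
  stopifnot(inherits(data, "multilevel_data"), n_quad >= 3)
  md <- glmm_prepare(data)
  X <- md$X
  p <- ncol(X)

  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular design matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  glm_fam <- switch(md$family, binomial = stats::binomial(),
                    poisson = stats::poisson(), gaussian = stats::gaussian())
  glm0 <- stats::glm.fit(X, md$y, family = glm_fam, offset = md$off)

  gaussian_fam <- md$family == "gaussian"
  if (is.null(start)) {
    beta0 <- glm0$coefficients
    sigma_u0 <- 0.3
  } else {
    beta0 <- start$beta
    sigma_u0 <- if (!is.null(start$sigma_u)) start$sigma_u else 0.3
    if (length(beta0) != p) stop("start$beta must have length ", p)
  }
  sigma_e0 <- if (gaussian_fam) {
    max(sqrt(sum(glm0$residuals^2) / max(1, nrow(X) - p)), 1e-3)
  } else NULL

  gh <- gauss_hermite(n_quad)
  env <- new.env()
  env$u_last <- rep(0, md$n_cl)

  nll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    # keep line searches out of absurd variance territory, with a slope so
    # the optimizer is pushed back rather than facing a flat cliff
    if (theta[p + 1L] > 12) return(1e8 * (theta[p + 1L] - 11))
    beta <- theta[1:p]
    sigma_u <- exp(theta[p + 1L])
    sigma_e <- if (gaussian_fam) exp(theta[p + 2L]) else NULL
    eta0 <- drop(X %*% beta) + md$off
    res <- agq_marginal_ll(md$y, eta0, md$ci, md$n_cl, sigma_u, md$family,
                           sigma_e = sigma_e, gh = gh,
                           u_start = env$u_last, per_cluster = TRUE)
    env$u_last <- res$u_hat
    if (!is.finite(res$ll)) return(1e10)
    -res$ll
  }

  theta0 <- c(beta0, log(sigma_u0), if (gaussian_fam) log(sigma_e0))
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12,
                                     trace = as.integer(verbose)))
  # restart (fresh Hessian) if the iteration cap was hit, e.g. while
  # crawling along the flat log-sigma ridge of a boundary fit
  tries <- 0L
  while (opt$convergence != 0L && tries < 2L) {
    opt <- stats::optim(opt$par, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    tries <- tries + 1L
  }
  theta <- unname(opt$par)
  loglik <- -opt$value

  # convergence check: max-norm of the central-difference gradient
  grad <- numeric(length(theta))
  hstep <- 1e-5 * pmax(abs(theta), 1)
  for (k in seq_along(theta)) {
    tp <- tm <- theta
    tp[k] <- tp[k] + hstep[k]; tm[k] <- tm[k] - hstep[k]
    grad[k] <- (nll(tp) - nll(tm)) / (2 * hstep[k])
  }
  sigma_u_hat <- exp(theta[p + 1L])
  boundary <- sigma_u_hat < 1e-6
  # near the boundary the log-sigma direction is flat; exclude it then
  conv_grad <- if (sigma_u_hat < 1e-4) max(abs(grad[1:p])) else max(abs(grad))
  # gradient max-norm criterion, scaled by the loglik magnitude (numeric
  # derivatives cannot resolve below ~|f| * sqrt(eps))
  converged <- conv_grad <= 1e-5 * max(1, abs(loglik))

  H <- stats::optimHess(theta, nll)
  vc_theta <- tryCatch(solve(H), error = function(e) {
    s <- svd(H)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })
  # delta method back-transform: d sigma / d log(sigma) = sigma
  jac <- c(rep(1, p), sigma_u_hat, if (gaussian_fam) exp(theta[p + 2L]))
  vc <- vc_theta * tcrossprod(jac)
  keep <- 1:(p + 1L)
  vc_out <- vc[keep, keep, drop = FALSE]
  vc_out <- (vc_out + t(vc_out)) / 2

  beta_hat <- theta[1:p]
  names(beta_hat) <- colnames(X)
  dimnames(vc_out) <- list(c(colnames(X), "sigma_u"),
                           c(colnames(X), "sigma_u"))
  se_beta <- sqrt(pmax(diag(vc_out)[1:p], 0))
  se_sigma_u <- if (boundary) NA_real_ else sqrt(max(vc_out[p + 1L, p + 1L], 0))

  s_cols <- intersect(colnames(X), data$subject_covs)
  c_cols <- intersect(colnames(X), data$cluster_covs)
  # factor covariates expand to multiple columns; match by prefix
  col_of <- function(declared) {
    unlist(lapply(declared, function(v) {
      grep(paste0("^", v), colnames(X), value = TRUE)
    }))
  }
  s_cols <- col_of(data$subject_covs)
  c_cols <- col_of(data$cluster_covs)
  part <- function(cols) {
    if (length(cols) == 0L) return(rep(0, nrow(X)))
    drop(X[, cols, drop = FALSE] %*% beta_hat[cols])
  }
  linpred_parts <- data.frame(
    cluster = md$d[[data$cluster]],
    subject_part = part(s_cols),
    cluster_part = part(c_cols)
  )

  structure(
    list(family = md$family,
         beta = beta_hat,
         sigma_u = sigma_u_hat,
         sigma_e = if (gaussian_fam) exp(theta[p + 2L]) else NULL,
         se_beta = stats::setNames(se_beta, colnames(X)),
         se_sigma_u = se_sigma_u,
         vcov = vc_out,
         loglik = loglik,
         converged = converged,
         boundary = boundary,
         grad_norm = conv_grad,
         n_quad = n_quad,
         linpred_parts = linpred_parts,
         subject_cols = s_cols,
         cluster_cols = c_cols,
         data = data),
    class = "rem_glmm"
  )
}

#' @export
print.rem_glmm <- function(x, ...) {
  cat("Random-intercept GLMM (", x$family, ", adaptive GHQ, ", x$n_quad,
      " nodes)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  sigma_u:", format(x$sigma_u, digits = 4),
      if (!is.na(x$se_sigma_u)) paste0("(SE ",
                                       format(x$se_sigma_u, digits = 3), ")"),
      if (x$boundary) "[boundary]", "\n")
  if (!x$converged) cat("  WARNING: convergence not achieved (grad norm ",
                        format(x$grad_norm), ")\n", sep = "")
  print(model_table(x))
  invisible(x)
}

#' Tabulate fixed-effect estimates with odds ratios
#'
#' Produces the conventional mixed-logistic-regression results table: one row
#' per coefficient with estimate, standard error, two-sided Wald p-value, the
#' exponentiated effect (odds ratio for the logit link) and its 95% Wald CI,
#' followed by a final row for the cluster random-intercept SD and its
#' standard error.
#'
#' @param fit A fitted `rem_glmm` model.
#' @param level Confidence level for the effect-scale interval.
#' @return A data frame.
#' @export
model_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rem_glmm"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$beta
  se <- fit$se_beta
  ratio_scale <- fit$family != "gaussian"
  eff <- if (ratio_scale) exp(est) else est
  lo <- if (ratio_scale) exp(est - z * se) else est - z * se
  hi <- if (ratio_scale) exp(est + z * se) else est + z * se
  tab <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    p_value = 2 * stats::pnorm(-abs(est / se)),
    effect = unname(eff),
    conf_low = unname(lo),
    conf_high = unname(hi),
    stringsAsFactors = FALSE
  )
  tab <- rbind(tab, data.frame(
    term = "Cluster SD", estimate = fit$sigma_u, se = fit$se_sigma_u,
    p_value = NA_real_, effect = NA_real_, conf_low = NA_real_,
    conf_high = NA_real_))
  rownames(tab) <- NULL
  tab
}
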