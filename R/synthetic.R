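# Two-level synthetic data with known parameters: subjects nested in
# clusters, a cluster random intercept, subject- and cluster-level
# covariates, and a binomial / Poisson / normal outcome.

#' Covariate generators for simulation designs
#'
#' `cov_bernoulli(p)` draws a 0/1 covariate with success probability `p`;
#' `cov_normal(mean, sd)` a normal covariate. `level = "cluster"` draws one
#' value per cluster, replicated across its subjects (a site
#' characteristic); the default `"subject"` draws per subject.
#'
#' @param p Success probability in (0, 1).
#' @param mean,sd Normal parameters.
#' @param level `"subject"` or `"cluster"`.
#' @return A covariate specification used by [simulation_design()].
#' @name covariate_specs
NULL

#' @rdname covariate_specs
#' @export
cov_bernoulli <- function(p, level = "subject") {
  stopifnot(p > 0, p < 1)
  structure(list(draw = function(n) stats::rbinom(n, 1, p),
                 level = match.arg(level, c("subject", "cluster"))),
            class = "cov_spec")
}

#' @rdname covariate_specs
#' @export
cov_normal <- function(mean = 0, sd = 1, level = "subject") {
  stopifnot(sd >= 0)
  structure(list(draw = function(n) stats::rnorm(n, mean, sd),
                 level = match.arg(level, c("subject", "cluster"))),
            class = "cov_spec")
}

#' Specify a two-level simulation design
#'
#' Collects everything needed to generate a dataset from the
#' random-intercept model: the linear predictor is
#' \eqn{x_{ij}'\beta + u_i} with \eqn{u_i} drawn from `random_effect`
#' (normal with SD `sigma_u` by default), and the outcome is drawn from
#' `family` through its canonical link.
#'
#' @param n_clusters Number of clusters N (>= 2).
#' @param cluster_size Either a fixed integer number of subjects per
#'   cluster, or `poisson_sizes(lambda)` for unbalanced Poisson-distributed
#'   sizes (truncated at 2).
#' @param beta Named true coefficients; must contain `"(Intercept)"`, other
#'   names must match `covariates`.
#' @param covariates Named list of covariate specs ([cov_bernoulli()],
#'   [cov_normal()]).
#' @param sigma_u SD of the normal random intercept (ignored if
#'   `random_effect` supplied).
#' @param random_effect Optional [ranef_dist] replacing the normal default
#'   (sampled by inverse-CDF, so any median-centered family works).
#' @param family Outcome family.
#' @param sigma_e Residual SD, gaussian family only.
#' @param seed Mandatory integer seed.
#' @return A `simulation_design` object.
#' @export
simulation_design <- function(n_clusters, cluster_size,
                              beta = c("(Intercept)" = -1.5),
                              covariates = list(),
                              sigma_u = 0.5, random_effect = NULL,
                              family = c("binomial", "poisson", "gaussian"),
                              sigma_e = 1, seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("a seed is mandatory in a simulation design")
  stopifnot(n_clusters >= 2)
  if (!"(Intercept)" %in% names(beta)) {
    stop("beta must contain an \"(Intercept)\" element")
  }
  extra <- setdiff(names(beta), c("(Intercept)", names(covariates)))
  if (length(extra) > 0L) {
    stop("beta names without a covariate spec: ",
         paste(extra, collapse = ", "))
  }
  if (is.null(random_effect)) random_effect <- ranef_normal(sigma_u)
  structure(list(n_clusters = n_clusters, cluster_size = cluster_size,
                 beta = beta, covariates = covariates,
                 random_effect = random_effect, family = family,
                 sigma_e = sigma_e, seed = seed),
            class = "simulation_design")
}

#' @rdname simulation_design
#' @param lambda Mean cluster size.
#' @export
poisson_sizes <- function(lambda) {
  structure(list(lambda = lambda), class = "poisson_sizes")
}

#' Generate a two-level dataset from a design
#'
#' Draws cluster random intercepts by inverse-CDF sampling from the design's
#' (median-centered) random-effect distribution, covariates per their specs,
#' and outcomes from the family's conditional distribution at linear
#' predictor \eqn{x'\beta + u_i}. Fully reproducible given the design seed.
#'
#' The true per-cluster intercepts are returned alongside, never inside, the
#' dataset: the analysis path sees only what a real study would.
#'
#' @param design A [simulation_design()].
#' @return A list with `dataset` (a [multilevel_data]), `u` (true cluster
#'   intercepts), and `design`.
#' @examples
#' sim <- make_dataset(simulation_design(n_clusters = 5, cluster_size = 10,
#'                                       seed = 7))
#' table(sim$dataset$data$cluster)
#' @export
make_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  N <- design$n_clusters
  sizes <- if (inherits(design$cluster_size, "poisson_sizes")) {
    pmax(stats::rpois(N, design$cluster_size$lambda), 2L)
  } else {
    rep(as.integer(design$cluster_size), N)
  }
  if (any(sizes < 1L)) stop("degenerate design: empty cluster(s)")
  n <- sum(sizes)
  cl <- rep(seq_len(N), sizes)

  u <- design$random_effect$quantile(stats::runif(N))

  covs <- list()
  subject_covs <- character()
  cluster_covs <- character()
  for (nm in names(design$covariates)) {
    spec <- design$covariates[[nm]]
    if (spec$level == "cluster") {
      covs[[nm]] <- spec$draw(N)[cl]
      cluster_covs <- c(cluster_covs, nm)
    } else {
      covs[[nm]] <- spec$draw(n)
      subject_covs <- c(subject_covs, nm)
    }
  }

  eta <- rep(design$beta[["(Intercept)"]], n) + u[cl]
  for (nm in names(covs)) {
    b <- if (nm %in% names(design$beta)) design$beta[[nm]] else 0
    eta <- eta + b * covs[[nm]]
  }

  y <- switch(design$family,
    binomial = stats::rbinom(n, 1, stats::plogis(eta)),
    poisson  = stats::rpois(n, exp(eta)),
    gaussian = stats::rnorm(n, eta, design$sigma_e)
  )

  d <- data.frame(y = y, cluster = cl)
  for (nm in names(covs)) d[[nm]] <- covs[[nm]]

  md <- multilevel_data(d, outcome = "y", cluster = "cluster",
                        subject_covs = subject_covs,
                        cluster_covs = cluster_covs,
                        family = design$family)
  list(dataset = md, u = u, design = design)
}

#' A compact fixture mimicking a procedure-use study
#'
#' A fixed published design echoing the qualitative structure of hospital
#' variation in treatment initiation: several subject-level risk factors
#' whose combined risk distribution is wide, weak cluster-level (site)
#' characteristics whose distribution is narrow, and a cluster random
#' intercept (`sigma_u = 0.5`) whose contribution is comparable to the
#' combined subject factors. Cluster sizes are moderately unbalanced
#' (Poisson with mean 60 across 60 clusters) and the intercept is calibrated
#' so the overall event rate is near 14.6%.
#'
#' @param seed Integer seed.
#' @return As [make_dataset()].
#' @export
make_af_like_fixture <- function(seed = 20180706) {
  design <- simulation_design(
    n_clusters = 60,
    cluster_size = poisson_sizes(60),
    beta = c("(Intercept)" = -2.16,
             age_z = -0.27, chf = 0.41, prior_ac = 0.37, alcohol = -0.36,
             ep_onsite = 0.08, rural_prop = -0.06),
    covariates = list(
      age_z = cov_normal(),
      chf = cov_bernoulli(0.30),
      prior_ac = cov_bernoulli(0.25),
      alcohol = cov_bernoulli(0.10),
      ep_onsite = cov_bernoulli(0.50, level = "cluster"),
      rural_prop = cov_normal(level = "cluster")),
    sigma_u = 0.5,
    family = "binomial",
    seed = seed)
  make_dataset(design)
}

#' Write a simulated dataset to disk
#'
#' Writes the analysis CSV (no true random effects) plus a sidecar JSON of
#' the true parameters for audit.
#'
#' @param sim Output of [make_dataset()].
#' @param prefix Path prefix; writes `<prefix>.csv` and
#'   `<prefix>_truth.json`.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(sim, prefix) {
  csv <- paste0(prefix, ".csv")
  truth <- paste0(prefix, "_truth.json")
  utils::write.csv(sim$dataset$data, csv, row.names = FALSE)
  re <- sim$design$random_effect
  jsonlite::write_json(
    list(beta = as.list(sim$design$beta),
         random_effect = list(kind = re$kind, params = re$params),
         family = sim$design$family,
         seed = sim$design$seed,
         u = sim$u),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, truth))
}
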