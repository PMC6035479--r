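#' Construct a two-level multilevel dataset
#'
#' Validates and packages subject-level data for random-intercept modelling:
#' a binary (or count) outcome, a cluster identifier, and fixed-effect
#' covariates partitioned into subject-level and cluster-level columns.
#' Cluster-level covariates must be constant within each cluster. Rows with
#' missing values in any used column are dropped with a message reporting the
#' count.
#'
#' @param data A data frame with one row per subject.
#' @param outcome Name of the outcome column. For `family = "binomial"` it
#'   must be coded 0/1; for `"poisson"` a non-negative integer count; for
#'   `"gaussian"` any numeric.
#' @param cluster Name of the cluster-identifier column (factor, character or
#'   integer labels).
#' @param subject_covs Character vector of subject-level covariate column
#'   names (may be empty).
#' @param cluster_covs Character vector of cluster-level covariate column
#'   names (may be empty); each must be constant within every cluster.
#' @param family Outcome family: `"binomial"` (logit link), `"poisson"`
#'   (log link) or `"gaussian"` (identity link).
#' @param offset Optional name of an offset column (log scale), Poisson
#'   family only.
#'
#' @return An object of class `multilevel_data`: a list with the validated
#'   data frame (`data`), the column roles, `family`, the cluster factor
#'   (`cluster_f`), per-cluster sizes (`n_i`) and the number of clusters
#'   (`n_clusters`).
#'
#' @examples
#' d <- make_dataset(simulation_design(n_clusters = 10, cluster_size = 20,
#'                                     seed = 1))
#' md <- d$dataset
#' md$n_clusters
#' @export
multilevel_data <- function(data, outcome, cluster,
                            subject_covs = character(),
                            cluster_covs = character(),
                            family = c("binomial", "poisson", "gaussian"),
                            offset = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  cols <- c(outcome, cluster, subject_covs, cluster_covs, offset)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(offset) && family != "poisson") {
    stop("an offset column is supported for the poisson family only")
  }

  data <- as.data.frame(data)[, cols, drop = FALSE]
  complete <- stats::complete.cases(data)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " row(s) with missing values")
    data <- data[complete, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no complete rows remain")

  y <- data[[outcome]]
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial outcome must be coded 0/1")
  }
  if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
    stop("poisson outcome must be a non-negative integer count")
  }
  if (!is.numeric(y)) stop("outcome must be numeric")

  cluster_f <- factor(data[[cluster]])
  if (nlevels(cluster_f) < 2L) {
    stop("at least 2 clusters are required (sigma_u is unidentifiable ",
         "with a single cluster)")
  }
  for (cc in cluster_covs) {
    per_cluster <- tapply(data[[cc]], cluster_f,
                          function(v) length(unique(v)))
    if (any(per_cluster > 1L)) {
      bad <- names(per_cluster)[per_cluster > 1L]
      stop("cluster-level covariate '", cc, "' varies within cluster(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }

  structure(
    list(data = data,
         outcome = outcome,
         cluster = cluster,
         subject_covs = subject_covs,
         cluster_covs = cluster_covs,
         offset = offset,
         family = family,
         cluster_f = cluster_f,
         n_i = as.integer(table(cluster_f)),
         n_clusters = nlevels(cluster_f),
         n_dropped = n_dropped),
    class = "multilevel_data"
  )
}

#' Read a multilevel dataset from a delimited text file
#'
#' Thin wrapper around [utils::read.csv()] plus [multilevel_data()] so that a
#' CSV with a header row can be loaded and validated in one call.
#'
#' @param file Path to a CSV file with a header.
#' @inheritParams multilevel_data
#' @param ... Passed to [utils::read.csv()].
#' @return A [multilevel_data] object.
#' @export
read_multilevel_csv <- function(file, outcome, cluster,
                                subject_covs = character(),
                                cluster_covs = character(),
                                family = "binomial", offset = NULL, ...) {
  multilevel_data(utils::read.csv(file, ...), outcome = outcome,
                  cluster = cluster, subject_covs = subject_covs,
                  cluster_covs = cluster_covs, family = family,
                  offset = offset)
}

#' @export
print.multilevel_data <- function(x, ...) {
  cat("Two-level dataset:", nrow(x$data), "subjects in", x$n_clusters,
      "clusters\n")
  cat("  outcome:", x$outcome, "(", x$family, ")\n")
  cat("  subject covariates:",
      if (length(x$subject_covs)) paste(x$subject_covs, collapse = ", ")
      else "(none)", "\n")
  cat("  cluster covariates:",
      if (length(x$cluster_covs)) paste(x$cluster_covs, collapse = ", ")
      else "(none)", "\n")
  if (x$n_dropped > 0L) cat("  rows dropped for missingness:", x$n_dropped,
                            "\n")
  invisible(x)
}
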