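# Assemble all REM measures, comparison measures and confidence intervals
# into one report, from either a fitted model (full-data mode) or printed
# estimates (measures-only mode).

#' Build a reference-effect-measures report
#'
#' Computes, for each declared source of variation (covariate subsets and
#' the cluster random effect), the central REM range and REM point values
#' with confidence intervals, plus the comparison block (MOR, the percentile
#' at which MOR equals REM, per-SD odds ratio, latent-scale ICC, and
#' optional individual outcome measures for user-specified covariate
#' patterns).
#'
#' Two entry modes are supported. In full-data mode (`fit` supplied) the
#' empirical risk distributions of covariate subsets are available and
#' bootstrap CIs can be requested. In measures-only mode (`estimates`
#' supplied: a list with `sigma_u` and optionally `se_sigma_u` and a named
#' `beta` vector) everything that is a closed-form function of the printed
#' estimates is computed; empirical REM and bootstrap CIs then error
#' informatively because they require subject-level data.
#'
#' @param fit A fitted `rem_glmm` (full-data mode).
#' @param estimates Named list with `sigma_u`, optionally `se_sigma_u`,
#'   `beta` (measures-only mode).
#' @param subsets Character vector of covariate subsets to report
#'   (`"subject"`, `"cluster"`, `"all"`, or covariate names); full-data mode
#'   only. Defaults to the declared subject and cluster sets that exist.
#' @param a_values REM percentiles to report as points (default 0.75 and
#'   0.975: moderate and extreme comparisons).
#' @param level Coverage for both REM ranges and CIs.
#' @param ci `"delta"`, `"bootstrap"`, `"both"` or `"none"`. Delta CIs exist
#'   only for the random-effect REM; bootstrap CIs cover every source but
#'   need data.
#' @param n_boot,seed Bootstrap settings (seed also stamps the report).
#' @param n_quad Quadrature nodes for bootstrap refits.
#' @param iom_patterns Optional named numeric vector of linear-predictor
#'   values \eqn{x'\beta}; an IOM range is reported for each.
#' @return An object of class `rem_report`.
#' @export
rem_report <- function(fit = NULL, estimates = NULL, subsets = NULL,
                       a_values = c(0.75, 0.975), level = 0.95,
                       ci = c("delta", "bootstrap", "both", "none"),
                       n_boot = 1000, seed = NULL, n_quad = 7,
                       iom_patterns = NULL) {
  ci <- match.arg(ci)
  if (is.null(fit) == is.null(estimates)) {
    stop("supply exactly one of 'fit' (full-data mode) or 'estimates' ",
         "(measures-only mode)")
  }
  measures_only <- is.null(fit)
  if (measures_only) {
    sigma_u <- estimates$sigma_u
    se_sigma_u <- if (!is.null(estimates$se_sigma_u)) estimates$se_sigma_u
                  else NA_real_
    beta <- estimates$beta
    if (ci %in% c("bootstrap", "both")) {
      stop("bootstrap CIs require subject-level data; measures-only mode ",
           "supports delta CIs only")
    }
    if (!is.null(subsets)) {
      stop("empirical covariate-subset REM requires subject-level data; ",
           "not available in measures-only mode")
    }
    family <- if (!is.null(estimates$family)) estimates$family
              else "binomial"
  } else {
    stopifnot(inherits(fit, "rem_glmm"))
    sigma_u <- fit$sigma_u
    se_sigma_u <- fit$se_sigma_u
    beta <- fit$beta
    family <- fit$family
    if (is.null(subsets)) {
      subsets <- c(if (length(fit$data$subject_covs)) "subject",
                   if (length(fit$data$cluster_covs)) "cluster")
    }
  }
  if (is.null(sigma_u) || sigma_u < 0) stop("a non-negative sigma_u is required")
  boundary <- is_null_sigma(sigma_u)
  if (boundary) {
    warning("sigma_u is at the zero boundary; all random-effect measures ",
            "take their null values")
  }
  do_boot <- ci %in% c("bootstrap", "both") && !measures_only
  do_delta <- ci %in% c("delta", "both") && !is.na(se_sigma_u) && !boundary
  if (do_boot && is.null(seed)) stop("bootstrap CIs require a seed")

  gce <- ranef_normal(sigma_u)
  dists <- list()
  rows <- list()

  add_source <- function(label, kind, dist, boot_stat = NULL) {
    rng <- if (kind == "gce") rem_range(dist, level)
           else rem_empirical_range(dist, level)
    row <- data.frame(label = label, kind = kind,
                      range_low = rng[["low"]], range_high = rng[["high"]])
    for (a in a_values) {
      point <- if (kind == "gce") rem_random(dist, a)
               else rem_empirical(dist, a)
      row[[sprintf("rem_%g", a)]] <- point
      lo <- hi <- NA_real_
      if (kind == "gce" && do_delta) {
        dci <- delta_ci_rem(sigma_u, se_sigma_u, a, level)
        lo <- dci$low; hi <- dci$high
      }
      if (do_boot && !is.null(boot_stat)) {
        bci <- cluster_bootstrap(fit$data, boot_stat(a), n_boot = n_boot,
                                 level = level, seed = seed,
                                 n_quad = n_quad, fit = fit)
        lo <- bci$low; hi <- bci$high
      }
      row[[sprintf("rem_%g_low", a)]] <- lo
      row[[sprintf("rem_%g_high", a)]] <- hi
    }
    rows[[length(rows) + 1L]] <<- row
    dists[[label]] <<- dist
  }

  if (!measures_only) {
    for (s in subsets) {
      rd <- model_risk_dist(fit, which = s)
      add_source(rd$label, "empirical", rd,
                 boot_stat = function(a) {
                   force(s); force(a)
                   function(f) rem_empirical(model_risk_dist(f, which = s), a)
                 })
    }
  }
  add_source("unexplained cluster variation", "gce", gce,
             boot_stat = if (do_boot) {
               function(a) {
                 force(a)
                 function(f) rem_random(f$sigma_u, a)
               }
             })

  comparison <- list(
    mor = if (boundary) 1 else mor(sigma_u),
    mor_percentile = mor_percentile(),
    per_sd_u = if (boundary) 1 else per_sd(sigma_u),
    icc = if (boundary) 0 else icc_latent(sigma_u)
  )
  if (!is.null(beta)) {
    terms <- setdiff(names(beta), "(Intercept)")
    if (length(terms) > 0L && !boundary) {
      pe <- pnorm_safe(beta[terms] / sigma_u)
      comparison$percentile_equivalents <- data.frame(
        term = terms,
        or = exp(unname(beta[terms])),
        percentile = unname(pe),
        flipped = 1 - unname(pe))
    }
  }
  if (!is.null(iom_patterns)) {
    if (family != "binomial") stop("IOM requires the binomial-logit family")
    alo <- (1 - level) / 2
    comparison$iom <- data.frame(
      pattern = names(iom_patterns),
      linpred = unname(iom_patterns),
      prob_median = iom(unname(iom_patterns), gce, 0.5),
      prob_low = iom(unname(iom_patterns), gce, alo),
      prob_high = iom(unname(iom_patterns), gce, 1 - alo))
  }

  model_block <- if (measures_only) {
    list(sigma_u = sigma_u, se_sigma_u = se_sigma_u,
         beta = if (!is.null(beta)) as.list(beta))
  } else {
    model_table(fit, level = level)
  }

  structure(
    list(sources = do.call(rbind, rows),
         dists = dists,
         comparison = comparison,
         model = model_block,
         meta = list(mode = if (measures_only) "measures-only" else "full",
                     level = level, a_values = a_values, ci = ci,
                     n_boot = if (do_boot) n_boot else NA_integer_,
                     seed = if (!is.null(seed)) seed else NA_integer_,
                     sigma_u = sigma_u, se_sigma_u = se_sigma_u,
                     boundary = boundary, family = family,
                     version = as.character(utils::packageVersion("remvar")))),
    class = "rem_report")
}

pnorm_safe <- function(x) stats::pnorm(x)

#' @export
print.rem_report <- function(x, digits = 2, ...) {
  cat("Reference effect measures (", x$meta$mode, " mode, ",
      round(100 * x$meta$level), "% ranges)\n\n", sep = "")
  s <- x$sources
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits = digits)
  print(s, row.names = FALSE)
  cat("\nComparison measures:\n")
  cat(sprintf("  MOR       %.*f  (= REM at the %.0fth percentile)\n",
              digits, x$comparison$mor,
              100 * x$comparison$mor_percentile))
  cat(sprintf("  PerSD_u   %.*f\n", digits, x$comparison$per_sd_u))
  cat(sprintf("  ICC       %.3f  (latent scale)\n", x$comparison$icc))
  if (!is.null(x$comparison$iom)) {
    cat("  IOM ranges:\n")
    print(within(x$comparison$iom, {
      prob_median <- round(prob_median, 3)
      prob_low <- round(prob_low, 3)
      prob_high <- round(prob_high, 3)
    }), row.names = FALSE)
  }
  invisible(x)
}

#' Write a report to JSON and CSV
#'
#' `report.json` carries full precision; `report.csv` is the table of
#' sources; `table1.csv` (full-data mode) is the coefficient table.
#'
#' @param report A `rem_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rem_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  j <- file.path(dir, "report.json")
  payload <- list(sources = report$sources,
                  comparison = report$comparison,
                  meta = report$meta)
  if (report$meta$mode == "full") payload$model <- report$model
  else payload$model <- report$model
  jsonlite::write_json(payload, j, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  paths <- c(paths, j)
  cs <- file.path(dir, "report.csv")
  utils::write.csv(report$sources, cs, row.names = FALSE)
  paths <- c(paths, cs)
  if (is.data.frame(report$model)) {
    t1 <- file.path(dir, "table1.csv")
    utils::write.csv(report$model, t1, row.names = FALSE)
    paths <- c(paths, t1)
  }
  invisible(paths)
}
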