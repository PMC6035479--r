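# End-to-end pipeline: config -> (load or simulate data) -> fit ->
# measures -> intervals -> tables and figures on disk.

#' Run the full analysis pipeline from a config
#'
#' Reads a JSON config (or an equivalent named list), executes the
#' requested mode, and writes `report.json`, `report.csv`, a `table1.csv`
#' coefficient table and the two figures (full-data mode) into `out_dir`.
#' All randomness (simulation, bootstrap) flows from the single `seed`
#' field.
#'
#' Config fields: `mode` (`"full"` or `"measures"`); `seed`; `level`;
#' full mode: either `data` (`csv`, `outcome`, `cluster`, `subject_covs`,
#' `cluster_covs`, `family`) or `simulate` (`af_fixture = true` for the
#' built-in fixture), plus `n_quad`, `ci` (`delta` / `bootstrap` / `both` /
#' `none`), `n_boot`; measures mode: `estimates` (`sigma_u`,
#' optional `se_sigma_u`, named `beta`). Optional `iom_patterns`: named
#' list, each entry either a number (a linear-predictor value) or an array
#' of coefficient names summed from `beta`. Optional `figures`: file
#' extension for the plots (default `"pdf"`; `false` to skip).
#'
#' @param config Path to a JSON config file, or a named list.
#' @param out_dir Output directory; `NULL` computes the report without
#'   writing artifacts.
#' @param verbose Print stage progress to stderr.
#' @return The `rem_report`, invisibly, with the fitted model (if any)
#'   attached as attribute `"fit"`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  say <- function(...) if (verbose) message("[remvar] ", ...)

  mode <- config$mode
  if (is.null(mode) || !mode %in% c("full", "measures")) {
    stop("config field 'mode' must be \"full\" or \"measures\"")
  }
  level <- config$level %||% 0.95
  seed <- config$seed
  ci <- config$ci %||% "delta"

  fit <- NULL
  if (mode == "full") {
    if (!is.null(config$data)) {
      dc <- config$data
      for (f in c("csv", "outcome", "cluster")) {
        if (is.null(dc[[f]])) stop("config field 'data$", f, "' is required")
      }
      say("loading ", dc$csv)
      md <- read_multilevel_csv(
        dc$csv, outcome = dc$outcome, cluster = dc$cluster,
        subject_covs = dc$subject_covs %||% character(),
        cluster_covs = dc$cluster_covs %||% character(),
        family = dc$family %||% "binomial")
    } else if (!is.null(config$simulate)) {
      if (is.null(seed)) stop("config field 'seed' is required to simulate")
      if (isTRUE(config$simulate$af_fixture)) {
        say("generating built-in fixture (seed ", seed, ")")
        md <- make_af_like_fixture(seed)$dataset
      } else {
        stop("config field 'simulate' supports af_fixture = true")
      }
    } else {
      stop("full mode requires a 'data' or 'simulate' config block")
    }
    n_quad <- config$n_quad %||% 15
    say("fitting random-intercept model (", n_quad, " quadrature nodes)")
    fit <- fit_random_intercept(md, n_quad = n_quad)
    if (!fit$converged) {
      warning("model fit did not meet the convergence criteria ",
              "(gradient norm ", format(fit$grad_norm), ")")
    }
    say("sigma_u = ", format(fit$sigma_u, digits = 4))
    iom_patterns <- resolve_iom_patterns(config$iom_patterns, fit$beta)
    report <- rem_report(fit = fit, level = level, ci = ci,
                         n_boot = config$n_boot %||% 1000, seed = seed,
                         n_quad = config$boot_n_quad %||% 7,
                         iom_patterns = iom_patterns)
  } else {
    est <- config$estimates
    if (is.null(est$sigma_u)) {
      stop("config field 'estimates$sigma_u' is required in measures mode")
    }
    beta <- if (!is.null(est$beta)) unlist(est$beta) else NULL
    iom_patterns <- resolve_iom_patterns(config$iom_patterns, beta)
    report <- rem_report(estimates = list(sigma_u = est$sigma_u,
                                          se_sigma_u = est$se_sigma_u,
                                          beta = beta),
                         level = level, ci = ci,
                         iom_patterns = iom_patterns)
  }

  if (!is.null(out_dir)) {
    say("writing artifacts to ", out_dir)
    write_report(report, out_dir)
    ext <- config$figures %||% "pdf"
    if (!isFALSE(ext)) {
      variation_sources_plot(report,
                             file.path(out_dir,
                                       paste0("variation_sources.", ext)))
      rows <- forest_rows_from(report, fit)
      forest_plot(rows, file.path(out_dir, paste0("forest.", ext)))
    }
  }
  attr(report, "fit") <- fit
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_iom_patterns <- function(spec, beta) {
  if (is.null(spec)) return(NULL)
  out <- vapply(spec, function(v) {
    if (is.numeric(v)) return(sum(v))
    if (is.character(v)) {
      miss <- setdiff(v, names(beta))
      if (length(miss) > 0L) {
        stop("iom pattern names not among coefficients: ",
             paste(miss, collapse = ", "))
      }
      return(sum(beta[v]))
    }
    stop("each iom pattern must be numeric or coefficient names")
  }, numeric(1))
  stats::setNames(out, names(spec))
}

# forest rows: fixed effects from the model table (if any), then the GCE
# band and empirical bands
forest_rows_from <- function(report, fit) {
  rows <- list()
  if (!is.null(fit)) {
    tab <- model_table(fit, level = report$meta$level)
    tab <- tab[!(tab$term %in% c("(Intercept)", "Cluster SD")), ]
    for (i in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- forest_row_effect(
        tab$term[i], tab$effect[i], tab$conf_low[i], tab$conf_high[i])
    }
  }
  for (lb in names(report$dists)) {
    rows[[length(rows) + 1L]] <- forest_row_band(lb, report$dists[[lb]])
  }
  rows
}
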