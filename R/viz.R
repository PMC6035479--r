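# Displays: a forest plot mixing fixed-effect odds ratios with shaded REM
# distribution bands, and a variation-sources plot of REM ranges with
# REM(0.75)-style points and CI whiskers. The numeric layer bound to the
# glyphs is exposed separately from rendering so it can be tested directly.

#' Forest-plot rows
#'
#' `forest_row_effect()` declares a point-and-whisker row for a fixed
#' effect (odds ratio and CI); `forest_row_band()` declares a shaded
#' REM-distribution band for a random-effect or empirical risk
#' distribution.
#'
#' @param label Row label.
#' @param effect Effect value (odds ratio; must be positive).
#' @param low,high CI endpoints (positive).
#' @param dist A [ranef_dist] or [risk_dist].
#' @return A `forest_row` object.
#' @name forest_rows
NULL

#' @rdname forest_rows
#' @export
forest_row_effect <- function(label, effect, low = NA, high = NA) {
  if (any(c(effect, low, high) <= 0, na.rm = TRUE)) {
    stop("ratio-scale effects and CI endpoints must be positive")
  }
  structure(list(label = label, kind = "fixed-effect", effect = effect,
                 low = low, high = high),
            class = "forest_row")
}

#' @rdname forest_rows
#' @export
forest_row_band <- function(label, dist) {
  if (!inherits(dist, "ranef_dist") && !inherits(dist, "risk_dist")) {
    stop("dist must be a ranef_dist or risk_dist")
  }
  structure(list(label = label, kind = "rem-band", dist = dist),
            class = "forest_row")
}

band_quantile <- function(dist, a) {
  if (inherits(dist, "ranef_dist")) rem_random(dist, a)
  else rem_empirical(dist, a)
}

#' Numeric layer of a forest plot
#'
#' Returns the exact numbers bound to the plot glyphs: one data frame of
#' point-and-whisker effects and one of nested shaded bands. Band edges at
#' upper percentile `p` are the REM values at percentiles `1 - p` and `p`
#' (so the outermost default band spans the 95% REM range exactly).
#'
#' @param rows List of [forest_row_effect()] / [forest_row_band()] rows;
#'   display order is the order given.
#' @param percentiles Upper percentiles of the shading ladder (mirrored
#'   below the median); default `c(0.975, 0.9, 0.8, 0.7, 0.6, 0.5)`.
#' @return List with data frames `effects` (label, y, effect, low, high)
#'   and `bands` (label, y, percentile, low, high, alpha).
#' @export
forest_plot_data <- function(rows,
                             percentiles = c(0.975, 0.9, 0.8, 0.7, 0.6,
                                             0.5)) {
  if (length(rows) < 1L) stop("at least one row is required")
  if (inherits(rows, "forest_row")) rows <- list(rows)
  stopifnot(all(vapply(rows, inherits, logical(1), "forest_row")))
  percentiles <- sort(unique(pmax(percentiles, 1 - percentiles)),
                      decreasing = TRUE)
  n <- length(rows)
  eff <- list(); bands <- list()
  for (i in seq_len(n)) {
    r <- rows[[i]]
    y <- n - i + 1L   # first row on top
    if (r$kind == "fixed-effect") {
      eff[[length(eff) + 1L]] <- data.frame(
        label = r$label, y = y, effect = r$effect, low = r$low,
        high = r$high)
    } else {
      # alpha ramp: darkest at the median, lightest at the extremes
      alphas <- seq(0.15, 0.85, length.out = length(percentiles))
      for (k in seq_along(percentiles)) {
        p <- percentiles[k]
        lo <- band_quantile(r$dist, 1 - p)
        hi <- band_quantile(r$dist, p)
        bands[[length(bands) + 1L]] <- data.frame(
          label = r$label, y = y, percentile = p, low = min(lo, hi),
          high = max(lo, hi), alpha = alphas[k])
      }
    }
  }
  list(effects = if (length(eff)) do.call(rbind, eff) else
         data.frame(label = character(), y = numeric(), effect = numeric(),
                    low = numeric(), high = numeric()),
       bands = if (length(bands)) do.call(rbind, bands) else
         data.frame(label = character(), y = numeric(),
                    percentile = numeric(), low = numeric(),
                    high = numeric(), alpha = numeric()),
       labels = vapply(rows, `[[`, character(1), "label"))
}

render_forest <- function(pd, xlab, band_fill = "#2166AC",
                          band_height = 0.38) {
  n <- length(pd$labels)
  g <- ggplot2::ggplot()
  if (nrow(pd$bands) > 0) {
    g <- g + ggplot2::geom_rect(
      data = pd$bands,
      ggplot2::aes(xmin = .data$low, xmax = .data$high,
                   ymin = .data$y - band_height,
                   ymax = .data$y + band_height,
                   alpha = .data$alpha),
      fill = band_fill)
  }
  if (nrow(pd$effects) > 0) {
    has_ci <- !is.na(pd$effects$low)
    if (any(has_ci)) {
      g <- g + ggplot2::geom_errorbarh(
        data = pd$effects[has_ci, ],
        ggplot2::aes(xmin = .data$low, xmax = .data$high, y = .data$y),
        height = 0.2)
    }
    g <- g + ggplot2::geom_point(
      data = pd$effects,
      ggplot2::aes(x = .data$effect, y = .data$y), size = 2)
  }
  g +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(breaks = seq(n, 1),
                                labels = pd$labels,
                                limits = c(0.5, n + 0.5)) +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios and REM distribution bands
#'
#' Draws fixed effects as points with CI whiskers and REM distributions as
#' nested shaded bands that darken toward the median, on a log-scaled axis
#' with a reference line at 1. Rendering is deterministic; the figure
#' format follows the file extension (`.pdf`, `.png`, `.svg`).
#'
#' @inheritParams forest_plot_data
#' @param file Optional output path; when `NULL` the ggplot object is
#'   returned unrendered.
#' @param xlab Axis label.
#' @param width,height Figure size in inches.
#' @return The ggplot object, invisibly when written to file.
#' @export
forest_plot <- function(rows, file = NULL,
                        percentiles = c(0.975, 0.9, 0.8, 0.7, 0.6, 0.5),
                        xlab = "Odds ratio", width = 7, height = NULL) {
  pd <- forest_plot_data(rows, percentiles)
  g <- render_forest(pd, xlab = xlab)
  if (!is.null(file)) {
    if (is.null(height)) height <- max(2, 0.4 * length(pd$labels) + 1)
    ggplot2::ggsave(file, g, width = width, height = height)
    return(invisible(g))
  }
  g
}

#' Numeric layer of the variation-sources plot
#'
#' One shaded band per variation source in a [rem_report] (covariate
#' subsets and unexplained cluster variation), with the reported REM point
#' values and their CI whiskers.
#'
#' @param report A `rem_report` built in full-data mode (or any report
#'   carrying distributions).
#' @inheritParams forest_plot_data
#' @return List with `bands`, `points` (label, y, a, rem, low, high) and
#'   `labels`.
#' @export
variation_plot_data <- function(report,
                                percentiles = c(0.975, 0.9, 0.8, 0.7, 0.6,
                                                0.5)) {
  stopifnot(inherits(report, "rem_report"))
  rows <- lapply(names(report$dists), function(lb) {
    forest_row_band(lb, report$dists[[lb]])
  })
  pd <- forest_plot_data(rows, percentiles)
  pts <- list()
  s <- report$sources
  for (i in seq_len(nrow(s))) {
    y <- nrow(s) - i + 1L
    for (a in report$meta$a_values) {
      pts[[length(pts) + 1L]] <- data.frame(
        label = s$label[i], y = y, a = a,
        rem = s[[sprintf("rem_%g", a)]][i],
        low = s[[sprintf("rem_%g_low", a)]][i],
        high = s[[sprintf("rem_%g_high", a)]][i])
    }
  }
  list(bands = pd$bands, points = do.call(rbind, pts), labels = pd$labels)
}

#' Variation-sources plot
#'
#' Shaded REM bands for every source of variation in a report, with REM
#' point values (e.g. REM(0.75)) and CI whiskers overlaid. Additional
#' single-covariate empirical distributions (e.g. a continuous covariate's
#' risk band) can be appended via `overlay`.
#'
#' @inheritParams variation_plot_data
#' @param file Optional output path (format from extension).
#' @param overlay Optional named list of extra [risk_dist]/[ranef_dist]
#'   objects appended as additional bands.
#' @param xlab Axis label.
#' @param width,height Figure size in inches.
#' @return The ggplot object.
#' @export
variation_sources_plot <- function(report, file = NULL,
                                   percentiles = c(0.975, 0.9, 0.8, 0.7,
                                                   0.6, 0.5),
                                   overlay = NULL,
                                   xlab = "Odds ratio vs. median reference",
                                   width = 7, height = NULL) {
  if (!is.null(overlay)) {
    for (lb in names(overlay)) report$dists[[lb]] <- overlay[[lb]]
    # overlays get bands only, no point rows
  }
  pd0 <- variation_plot_data(report, percentiles)
  if (!is.null(overlay)) {
    rows <- lapply(names(report$dists), function(lb) {
      forest_row_band(lb, report$dists[[lb]])
    })
    pdf_all <- forest_plot_data(rows, percentiles)
    pd0$bands <- pdf_all$bands
    pd0$labels <- pdf_all$labels
    # re-anchor point rows to the new y positions
    if (nrow(pd0$points) > 0) {
      ymap <- stats::setNames(rev(seq_along(pd0$labels)), pd0$labels)
      pd0$points$y <- ymap[pd0$points$label]
    }
  }
  g <- render_forest(list(effects = data.frame(label = character(),
                                               y = numeric(),
                                               effect = numeric(),
                                               low = numeric(),
                                               high = numeric()),
                          bands = pd0$bands, labels = pd0$labels),
                     xlab = xlab)
  if (nrow(pd0$points) > 0) {
    has_ci <- !is.na(pd0$points$low)
    if (any(has_ci)) {
      g <- g + ggplot2::geom_errorbarh(
        data = pd0$points[has_ci, ],
        ggplot2::aes(xmin = .data$low, xmax = .data$high,
                     y = .data$y - 0.12),
        height = 0.1, colour = "grey20")
    }
    g <- g + ggplot2::geom_point(
      data = pd0$points,
      ggplot2::aes(x = .data$rem, y = .data$y - 0.12),
      shape = 18, size = 2.5, colour = "grey20")
  }
  if (!is.null(file)) {
    if (is.null(height)) height <- max(2, 0.5 * length(pd0$labels) + 1)
    ggplot2::ggsave(file, g, width = width, height = height)
    return(invisible(g))
  }
  g
}
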