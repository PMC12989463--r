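## Metric performance: regression on the log2 phosphorus gradient, the
## geographic (latitude-longitude) disturbance model, family comparisons by
## ANOVA/Tukey on adjusted R2 and by Kruskal-Wallis on within-group ranks.

#' Regress a metric on the log2 phosphorus gradient
#'
#' Ordinary least squares of the metric on log2(mat P).  Missing pairs are
#' dropped; at least 4 complete pairs are required.
#'
#' @param y metric values per sample.
#' @param mat_p positive per-sample mat P.
#' @return named list `slope`, `adj_r2`, `p`, `n`.
#' @export
fit_metric_gradient <- function(y, mat_p) {
  ok <- !is.na(y) & !is.na(mat_p)
  if (sum(ok) < 4L) stop("need at least 4 paired non-missing observations")
  if (any(mat_p[ok] <= 0)) stop("mat_p must be positive")
  x <- log2(mat_p[ok])
  yy <- y[ok]
  if (stats::sd(yy) == 0)
    return(list(slope = 0, adj_r2 = NA_real_, p = NA_real_, n = sum(ok),
                constant = TRUE))
  fit <- stats::lm(yy ~ x)
  s <- summary(fit)
  list(slope = stats::coef(fit)[["x"]], adj_r2 = s$adj.r.squared,
       p = s$coefficients["x", "Pr(>|t|)"], n = sum(ok), constant = FALSE)
}

#' Adjusted R2 of a latitude-longitude disturbance model
#'
#' OLS of the values on latitude, longitude and their interaction; the
#' geographic surrogate for the human-disturbance gradient.  Both metrics
#' and mat P itself can be scored.
#'
#' @param y values per sample (a metric, or mat P).
#' @param lat,long decimal-degree coordinates.
#' @return adjusted R2 (may be negative), or `NA` on a degenerate
#'   (collinear) design.
#' @export
latlong_model <- function(y, lat, long) {
  ok <- !is.na(y) & !is.na(lat) & !is.na(long)
  if (sum(ok) < 6L) stop("need at least 6 complete cases")
  fit <- stats::lm(y[ok] ~ lat[ok] * long[ok])
  if (any(is.na(stats::coef(fit)))) {
    warning("degenerate lat/long design: adjusted R2 undefined")
    return(NA_real_)
  }
  adj_r2(fit)
}

#' Performance table for a metric matrix
#'
#' Scores every metric against log2(mat P) (slope, adjusted R2, p) and,
#' when coordinates are available, against the latitude-longitude model.
#'
#' @param metrics a `metric_matrix` from [build_metric_matrix()].
#' @param samples sample metadata data frame (columns `sample`, `mat_p`,
#'   optionally `latitude`, `longitude`).
#' @return data frame, one row per metric, with the metric metadata
#'   (`type`, `source`, `trait`) plus `slope`, `adj_r2`, `p`,
#'   `adj_r2_latlong`.
#' @export
evaluate_metrics <- function(metrics, samples) {
  meta <- metric_metadata(metrics)
  samples <- samples[match(metrics$sample, samples$sample), , drop = FALSE]
  has_geo <- all(c("latitude", "longitude") %in% names(samples))
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta$metric[i]
    y <- metrics[[m]]
    fit <- tryCatch(fit_metric_gradient(y, samples$mat_p),
                    error = function(e) list(slope = NA_real_,
                                             adj_r2 = NA_real_,
                                             p = NA_real_, n = NA_integer_))
    ll <- if (has_geo)
      tryCatch(latlong_model(y, samples$latitude, samples$longitude),
               error = function(e) NA_real_)
    else NA_real_
    data.frame(metric = m, type = meta$type[i], source = meta$source[i],
               trait = meta$trait[i], slope = fit$slope,
               adj_r2 = fit$adj_r2, p = fit$p, adj_r2_latlong = ll)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Restrict a performance table to the 24-cell trait-metric factorial.
factorial_rows <- function(perf) {
  perf[!is.na(perf$source) & !is.na(perf$trait), , drop = FALSE]
}

#' One-way ANOVA with Tukey HSD across a metric family factor
#'
#' Compares mean adjusted R2 of the 24 trait metrics grouped by metric
#' `type`, trait `source`, or `trait`.
#'
#' @param perf performance table from [evaluate_metrics()].
#' @param factor one of `"type"`, `"source"`, `"trait"`.
#' @param response column to compare (default `"adj_r2"`).
#' @return list `F`, `p`, `tukey` (data frame of pairwise comparisons with
#'   Tukey-adjusted p), `anova` (the aov fit).
#' @export
family_anova <- function(perf, factor = c("type", "source", "trait"),
                         response = "adj_r2") {
  factor <- match.arg(factor)
  d <- factorial_rows(perf)
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  g <- base::factor(d[[factor]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("factor '", factor, "' has fewer than 2 levels")
  sizes <- table(g)
  if (any(sizes < 2L)) {
    warning("dropping level(s) with < 2 observations: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- g %in% names(sizes)[sizes >= 2L]
    d <- d[keep, , drop = FALSE]
    g <- droplevels(g[keep])
    if (nlevels(g) < 2L) stop("fewer than 2 usable levels")
  }
  fit <- stats::aov(d[[response]] ~ g)
  an <- summary(fit)[[1L]]
  tuk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tuk), tuk, row.names = NULL,
                      check.names = FALSE)
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L], tukey = tukey,
       anova = fit)
}

#' Within-group performance ranks for the three grouping schemes
#'
#' Adds three rank columns to the 24-row factorial performance table,
#' controlling in turn for the other two metric attributes: `rank_type`
#' ranks the 4 calculation types within each source x trait group (1 =
#' lowest adjusted R2), `rank_source` ranks the 3 sources within each type
#' x trait group, and `rank_trait` ranks the 2 traits within each type x
#' source group.  Ties are mid-ranked.
#'
#' @param perf performance table from [evaluate_metrics()].
#' @param response ranked column (default `"adj_r2"`).
#' @return the factorial rows of `perf` with `rank_type`, `rank_source`,
#'   `rank_trait` appended.
#' @export
grouped_ranks <- function(perf, response = "adj_r2") {
  d <- factorial_rows(perf)
  rank_within <- function(by) {
    grp <- interaction(d[by], drop = TRUE)
    out <- rep(NA_real_, nrow(d))
    for (g in levels(grp)) {
      i <- which(grp == g)
      out[i] <- rank(d[[response]][i], ties.method = "average",
                     na.last = "keep")
    }
    out
  }
  d$rank_type <- rank_within(c("source", "trait"))
  d$rank_source <- rank_within(c("type", "trait"))
  d$rank_trait <- rank_within(c("type", "source"))
  d
}

#' Kruskal-Wallis comparison of performance ranks
#'
#' Tests whether one level of a metric attribute consistently ranks higher
#' than the others across the complementary groups.
#'
#' @param ranks output of [grouped_ranks()].
#' @param factor one of `"type"`, `"source"`, `"trait"`; the matching rank
#'   column is used.
#' @return list `H` (chi-squared statistic), `p`, `df`.
#' @export
family_kruskal <- function(ranks, factor = c("type", "source", "trait")) {
  factor <- match.arg(factor)
  col <- paste0("rank_", factor)
  d <- ranks[!is.na(ranks[[col]]), , drop = FALSE]
  g <- droplevels(base::factor(d[[factor]]))
  if (nlevels(g) < 2L) stop("factor '", factor, "' has fewer than 2 levels")
  kt <- stats::kruskal.test(d[[col]], g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}
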