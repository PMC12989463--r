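## Trait assignment along the phosphorus gradient: gradient regression,
## weighted-average optima/tolerances, and merging with literature and
## TITAN trait calls.

#' Taxa observed in at least a minimum number of samples
#'
#' Occurrence filter applied before trait characterization: with fewer than
#' about five occurrences neither regression nor indicator analysis has
#' reasonable power.  The bound is inclusive (a taxon in exactly
#' `min_occurrences` samples is retained).
#'
#' @param counts count matrix (taxa x samples).
#' @param min_occurrences minimum number of samples with a positive count
#'   (default 5).
#' @return character vector of retained taxon ids.
#' @export
occurrence_filter <- function(counts, min_occurrences = 5L) {
  stopifnot(min_occurrences >= 1L)
  occ <- rowSums(counts > 0)
  rownames(counts)[occ >= min_occurrences]
}

## Classify one taxon from its relative abundances along log2 mat P.
## Stage 1: degree-1 fit; a significant slope decides the trait by sign.
## Stage 2: degree-2 fit catches non-linear responses; direction is the sign
## of the fitted change across the observed gradient.  A significant
## quadratic whose fitted end-point change is exactly zero stays unassigned.
classify_taxon_regression <- function(p, logx, alpha = 0.05) {
  if (length(unique(logx)) < 2L) stop("constant gradient: cannot regress")
  fit1 <- stats::lm(p ~ logx)
  s1 <- summary(fit1)
  slope <- stats::coef(fit1)[["logx"]]
  p1 <- s1$coefficients["logx", "Pr(>|t|)"]
  if (is.finite(p1) && p1 <= alpha && slope != 0)
    return(list(trait = if (slope < 0) "lowP" else "highP",
                p_linear = p1, p_poly = NA_real_))
  fit2 <- stats::lm(p ~ logx + I(logx^2))
  f <- summary(fit2)$fstatistic
  p2 <- if (is.null(f)) NA_real_ else
    stats::pf(f[["value"]], f[["numdf"]], f[["dendf"]], lower.tail = FALSE)
  if (is.finite(p2) && p2 <= alpha) {
    ends <- stats::predict(fit2, data.frame(logx = range(logx)))
    d <- ends[2L] - ends[1L]
    if (d != 0)
      return(list(trait = if (d < 0) "lowP" else "highP",
                  p_linear = p1, p_poly = p2))
  }
  list(trait = "unassigned", p_linear = p1, p_poly = p2)
}

#' Assign low-P/high-P traits by regression on the phosphorus gradient
#'
#' For each taxon passing the occurrence filter, fits relative abundance on
#' log2(mat P) with linear then quadratic regression.  A significant linear
#' slope assigns the trait by its sign (negative = lowP, positive = highP);
#' otherwise a significant quadratic assigns it by the sign of the fitted
#' change from the gradient minimum to its maximum; otherwise the taxon is
#' unassigned.
#'
#' @param counts count matrix (taxa x samples); converted internally to
#'   relative abundances.
#' @param mat_p positive per-sample mat P (ug P per g dry mass); samples
#'   with missing mat P are dropped.
#' @param alpha significance level per test (default 0.05).
#' @param min_occurrences occurrence filter threshold (default 5).
#' @return trait table data frame: `taxon`, `source` (`"regression"`),
#'   `trait`, `n_occurrences`, `p_linear`, `p_poly`.  Filtered-out taxa are
#'   included with trait `"unassigned"`.
#' @export
assign_traits_regression <- function(counts, mat_p, alpha = 0.05,
                                     min_occurrences = 5L) {
  keep <- !is.na(mat_p)
  counts <- counts[, keep, drop = FALSE]
  mat_p <- mat_p[keep]
  if (any(mat_p <= 0)) stop("mat_p must be positive")
  logx <- log2(mat_p)
  props <- relative_abundance(counts)
  analyzed <- occurrence_filter(counts, min_occurrences)
  res <- lapply(rownames(counts), function(tx) {
    n_occ <- sum(counts[tx, ] > 0)
    if (!tx %in% analyzed)
      return(data.frame(taxon = tx, source = "regression",
                        trait = "unassigned", n_occurrences = n_occ,
                        p_linear = NA_real_, p_poly = NA_real_))
    cl <- classify_taxon_regression(props[tx, ], logx, alpha)
    data.frame(taxon = tx, source = "regression", trait = cl$trait,
               n_occurrences = n_occ, p_linear = cl$p_linear,
               p_poly = cl$p_poly)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Weighted-average phosphorus optimum and tolerance for one taxon
#'
#' The optimum is the abundance-weighted mean of mat P over samples and the
#' tolerance the abundance-weighted standard deviation:
#' `u = sum(y * x) / sum(y)`, `t = sqrt(sum(y * (x - u)^2) / sum(y))`.
#'
#' @param y non-negative abundances of the taxon per sample (relative
#'   abundances recommended so samples weigh equally).
#' @param x per-sample mat P on the scale the optimum should be reported on.
#' @return named numeric vector `c(optimum, tolerance)`.
#' @export
wa_optimum_tolerance <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (any(y < 0)) stop("abundances must be non-negative")
  w <- sum(y)
  if (w <= 0) stop("all-zero abundance: optimum undefined")
  u <- sum(y * x) / w
  t <- sqrt(sum(y * (x - u)^2) / w)
  c(optimum = u, tolerance = t)
}

#' Weighted-average optima and tolerances for all taxa
#'
#' Computed from relative abundances for every taxon with any occurrence
#' (no occurrence filter: weighted-average inference is most precise with
#' all taxa in the model).  Optima are on raw mat P (ug per g) by default;
#' `log_scale = TRUE` computes them on log2 mat P.
#'
#' @param counts count matrix (taxa x samples).
#' @param mat_p per-sample mat P; missing values drop the sample.
#' @param log_scale logical; compute on log2(mat P) instead of raw.
#' @return data frame: `taxon`, `n_occurrences`, `optimum`, `tolerance`.
#' @export
wa_optima <- function(counts, mat_p, log_scale = FALSE) {
  keep <- !is.na(mat_p)
  counts <- counts[, keep, drop = FALSE]
  x <- if (log_scale) log2(mat_p[keep]) else mat_p[keep]
  props <- relative_abundance(counts)
  res <- lapply(rownames(counts), function(tx) {
    n_occ <- sum(counts[tx, ] > 0)
    if (n_occ == 0L)
      return(data.frame(taxon = tx, n_occurrences = 0L,
                        optimum = NA_real_, tolerance = NA_real_))
    ut <- wa_optimum_tolerance(props[tx, ], x)
    data.frame(taxon = tx, n_occurrences = n_occ,
               optimum = ut[["optimum"]], tolerance = ut[["tolerance"]])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge trait calls from regression, TITAN and literature sources
#'
#' Produces a long trait table with one row per taxon and source over the
#' union of taxa (absent combinations get trait `"unassigned"`), and attaches
#' a disagreement report listing taxa whose assigned traits conflict across
#' sources.
#'
#' @param regression,titan,literature data frames with columns `taxon`,
#'   `trait` and optionally `n_occurrences`, `optimum`, `tolerance`; any may
#'   be `NULL` or empty.
#' @return data frame `taxon`, `source`, `trait`, `n_occurrences` with
#'   attribute `disagreements` (data frame of conflicting taxa in wide form).
#' @export
merge_trait_sources <- function(regression = NULL, titan = NULL,
                                literature = NULL) {
  tabs <- list(regression = regression, titan = titan,
               literature = literature)
  norm <- function(d, src) {
    if (is.null(d) || nrow(d) == 0L)
      return(data.frame(taxon = character(), source = character(),
                        trait = character(), n_occurrences = integer()))
    if (anyDuplicated(d$taxon))
      stop("duplicate (taxon, source) rows in ", src, " table: ",
           paste(unique(d$taxon[duplicated(d$taxon)]), collapse = ", "))
    bad <- !d$trait %in% c("lowP", "highP", "unassigned")
    if (any(bad)) stop("unknown trait value(s): ",
                       paste(unique(d$trait[bad]), collapse = ", "))
    data.frame(taxon = as.character(d$taxon), source = src,
               trait = d$trait,
               n_occurrences = if ("n_occurrences" %in% names(d))
                 d$n_occurrences else NA_integer_)
  }
  long <- do.call(rbind, Map(norm, tabs, names(tabs)))
  taxa <- sort(unique(long$taxon))
  full <- expand.grid(taxon = taxa, source = names(tabs),
                      stringsAsFactors = FALSE)
  out <- merge(full, long, by = c("taxon", "source"), all.x = TRUE)
  out$trait[is.na(out$trait)] <- "unassigned"
  out <- out[order(out$taxon, match(out$source, names(tabs))), ]
  rownames(out) <- NULL

  wide <- stats::reshape(out[, c("taxon", "source", "trait")],
                         idvar = "taxon", timevar = "source",
                         direction = "wide")
  names(wide) <- sub("^trait\\.", "", names(wide))
  assigned <- as.matrix(wide[, -1L, drop = FALSE])
  conflict <- apply(assigned, 1L, function(tr) {
    tr <- tr[tr != "unassigned"]
    length(unique(tr)) > 1L
  })
  dis <- wide[conflict, , drop = FALSE]
  rownames(dis) <- NULL
  if (nrow(dis) > 0L)
    message("trait disagreement across sources for: ",
            paste(dis$taxon, collapse = ", "))
  attr(out, "disagreements") <- dis
  out
}
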