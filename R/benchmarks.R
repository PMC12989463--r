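## Candidate management benchmarks along the mat-P gradient: regression
## tree changepoints with permutation significance, cluster-group
## phosphorus percentiles, and the TITAN community changepoint.

#' Bray-Curtis dissimilarity among samples
#'
#' Computed on relative abundances, so differing count totals do not enter
#' the distances.
#'
#' @param counts count matrix (taxa x samples) or `std_counts` object.
#' @return symmetric sample x sample dissimilarity matrix in `[0, 1]` with
#'   zero diagonal.
#' @export
bray_curtis <- function(counts) {
  props <- relative_abundance(counts)
  as.matrix(vegan::vegdist(t(props), method = "bray"))
}

#' Hierarchical sample groups with per-group phosphorus percentiles
#'
#' Agglomerates samples on a dissimilarity matrix and cuts the tree at a
#' dissimilarity height; reports, per group, the mat P percentiles (50th,
#' 75th, 90th, linearly interpolated) and the mean pairwise within-group
#' dissimilarity.  The 75th percentile of low-P groups is a candidate
#' management benchmark.
#'
#' @param d dissimilarity matrix (as from [bray_curtis()]) or `dist`.
#' @param linkage agglomeration method: `"average"` (UPGMA, default),
#'   `"complete"`, or `"ward"` (ward.D2).
#' @param cut_height dissimilarity level at which to cut (default 0.75).
#' @param mat_p optional per-sample mat P aligned with the matrix order.
#' @return object of class `cluster_result`: `groups` (named integer
#'   vector), `summary` (per-group data frame: size, mean within-group
#'   dissimilarity, mat P percentiles), `tree` (the hclust object),
#'   `cut_height`.
#' @export
hierarchical_groups <- function(d, linkage = c("average", "complete", "ward"),
                                cut_height = 0.75, mat_p = NULL) {
  linkage <- match.arg(linkage)
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(dd, method = method)
  if (cut_height < 0) stop("cut_height must be non-negative")
  ## a cut above the tree top simply leaves one group
  groups <- stats::cutree(tree, h = cut_height)
  dm <- as.matrix(dd)
  rows <- lapply(sort(unique(groups)), function(g) {
    i <- which(groups == g)
    wd <- if (length(i) > 1L) mean(dm[i, i][lower.tri(dm[i, i])]) else NA_real_
    q <- if (!is.null(mat_p)) {
      stats::quantile(mat_p[i], c(0.5, 0.75, 0.9), na.rm = TRUE, type = 7)
    } else rep(NA_real_, 3L)
    data.frame(group = g, n = length(i), mean_within_dissim = wd,
               mat_p_q50 = q[[1L]], mat_p_q75 = q[[2L]], mat_p_q90 = q[[3L]])
  })
  structure(list(groups = groups, summary = do.call(rbind, rows),
                 tree = tree, cut_height = cut_height),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(unique(x$groups)), "groups at height",
      x$cut_height, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

## Best single SSE-minimizing split of y along x (ties in x kept together).
## Returns NULL when no admissible split exists.  O(n log n).
best_split <- function(y, x, min_leaf) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  ux <- unique(xs)
  if (length(ux) < 2L) return(NULL)
  k_all <- cumsum(tabulate(match(xs, ux)))[-length(ux)]
  cp_all <- (ux[-length(ux)] + ux[-1L]) / 2
  ok <- k_all >= min_leaf & (n - k_all) >= min_leaf
  if (!any(ok)) return(NULL)
  k <- k_all[ok]; cp <- cp_all[ok]
  cs <- cumsum(ys)
  tot <- cs[n]
  ## SSE reduction = between-group sum of squares of the split
  reduction <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
  i <- which.max(reduction)
  list(changepoint = cp[i], k = k[i], reduction = reduction[i],
       mean_left = cs[k[i]] / k[i],
       mean_right = (tot - cs[k[i]]) / (n - k[i]),
       left = ord[seq_len(k[i])], right = ord[(k[i] + 1L):n])
}

#' Regression-tree changepoints with permutation significance
#'
#' Recursively splits the gradient to minimize the within-group sum of
#' squared errors of a metric, accepting each split only if its SSE
#' reduction is significant against `n_perm` permutations of the metric
#' values within the node (exceedance p <= `alpha`).  Breakpoints are
#' reported at the midpoint of the straddling gradient values.
#'
#' @param y metric values.
#' @param x mat P values, same length.
#' @param min_leaf minimum samples per side of a split (default 5).
#' @param max_depth maximum recursion depth (default 3).
#' @param n_perm permutations per candidate split (default 999).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed for the permutation streams.
#' @return object of class `changepoint_result`: data frame `breakpoints`
#'   with columns `changepoint`, `p`, `mean_left`, `mean_right`,
#'   `sse_reduction`, ordered by changepoint (zero rows when no
#'   significant split exists).
#' @export
tree_changepoints <- function(y, x, min_leaf = 5L, max_depth = 3L,
                              n_perm = 999L, alpha = 0.01, seed = 1L) {
  stopifnot(length(y) == length(x))
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 2L * min_leaf)
    stop("need at least 2 * min_leaf observations")
  acc <- list()
  node_id <- 0L
  recurse <- function(idx, depth) {
    if (depth > max_depth || length(idx) < 2L * min_leaf) return()
    sp <- best_split(y[idx], x[idx], min_leaf)
    if (is.null(sp) || sp$reduction <= 0) return()
    node_id <<- node_id + 1L
    pval <- with_seed(derive_seed(seed, "treeperm", node_id), {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        spb <- best_split(sample(y[idx]), x[idx], min_leaf)
        if (!is.null(spb) && spb$reduction >= sp$reduction)
          exceed <- exceed + 1L
      }
      (1 + exceed) / (n_perm + 1)
    })
    if (pval > alpha) return()
    acc[[length(acc) + 1L]] <<- data.frame(
      changepoint = sp$changepoint, p = pval, mean_left = sp$mean_left,
      mean_right = sp$mean_right, sse_reduction = sp$reduction)
    recurse(idx[sp$left], depth + 1L)
    recurse(idx[sp$right], depth + 1L)
  }
  recurse(seq_along(y), 1L)
  bp <- if (length(acc)) do.call(rbind, acc) else
    data.frame(changepoint = numeric(0), p = numeric(0),
               mean_left = numeric(0), mean_right = numeric(0),
               sse_reduction = numeric(0))
  bp <- bp[order(bp$changepoint), , drop = FALSE]
  rownames(bp) <- NULL
  structure(list(breakpoints = bp, alpha = alpha, n = length(y)),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat("changepoint_result:", nrow(x$breakpoints),
      "significant breakpoint(s) at alpha =", x$alpha, "\n")
  if (nrow(x$breakpoints)) print(x$breakpoints, row.names = FALSE)
  invisible(x)
}

#' Candidate benchmark table across the three derivation methods
#'
#' Assembles one table of candidate mat P benchmarks: regression-tree
#' changepoints for each metric of the benchmark subset (diversity, WAM and
#' TITAN-trait metrics), cluster-group mat P percentiles for low-P groups,
#' the TITAN community sum(z-) changepoint, and percentiles of mat P within
#' user-designated minimally disturbed regions.
#'
#' @param metrics a `metric_matrix`.
#' @param samples sample metadata (needs `sample`, `mat_p`; `region` used
#'   for the minimally disturbed summary).
#' @param titan_profile optional `community_profile`.
#' @param cluster_result optional `cluster_result` built with mat P.
#' @param reference_regions optional character vector of region codes
#'   treated as minimally disturbed.
#' @param tree_args list of arguments forwarded to [tree_changepoints()].
#' @return list of class `benchmark_report`: `table` (data frame `method`,
#'   `item`, `benchmark`, `detail`), `metrics_evaluated` (the benchmark
#'   subset names), `reference_summary`.
#' @export
benchmark_report <- function(metrics, samples, titan_profile = NULL,
                             cluster_result = NULL,
                             reference_regions = NULL,
                             tree_args = list()) {
  samples <- samples[match(metrics$sample, samples$sample), , drop = FALSE]
  subset <- benchmark_metric_subset(metrics)
  rows <- list()
  for (m in subset) {
    cp <- tryCatch(
      do.call(tree_changepoints,
              c(list(y = metrics[[m]], x = samples$mat_p), tree_args)),
      error = function(e) NULL)
    if (is.null(cp)) next
    for (i in seq_len(nrow(cp$breakpoints)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = "tree", item = m,
        benchmark = cp$breakpoints$changepoint[i],
        detail = sprintf("p=%.4g", cp$breakpoints$p[i]))
  }
  if (!is.null(cluster_result)) {
    s <- cluster_result$summary
    low <- s[order(s$mat_p_q50), , drop = FALSE]
    for (i in seq_len(nrow(low)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = "cluster", item = paste0("group_", low$group[i]),
        benchmark = low$mat_p_q75[i],
        detail = sprintf("n=%d, q90=%.4g", low$n[i], low$mat_p_q90[i]))
  }
  if (!is.null(titan_profile)) {
    rows[[length(rows) + 1L]] <- data.frame(
      method = "titan", item = "community_z-",
      benchmark = unname(titan_profile$changepoint["z-"]),
      detail = sprintf("%d taxa", length(titan_profile$taxa_used[["z-"]])))
  }
  ref <- NULL
  if (!is.null(reference_regions) && "region" %in% names(samples)) {
    p <- samples$mat_p[samples$region %in% reference_regions]
    p <- p[!is.na(p)]
    if (length(p)) {
      q <- stats::quantile(p, c(0.5, 0.75, 0.9), type = 7)
      ref <- data.frame(n = length(p), q50 = q[[1L]], q75 = q[[2L]],
                        q90 = q[[3L]])
      rows[[length(rows) + 1L]] <- data.frame(
        method = "reference_percentile", item = "minimally_disturbed",
        benchmark = q[[2L]],
        detail = sprintf("q50=%.4g, q90=%.4g, n=%d", q[[1L]], q[[3L]],
                         length(p)))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), item = character(0),
               benchmark = numeric(0), detail = character(0))
  rownames(tab) <- NULL
  structure(list(table = tab, metrics_evaluated = subset,
                 reference_summary = ref),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", length(x$metrics_evaluated),
      "metrics evaluated;", nrow(x$table), "candidate benchmark(s)\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
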