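## Counting-effort standardization (rarefaction to a fixed valve count) and
## relative abundances.

#' Rarefy one sample's counts to a fixed valve effort
#'
#' Subsamples exactly `target` valves uniformly without replacement, the
#' same operation as ranking every counted valve by a random number and
#' keeping the lowest `target`.  Samples already at or under the target are
#' returned unchanged and flagged.
#'
#' @param y named non-negative integer vector of valve counts for one sample.
#' @param target integer valve effort (default 600).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return integer vector like `y` with attribute `under_target` (logical).
#' @export
rarefy_sample <- function(y, target = 600L, seed = NULL) {
  if (length(target) != 1L || target < 1L) stop("target must be >= 1")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  total <- sum(y)
  if (total <= target) {
    if (total < target)
      warning("sample total ", total, " is under the target of ", target,
              "; returned unchanged")
    out <- as.integer(y)
    names(out) <- names(y)
    attr(out, "under_target") <- total < target
    return(out)
  }
  draw <- function() {
    valves <- rep.int(seq_along(y), y)     # one entry per physical valve
    kept <- sample(valves, target)         # uniform, without replacement
    tabulate(kept, nbins = length(y))
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- as.integer(out)
  names(out) <- names(y)
  attr(out, "under_target") <- FALSE
  out
}

#' Rarefy every sample of a count matrix to a fixed effort
#'
#' @param counts validated count matrix (taxa x samples).
#' @param target integer valve effort per sample (default 600).
#' @param seed integer master seed; each sample uses its own derived
#'   substream so results do not depend on column order processing.
#' @return object of class `std_counts`: list with `counts` (rarefied
#'   matrix), `original_totals`, `target` and `under_target` (logical per
#'   sample).
#' @export
rarefy_matrix <- function(counts, target = 600L, seed = 1L) {
  validate_count_matrix(counts)
  totals <- colSums(counts)
  out <- counts
  under <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    yj <- suppressWarnings(
      rarefy_sample(counts[, j], target,
                    seed = derive_seed(seed, "rarefy", j)))
    out[, j] <- yj
    under[j] <- attr(yj, "under_target")
  }
  if (any(under))
    warning(sum(under), " sample(s) under the ", target,
            "-valve target were kept unchanged")
  names(under) <- colnames(counts)
  structure(list(counts = out, original_totals = totals, target = target,
                 under_target = under),
            class = "std_counts")
}

#' @export
print.std_counts <- function(x, ...) {
  cat("std_counts:", ncol(x$counts), "samples standardized to",
      x$target, "valves;", sum(x$under_target), "under target\n")
  invisible(x)
}

#' Relative abundances per sample
#'
#' @param counts count matrix (taxa x samples) or a `std_counts` object.
#' @return matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(counts) {
  if (inherits(counts, "std_counts")) counts <- counts$counts
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("empty sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2L, totals, "/")
}
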