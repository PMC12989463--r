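## Shared fixtures and independent brute-force oracles.  The oracles are
## written as plain loops over the definitions, deliberately sharing no
## code with the package internals they check.

make_counts <- function() {
  m <- matrix(c(10L, 0L,
                5L,  5L,
                0L, 20L), nrow = 3, byrow = TRUE,
              dimnames = list(c("taxA", "taxB", "taxC"), c("s1", "s2")))
  m
}

rand_counts <- function(n_taxa = 8, n_samples = 6, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

## Dufrene-Legendre indicator values, computed directly from the defining
## quantities: group mean abundances and occurrence frequencies.
oracle_indval <- function(y, g) {
  mean_in <- mean(y[g]); mean_out <- mean(y[!g])
  a_in <- if (mean_in + mean_out > 0) mean_in / (mean_in + mean_out) else 0
  b_in <- sum(y[g] > 0) / sum(g)
  b_out <- sum(y[!g] > 0) / sum(!g)
  c(left = 100 * a_in * b_in, right = 100 * (1 - a_in) * b_out)
}

## Exhaustive scan of every admissible gradient split (ties kept on one
## side), scoring both sides with oracle_indval.
oracle_iv_scan <- function(y, x, min_split = 5) {
  ux <- sort(unique(x))
  rows <- NULL
  for (i in seq_len(length(ux) - 1)) {
    g <- x <= ux[i]
    if (sum(g) < min_split || sum(!g) < min_split) next
    iv <- oracle_indval(y, g)
    rows <- rbind(rows, data.frame(changepoint = (ux[i] + ux[i + 1]) / 2,
                                   left = iv["left"], right = iv["right"],
                                   iv_max = max(iv)))
  }
  rows
}

## Exhaustive best SSE-reducing single split.
oracle_best_sse <- function(y, x, min_leaf = 5) {
  ux <- sort(unique(x))
  best <- NULL
  sse <- function(v) sum((v - mean(v))^2)
  for (i in seq_len(length(ux) - 1)) {
    g <- x <= ux[i]
    if (sum(g) < min_leaf || sum(!g) < min_leaf) next
    red <- sse(y) - sse(y[g]) - sse(y[!g])
    if (is.null(best) || red > best$reduction)
      best <- list(changepoint = (ux[i] + ux[i + 1]) / 2, reduction = red)
  }
  best
}

## A tiny trait table in the merged long format.
make_trait_map <- function() {
  c(taxA = "lowP", taxB = "highP", taxC = "unassigned")
}
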