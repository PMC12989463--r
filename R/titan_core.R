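## Threshold indicator taxa analysis (TITAN): per-taxon indicator-value
## changepoints standardized as permutation z-scores, bootstrap
## purity/reliability, and community sum(z) profiles.

#' Dufrene-Legendre indicator value for a binary partition
#'
#' Specificity is the group mean abundance over the sum of the two group
#' means; fidelity is the fraction of the group's samples in which the
#' taxon occurs; their product scaled to 0-100 is the indicator value.
#'
#' @param y non-negative abundance vector.
#' @param g logical vector, `TRUE` for the first (left) group; both groups
#'   must be non-empty.
#' @return named numeric vector `c(left, right)`, each in `[0, 100]`.
#' @export
indval <- function(y, g) {
  stopifnot(length(y) == length(g), is.logical(g))
  if (!any(g) || all(g)) stop("both groups must be non-empty")
  if (all(y == 0)) {
    warning("all-zero abundance: indicator values are 0")
    return(c(left = 0, right = 0))
  }
  mL <- mean(y[g]); mR <- mean(y[!g])
  A_L <- if (mL + mR > 0) mL / (mL + mR) else 0
  B_L <- mean(y[g] > 0); B_R <- mean(y[!g] > 0)
  c(left = 100 * A_L * B_L, right = 100 * (1 - A_L) * B_R)
}

## Candidate changepoints along x with ties kept together: a threshold on a
## measured gradient cannot separate equal values.  Returns left-group
## sample counts `k` at each admissible boundary and the midpoint
## changepoint values.
titan_candidates <- function(x, min_split) {
  n <- length(x)
  xs <- sort(x)
  ux <- unique(xs)
  if (length(ux) < 2L) stop("constant gradient: no candidate changepoints")
  k_all <- cumsum(tabulate(match(xs, ux)))[-length(ux)]
  cp_all <- (ux[-length(ux)] + ux[-1L]) / 2
  ok <- k_all >= min_split & (n - k_all) >= min_split
  list(k = k_all[ok], changepoint = cp_all[ok])
}

## Indicator-value profile over all candidate left sizes `k` for a vector
## `ys` already sorted by the gradient.  O(n + K) via cumulative sums.
iv_profile <- function(ys, k) {
  n <- length(ys)
  cs <- cumsum(ys); csp <- cumsum(ys > 0)
  tot <- cs[n]; totp <- csp[n]
  mL <- cs[k] / k
  mR <- (tot - cs[k]) / (n - k)
  denom <- mL + mR
  A_L <- ifelse(denom > 0, mL / denom, 0)
  B_L <- csp[k] / k
  B_R <- (totp - csp[k]) / (n - k)
  cbind(left = 100 * A_L * B_L, right = 100 * (1 - A_L) * B_R)
}

#' TITAN changepoint analysis for one taxon
#'
#' Scans every admissible split of the gradient, scores the taxon's
#' indicator value on each side, standardizes the larger one as a z score
#' against `n_perm` random permutations of the sample-group association,
#' and selects the split maximizing z (or raw indicator value with
#' `select_by = "indval"`).  The response direction is `"z-"` when the
#' indicator side is the low-gradient group (a decreaser / low-P taxon) and
#' `"z+"` otherwise.  The permutation p is a maximum-statistic exceedance
#' probability -- the observed candidate-wise maximum indicator value
#' against the permutation distribution of that maximum -- so the
#' taxon-level test stays calibrated despite changepoint selection.
#'
#' @param y non-negative abundance vector (relative abundances recommended).
#' @param x gradient values, same length.
#' @param n_perm number of permutations (default 250).
#' @param min_split minimum samples on each side of a split (default 5).
#' @param seed optional integer seed for the permutation stream.
#' @param select_by `"z"` (default, the reference behaviour) or `"indval"`.
#' @return object of class `titan_taxon`: list with `direction`,
#'   `changepoint`, `indval`, `z`, `p`, and per-candidate vectors
#'   `candidates`, `iv_obs`, `z_profile`, `side`.
#' @export
titan_taxon <- function(y, x, n_perm = 250L, min_split = 5L, seed = NULL,
                        select_by = c("z", "indval")) {
  select_by <- match.arg(select_by)
  stopifnot(length(y) == length(x))
  n <- length(y)
  if (n < 2L * min_split)
    stop("need at least 2 * min_split = ", 2L * min_split, " samples")
  if (sum(y > 0) < min_split)
    stop("taxon occurs in fewer than min_split = ", min_split, " samples")
  ord <- order(x)
  ys <- y[ord]
  cand <- titan_candidates(x, min_split)
  K <- length(cand$k)
  obs <- iv_profile(ys, cand$k)
  iv_obs <- pmax(obs[, "left"], obs[, "right"])
  side <- ifelse(obs[, "left"] >= obs[, "right"], "left", "right")

  perm_iv <- with_seed(seed, {
    m <- matrix(0, n_perm, K)
    for (b in seq_len(n_perm)) {
      pr <- iv_profile(sample(ys), cand$k)
      m[b, ] <- pmax(pr[, "left"], pr[, "right"])
    }
    m
  })
  mu <- colMeans(perm_iv)
  sdv <- apply(perm_iv, 2L, stats::sd)
  z <- ifelse(sdv > 0, (iv_obs - mu) / sdv, 0)

  k_star <- if (select_by == "z") which.max(z) else which.max(iv_obs)
  ## maximum-statistic permutation p: observed candidate-wise maximum
  ## indicator value against the permutation distribution of the same
  ## maximum.  A per-candidate exceedance p at the selected candidate
  ## would be anti-conservative (the candidate is chosen for extremeness);
  ## the max-statistic test is exactly calibrated under the null.
  perm_max <- apply(perm_iv, 1L, max)
  p <- (1 + sum(perm_max >= max(iv_obs))) / (n_perm + 1)
  structure(list(
    direction = if (side[k_star] == "left") "z-" else "z+",
    changepoint = cand$changepoint[k_star],
    indval = iv_obs[k_star],
    z = z[k_star],
    p = p,
    candidates = cand$changepoint,
    iv_obs = iv_obs,
    z_profile = z,
    side = side
  ), class = "titan_taxon")
}

#' @export
print.titan_taxon <- function(x, ...) {
  cat(sprintf("titan_taxon: direction %s, changepoint %.4g, IndVal %.1f, z %.2f, p %.4g\n",
              x$direction, x$changepoint, x$indval, x$z, x$p))
  invisible(x)
}

#' Bootstrap purity, reliability and changepoint quantiles for one taxon
#'
#' Resamples the samples with replacement `n_boot` times and reruns
#' [titan_taxon()] on each replicate.  Purity is the fraction of replicates
#' agreeing with the observed response direction; reliability the fraction
#' with permutation p <= `p_level`.  Replicates in which the taxon falls
#' under `min_split` occurrences are redrawn (up to 10 attempts, then
#' counted as failures).
#'
#' @inheritParams titan_taxon
#' @param n_boot number of bootstrap replicates (default 500).
#' @param p_level significance level used for reliability (default 0.05).
#' @return list: `purity`, `reliability`, `quantiles` (0.05, 0.25, 0.5,
#'   0.75, 0.95 of bootstrap changepoints), `boot_changepoints`,
#'   `n_failed`.
#' @export
titan_bootstrap <- function(y, x, n_boot = 500L, n_perm = 250L,
                            min_split = 5L, seed = NULL, p_level = 0.05) {
  obs <- titan_taxon(y, x, n_perm = n_perm, min_split = min_split,
                     seed = if (is.null(seed)) NULL
                            else derive_seed(seed, "boot:obs"))
  n <- length(y)
  dirs <- character(n_boot)
  ps <- numeric(n_boot)
  cps <- numeric(n_boot)
  failed <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    bseed <- if (is.null(seed)) NULL else derive_seed(seed, "boot", b)
    rep_res <- with_seed(bseed, {
      res <- NULL
      for (attempt in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(y[idx] > 0) < min_split ||
            length(unique(x[idx])) < 2L) next
        cand_ok <- tryCatch(
          length(titan_candidates(x[idx], min_split)$k) >= 1L,
          error = function(e) FALSE)
        if (!cand_ok) next
        res <- titan_taxon(y[idx], x[idx], n_perm = n_perm,
                           min_split = min_split)
        break
      }
      res
    })
    if (is.null(rep_res)) {
      failed[b] <- TRUE
      dirs[b] <- NA_character_; ps[b] <- NA_real_; cps[b] <- NA_real_
    } else {
      dirs[b] <- rep_res$direction
      ps[b] <- rep_res$p
      cps[b] <- rep_res$changepoint
    }
  }
  if (any(failed))
    message(sum(failed), " bootstrap replicate(s) failed after 10 redraws")
  ok <- !failed
  list(purity = mean(dirs[ok] == obs$direction),
       reliability = mean(ps[ok] <= p_level),
       quantiles = stats::quantile(cps[ok],
                                   c(0.05, 0.25, 0.5, 0.75, 0.95),
                                   names = TRUE),
       boot_changepoints = cps[ok],
       n_failed = sum(failed),
       observed = obs)
}

#' TITAN over all eligible taxa of an assemblage
#'
#' Runs [titan_taxon()] and [titan_bootstrap()] for every taxon passing the
#' occurrence filter, on relative abundances against mat P.
#'
#' @param counts count matrix (taxa x samples).
#' @param mat_p per-sample mat P; samples with missing values are dropped.
#' @param n_perm permutations per taxon (default 250).
#' @param n_boot bootstrap replicates per taxon (default 500; 0 skips the
#'   bootstrap, leaving purity/reliability `NA`).
#' @param min_split minimum group size (default 5).
#' @param min_occurrences occurrence filter (default 5).
#' @param seed integer master seed; each taxon gets derived substreams.
#' @return object of class `titan_result`: list with `taxa` (per-taxon data
#'   frame), `z_profiles` (taxa x candidates matrix), `candidates`,
#'   `abundance` and `mat_p` (kept for community bootstrapping), and the
#'   call parameters.
#' @export
titan_assemblage <- function(counts, mat_p, n_perm = 250L, n_boot = 500L,
                             min_split = 5L, min_occurrences = 5L,
                             seed = 1L) {
  keep <- !is.na(mat_p)
  counts <- counts[, keep, drop = FALSE]
  x <- mat_p[keep]
  taxa <- occurrence_filter(counts, max(min_occurrences, min_split))
  if (length(taxa) == 0L) stop("no taxa pass the occurrence filter")
  props <- relative_abundance(counts)
  cand <- titan_candidates(x, min_split)
  zmat <- matrix(NA_real_, length(taxa), length(cand$k),
                 dimnames = list(taxa, NULL))
  rows <- vector("list", length(taxa))
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    ## one shared permutation stream: the sample-gradient association is
    ## permuted identically for every taxon (identical taxa then receive
    ## identical z profiles, and community sums are coherent)
    tt <- titan_taxon(props[tx, ], x, n_perm = n_perm,
                      min_split = min_split,
                      seed = derive_seed(seed, "titan:perm"))
    zmat[i, ] <- tt$z_profile
    pur <- rel <- NA_real_
    q <- rep(NA_real_, 5L)
    if (n_boot > 0L) {
      bt <- titan_bootstrap(props[tx, ], x, n_boot = n_boot,
                            n_perm = n_perm, min_split = min_split,
                            seed = derive_seed(seed, paste0("boot:", tx)))
      pur <- bt$purity; rel <- bt$reliability; q <- unname(bt$quantiles)
    }
    rows[[i]] <- data.frame(
      taxon = tx, direction = tt$direction, changepoint = tt$changepoint,
      indval = tt$indval, z = tt$z, p = tt$p,
      purity = pur, reliability = rel,
      cp_q05 = q[1L], cp_q25 = q[2L], cp_q50 = q[3L],
      cp_q75 = q[4L], cp_q95 = q[5L])
  }
  taxa_df <- do.call(rbind, rows)
  rownames(taxa_df) <- NULL
  structure(list(taxa = taxa_df, z_profiles = zmat,
                 candidates = cand$changepoint, k = cand$k,
                 abundance = props[taxa, , drop = FALSE], mat_p = x,
                 n_perm = n_perm, n_boot = n_boot, min_split = min_split,
                 seed = seed),
            class = "titan_result")
}

#' @export
print.titan_result <- function(x, ...) {
  cat("titan_result:", nrow(x$taxa), "taxa,", length(x$candidates),
      "candidate changepoints\n")
  tab <- table(x$taxa$direction)
  cat("  directions:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Community sum(z) profile and community changepoints
#'
#' Sums the per-candidate z scores (negative z truncated at zero: a
#' below-null association carries no indicator evidence) over taxa passing
#' the purity and reliability filters, separately for decreasers (z-) and
#' increasers (z+).  The community changepoint per direction is the
#' candidate maximizing the sum.  Optionally bootstraps the community
#' changepoints by resampling samples and recomputing the filtered-sum
#' argmax, yielding cumulative frequency curves.
#'
#' @param result a `titan_result` from [titan_assemblage()].
#' @param purity_min,reliability_min bootstrap filters (defaults 0.95); taxa
#'   with `NA` purity/reliability (bootstrap skipped) pass when both limits
#'   are 0.
#' @param n_boot community bootstrap replicates (default 0 = skip).
#' @param n_perm permutations per taxon inside the community bootstrap
#'   (default 50, lighter than the observed analysis).
#' @param seed integer seed for the community bootstrap.
#' @return object of class `community_profile`: `candidates`, `sum_z` (two
#'   rows `z-`/`z+`), `changepoint` (named per direction), `taxa_used`, and
#'   when bootstrapped `boot_cdf` (per direction: candidate grid and
#'   nondecreasing cumulative frequencies).
#' @export
community_profile <- function(result, purity_min = 0.95,
                              reliability_min = 0.95, n_boot = 0L,
                              n_perm = 50L, seed = 1L) {
  stopifnot(inherits(result, "titan_result"))
  td <- result$taxa
  passes <- (is.na(td$purity) & purity_min <= 0 |
               (!is.na(td$purity) & td$purity >= purity_min)) &
            (is.na(td$reliability) & reliability_min <= 0 |
               (!is.na(td$reliability) & td$reliability >= reliability_min))
  sum_z <- matrix(0, 2L, length(result$candidates),
                  dimnames = list(c("z-", "z+"), NULL))
  changepoint <- c("z-" = NA_real_, "z+" = NA_real_)
  taxa_used <- list()
  for (dir in c("z-", "z+")) {
    sel <- passes & td$direction == dir
    taxa_used[[dir]] <- td$taxon[sel]
    if (!any(sel)) {
      warning("no taxa pass filters for direction ", dir)
      next
    }
    zsub <- result$z_profiles[td$taxon[sel], , drop = FALSE]
    sum_z[dir, ] <- colSums(pmax(zsub, 0))
    changepoint[dir] <- result$candidates[which.max(sum_z[dir, ])]
  }

  boot_cdf <- NULL
  if (n_boot > 0L) {
    x <- result$mat_p
    props <- result$abundance
    n <- length(x)
    boot_cp <- list("z-" = numeric(0), "z+" = numeric(0))
    for (b in seq_len(n_boot)) {
      cp_b <- with_seed(derive_seed(seed, "commboot", b), {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]
        out <- c("z-" = NA_real_, "z+" = NA_real_)
        cand_b <- tryCatch(titan_candidates(xb, result$min_split),
                           error = function(e) NULL)
        if (!is.null(cand_b) && length(cand_b$k) >= 1L) {
          for (dir in c("z-", "z+")) {
            taxa_d <- taxa_used[[dir]]
            taxa_d <- taxa_d[rowSums(props[taxa_d, idx, drop = FALSE] > 0) >=
                               result$min_split]
            if (length(taxa_d) == 0L) next
            zsum <- numeric(length(cand_b$k))
            for (tx in taxa_d) {
              tt <- tryCatch(
                titan_taxon(props[tx, idx], xb, n_perm = n_perm,
                            min_split = result$min_split),
                error = function(e) NULL)
              if (!is.null(tt)) zsum <- zsum + pmax(tt$z_profile, 0)
            }
            out[dir] <- cand_b$changepoint[which.max(zsum)]
          }
        }
        out
      })
      for (dir in c("z-", "z+"))
        if (!is.na(cp_b[dir])) boot_cp[[dir]] <- c(boot_cp[[dir]], cp_b[dir])
    }
    boot_cdf <- lapply(boot_cp, function(cp) {
      if (length(cp) == 0L) return(NULL)
      grid <- sort(unique(c(result$candidates, cp)))
      list(grid = grid,
           cumfreq = stats::ecdf(cp)(grid))
    })
  }

  structure(list(candidates = result$candidates, sum_z = sum_z,
                 changepoint = changepoint, taxa_used = taxa_used,
                 boot_cdf = boot_cdf),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("community_profile:\n")
  for (dir in c("z-", "z+"))
    cat(sprintf("  %s: %d taxa, changepoint %.4g\n", dir,
                length(x$taxa_used[[dir]]), x$changepoint[dir]))
  invisible(x)
}

#' Trait table rows from TITAN results
#'
#' Decreasers (z-) passing the purity and reliability filters are low-P
#' taxa, increasers (z+) high-P; all others are unassigned.
#'
#' @param result a `titan_result`.
#' @param purity_min,reliability_min filters (defaults 0.95); set both to 0
#'   to assign every analyzed taxon.
#' @return trait table data frame: `taxon`, `source` (`"titan"`), `trait`,
#'   `n_occurrences`.
#' @export
traits_from_titan <- function(result, purity_min = 0.95,
                              reliability_min = 0.95) {
  stopifnot(inherits(result, "titan_result"))
  td <- result$taxa
  passes <- (is.na(td$purity) & purity_min <= 0 |
               (!is.na(td$purity) & td$purity >= purity_min)) &
            (is.na(td$reliability) & reliability_min <= 0 |
               (!is.na(td$reliability) & td$reliability >= reliability_min))
  trait <- ifelse(!passes, "unassigned",
                  ifelse(td$direction == "z-", "lowP", "highP"))
  occ <- rowSums(result$abundance[td$taxon, , drop = FALSE] > 0)
  data.frame(taxon = td$taxon, source = "titan", trait = trait,
             n_occurrences = as.integer(occ))
}
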