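## The metric suite: four trait-metric calculation types (PropValves,
## PropTaxa, noTaxa, RlogA) x three trait sources x two traits, plus three
## diversity metrics and two weighted-average inferred-P metrics.

## Trait lookup for one source: named character vector taxon -> trait.
trait_map_for_source <- function(trait_table, source) {
  rows <- trait_table[trait_table$source == source, , drop = FALSE]
  stats::setNames(rows$trait, rows$taxon)
}

#' Simple trait metrics for one sample
#'
#' For one sample and one trait source computes, per trait t, the
#' proportion of valves `PropValves = sum(v_t) / V`, the proportion of taxa
#' `PropTaxa = t_t / T`, and the number of taxa `noTaxa = t_t`, where the
#' denominators `V` and `T` count only valves/taxa of trait-assigned taxa
#' present in the sample.  With no trait-assigned taxon present the
#' proportions are `NA` (with a warning) and noTaxa is 0.
#'
#' @param y named count vector for one sample.
#' @param trait_map named character vector taxon -> trait
#'   (`lowP`/`highP`/`unassigned`).
#' @param include_unassigned logical; when `TRUE` the denominators include
#'   all present taxa (sensitivity analysis), not only trait-assigned ones.
#' @return named numeric vector `PropValves_lowP`, `PropValves_highP`,
#'   `PropTaxa_lowP`, `PropTaxa_highP`, `noTaxa_lowP`, `noTaxa_highP`.
#' @export
simple_trait_metrics <- function(y, trait_map, include_unassigned = FALSE) {
  tr <- trait_map[names(y)]
  tr[is.na(tr)] <- "unassigned"
  present <- y > 0
  assigned <- tr %in% c("lowP", "highP")
  denom_set <- present & (assigned | include_unassigned)
  out <- c(PropValves_lowP = NA_real_, PropValves_highP = NA_real_,
           PropTaxa_lowP = NA_real_, PropTaxa_highP = NA_real_,
           noTaxa_lowP = sum(present & tr == "lowP"),
           noTaxa_highP = sum(present & tr == "highP"))
  if (!any(present & assigned)) {
    warning("no trait-assigned taxa present: proportions undefined")
    return(out)
  }
  V <- sum(y[denom_set])
  Tn <- sum(denom_set)
  for (t in c("lowP", "highP")) {
    sel <- present & tr == t
    out[paste0("PropValves_", t)] <- sum(y[sel]) / V
    out[paste0("PropTaxa_", t)] <- sum(sel) / Tn
  }
  out
}

#' Relative log-abundance (RlogA) metric for one sample
#'
#' Down-weights abundant taxa by working on the natural-log scale: each
#' trait-assigned present taxon i contributes `RlogA_i = log(A_i) /
#' sum(log(A))` over trait-assigned taxa, and the sample's metric for trait
#' t is `sum over taxa with trait t of RlogA_i / sum over all assigned taxa
#' of RlogA_i`, which reduces algebraically to the ratio of log-count sums.
#' A taxon counted once contributes `log(1) = 0` weight by construction --
#' the literal formula is kept, with no +1 shift.  When every assigned
#' taxon present has count <= 1 the denominator is zero and the metric is
#' `NA` with a warning.
#'
#' @param y named count vector for one sample.
#' @param trait_map named character vector taxon -> trait.
#' @return named numeric vector `RlogA_lowP`, `RlogA_highP`.
#' @export
rloga_metric <- function(y, trait_map) {
  tr <- trait_map[names(y)]
  tr[is.na(tr)] <- "unassigned"
  sel <- y > 0 & tr %in% c("lowP", "highP")
  denom <- sum(log(y[sel]))
  if (!any(sel) || denom <= 0) {
    warning("RlogA denominator is zero (no assigned taxon with count >= 2)")
    return(c(RlogA_lowP = NA_real_, RlogA_highP = NA_real_))
  }
  ## literal double ratio: per-taxon shares first, then the trait sum over
  ## the share total
  shares <- log(y[sel]) / denom
  c(RlogA_lowP = sum(shares[tr[sel] == "lowP"]) / sum(shares),
    RlogA_highP = sum(shares[tr[sel] == "highP"]) / sum(shares))
}

#' Diversity metrics for one sample
#'
#' Richness is the number of taxa present in the standardized count;
#' Shannon diversity uses natural logs; Pielou's evenness is `H / log(S)`
#' (undefined for a single-taxon sample).
#'
#' @param y count vector for one sample with positive total.
#' @return named numeric vector `richness`, `shannon`, `evenness`.
#' @export
diversity_metrics <- function(y) {
  if (sum(y) <= 0) stop("empty sample")
  S <- sum(y > 0)
  H <- vegan::diversity(y, index = "shannon")
  J <- if (S > 1L) H / log(S) else NA_real_
  c(richness = S, shannon = unname(H), evenness = unname(J))
}

#' Weighted-average inferred mat P for one sample
#'
#' The simple variant infers the stressor as the abundance-weighted mean of
#' the present taxa's optima; the tolerance-downweighted variant weights
#' each taxon by `y / t^2` so narrow-niche taxa count more.  Taxa with zero
#' tolerance are given the smallest positive tolerance observed.
#'
#' @param y named abundance vector for one sample.
#' @param optima data frame `taxon`, `optimum`, `tolerance` (as from
#'   [wa_optima()]).
#' @param variant `"simple"` or `"tol"`.
#' @return inferred mat P (same units as the optima), or `NA` when no
#'   present taxon has an optimum.
#' @export
wam_infer <- function(y, optima, variant = c("simple", "tol")) {
  variant <- match.arg(variant)
  u <- stats::setNames(optima$optimum, optima$taxon)[names(y)]
  tl <- stats::setNames(optima$tolerance, optima$taxon)[names(y)]
  sel <- y > 0 & !is.na(u)
  if (!any(sel)) return(NA_real_)
  w <- y[sel]
  if (variant == "tol") {
    t2 <- tl[sel]
    pos <- t2[!is.na(t2) & t2 > 0]
    floor_t <- if (length(pos)) min(pos) else 1
    t2[is.na(t2) | t2 <= 0] <- floor_t
    w <- w / t2^2
  }
  sum(w * u[sel]) / sum(w)
}

#' Build the full per-sample metric matrix
#'
#' Computes the 24 trait metrics (4 types x 3 sources x 2 traits), the 3
#' diversity metrics and the 2 weighted-average metrics -- 29 columns --
#' for every sample of a standardized count matrix.
#'
#' @param std counts as a `std_counts` object from [rarefy_matrix()] or a
#'   plain count matrix.
#' @param trait_table long trait table (`taxon`, `source`, `trait`) as from
#'   [merge_trait_sources()].
#' @param optima optima table as from [wa_optima()].
#' @param include_unassigned passed to [simple_trait_metrics()].
#' @return object of class `metric_matrix`: data frame with a `sample`
#'   column and 29 metric columns, and attribute `metadata` (data frame
#'   `metric`, `type`, `source`, `trait`).
#' @export
build_metric_matrix <- function(std, trait_table, optima,
                                include_unassigned = FALSE) {
  counts <- if (inherits(std, "std_counts")) std$counts else std
  sources <- c("literature", "regression", "titan")
  types <- c("PropValves", "PropTaxa", "noTaxa", "RlogA")
  traits <- c("lowP", "highP")

  meta <- expand.grid(trait = traits, source = sources, type = types,
                      stringsAsFactors = FALSE)[, c("type", "source", "trait")]
  meta <- meta[order(match(meta$type, types), match(meta$source, sources)), ]
  meta$metric <- paste(meta$type, abbreviate_source(meta$source), meta$trait,
                       sep = "_")
  extra <- data.frame(
    type = c("richness", "shannon", "evenness", "WAM_simple", "WAM_tol"),
    source = NA_character_, trait = NA_character_,
    metric = c("richness", "shannon", "evenness", "WAM_simple", "WAM_tol"))
  meta <- rbind(meta[, c("metric", "type", "source", "trait")],
                extra[, c("metric", "type", "source", "trait")])
  rownames(meta) <- NULL

  empty_sources <- character(0)
  maps <- lapply(sources, function(s) {
    m <- trait_map_for_source(trait_table, s)
    if (!any(m %in% c("lowP", "highP"))) empty_sources <<- c(empty_sources, s)
    m
  })
  names(maps) <- sources
  if (length(empty_sources))
    warning("no trait assignments for source(s): ",
            paste(empty_sources, collapse = ", "),
            "; those metric columns will be NA")

  vals <- matrix(NA_real_, ncol(counts), nrow(meta),
                 dimnames = list(colnames(counts), meta$metric))
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]
    for (s in sources) {
      if (s %in% empty_sources) next
      stm <- suppressWarnings(simple_trait_metrics(y, maps[[s]],
                                                   include_unassigned))
      rl <- suppressWarnings(rloga_metric(y, maps[[s]]))
      for (t in traits) {
        vals[j, paste("PropValves", abbreviate_source(s), t, sep = "_")] <-
          stm[paste0("PropValves_", t)]
        vals[j, paste("PropTaxa", abbreviate_source(s), t, sep = "_")] <-
          stm[paste0("PropTaxa_", t)]
        vals[j, paste("noTaxa", abbreviate_source(s), t, sep = "_")] <-
          stm[paste0("noTaxa_", t)]
        vals[j, paste("RlogA", abbreviate_source(s), t, sep = "_")] <-
          rl[paste0("RlogA_", t)]
      }
    }
    vals[j, c("richness", "shannon", "evenness")] <- diversity_metrics(y)
    vals[j, "WAM_simple"] <- wam_infer(y, optima, "simple")
    vals[j, "WAM_tol"] <- wam_infer(y, optima, "tol")
  }
  out <- data.frame(sample = colnames(counts), vals, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, metadata = meta, class = c("metric_matrix", "data.frame"))
}

abbreviate_source <- function(s) {
  c(literature = "lit", regression = "reg", titan = "titan")[s]
}

#' Metric metadata of a metric matrix
#'
#' @param x a `metric_matrix`.
#' @return data frame `metric`, `type`, `source`, `trait`.
#' @export
metric_metadata <- function(x) attr(x, "metadata")

#' The benchmark metric subset
#'
#' The metrics carried into benchmark derivation: the 3 diversity metrics,
#' the 2 weighted-average metrics, and the 8 TITAN-trait metrics
#' (literature- and regression-trait metrics are excluded as redundant with
#' the better-performing TITAN traits).
#'
#' @param x a `metric_matrix`.
#' @return character vector of 13 metric names.
#' @export
benchmark_metric_subset <- function(x) {
  meta <- metric_metadata(x)
  keep <- meta$type %in% c("richness", "shannon", "evenness",
                           "WAM_simple", "WAM_tol") |
    (!is.na(meta$source) & meta$source == "titan")
  meta$metric[keep]
}
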