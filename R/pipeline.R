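## End-to-end pipeline: standardize -> traits (+TITAN) -> metrics ->
## evaluate -> benchmarks, with CSV outputs and a JSON run manifest.

#' Run the full metric-development pipeline
#'
#' Executes counting-effort standardization, trait assignment (gradient
#' regression and TITAN, plus an optional literature lookup), the 29-metric
#' suite, performance evaluation, and benchmark derivation, writing every
#' intermediate table as CSV plus a reproducibility manifest.
#'
#' @param config list (or path to a JSON file) with elements:
#'   * `preset` (a [sim_preset()] name) or `counts`/`samples` (file paths);
#'   * optional `literature` (path to a CSV with `taxon`, `trait`);
#'   * optional `n_samples`, `target` (default 600), `n_perm` (default
#'     250), `n_boot` (default 500), `min_split`, `min_occurrences`,
#'     `purity_min`/`reliability_min` (default 0.95), `alpha` (trait
#'     regression, default 0.05), `tree_alpha` (default 0.01),
#'     `cut_height` (default 0.75), `linkage` (default "average"),
#'     `reference_regions`.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; every stage derives substreams.
#' @return (invisibly) list with all stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- function(name, default) config[[name]] %||% default
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- inputs ---------------------------------------------------------
  inputs <- stage("input", {
    if (!is.null(config$preset)) {
      sim <- simulate_assemblage(sim_preset(config$preset,
                                            cfg("n_samples", 80L)),
                                 seed = derive_seed(seed, "simulate"))
      write_count_matrix(sim$counts, file.path(out_dir, "counts.csv"))
      utils::write.csv(sim$samples, file.path(out_dir, "samples.csv"),
                       row.names = FALSE)
      list(counts = sim$counts, samples = sim$samples, truth = sim$truth)
    } else {
      list(counts = read_count_matrix(config$counts),
           samples = read_sample_table(config$samples), truth = NULL)
    }
  })
  aset <- stage("bind", bind_analysis_set(inputs$counts, inputs$samples))
  if (is.null(aset$samples$mat_p))
    stop("pipeline stage 'bind' failed: samples have no mat_p column",
         call. = FALSE)

  ## -- standardize ----------------------------------------------------
  target <- cfg("target", 600L)
  std <- stage("standardize",
               rarefy_matrix(aset$counts, target = target,
                             seed = derive_seed(seed, "rarefy")))
  write_count_matrix(std$counts, file.path(out_dir, "counts_std.csv"))

  ## -- traits ---------------------------------------------------------
  mat_p <- aset$samples$mat_p
  reg <- stage("traits:regression",
               assign_traits_regression(std$counts, mat_p,
                                        alpha = cfg("alpha", 0.05),
                                        min_occurrences =
                                          cfg("min_occurrences", 5L)))
  titan_res <- stage("traits:titan",
    titan_assemblage(std$counts, mat_p,
                     n_perm = cfg("n_perm", 250L),
                     n_boot = cfg("n_boot", 500L),
                     min_split = cfg("min_split", 5L),
                     min_occurrences = cfg("min_occurrences", 5L),
                     seed = derive_seed(seed, "titan")))
  titan_traits <- traits_from_titan(titan_res,
                                    purity_min = cfg("purity_min", 0.95),
                                    reliability_min =
                                      cfg("reliability_min", 0.95))
  lit <- if (!is.null(config$literature))
    utils::read.csv(config$literature, stringsAsFactors = FALSE) else NULL
  traits <- stage("traits:merge",
                  merge_trait_sources(regression = reg, titan = titan_traits,
                                      literature = lit))
  utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  optima <- stage("traits:wa", wa_optima(std$counts, mat_p))
  utils::write.csv(optima, file.path(out_dir, "optima.csv"),
                   row.names = FALSE)

  ## -- metrics --------------------------------------------------------
  metrics <- stage("metrics",
                   suppressWarnings(build_metric_matrix(std, traits, optima)))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(metric_metadata(metrics),
                   file.path(out_dir, "metric_metadata.csv"),
                   row.names = FALSE)

  ## -- evaluate -------------------------------------------------------
  perf <- stage("evaluate", evaluate_metrics(metrics, aset$samples))
  ranks <- stage("evaluate:ranks", grouped_ranks(perf))
  utils::write.csv(ranks, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)

  ## -- benchmarks -----------------------------------------------------
  profile <- stage("benchmarks:titan",
                   community_profile(titan_res,
                                     purity_min = cfg("purity_min", 0.95),
                                     reliability_min =
                                       cfg("reliability_min", 0.95)))
  clust <- stage("benchmarks:cluster", {
    d <- bray_curtis(std$counts)
    hierarchical_groups(d, linkage = cfg("linkage", "average"),
                        cut_height = cfg("cut_height", 0.75),
                        mat_p = mat_p)
  })
  bench <- stage("benchmarks",
    benchmark_report(metrics, aset$samples, titan_profile = profile,
                     cluster_result = clust,
                     reference_regions = cfg("reference_regions", "NW"),
                     tree_args = list(alpha = cfg("tree_alpha", 0.01),
                                      n_perm = cfg("tree_n_perm", 999L),
                                      seed = derive_seed(seed, "tree"))))
  utils::write.csv(bench$table, file.path(out_dir, "benchmarks.csv"),
                   row.names = FALSE)

  manifest <- list(
    tool = "diatomtraits",
    version = as.character(utils::packageVersion("diatomtraits")),
    seed = seed,
    parameters = config[setdiff(names(config), c("counts", "samples"))],
    inputs = config[intersect(names(config), c("counts", "samples",
                                               "literature", "preset"))],
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(analysis_set = aset, standardized = std, traits = traits,
                 optima = optima, titan = titan_res, metrics = metrics,
                 performance = perf, ranks = ranks, profile = profile,
                 cluster = clust, benchmarks = bench,
                 truth = inputs$truth))
}
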