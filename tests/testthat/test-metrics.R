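test_that("simple trait metrics exclude unassigned taxa from denominators", {
  y <- c(taxA = 30, taxB = 70, taxC = 100)
  out <- simple_trait_metrics(y, make_trait_map())
  expect_equal(out[["PropValves_lowP"]], 0.3)
  expect_equal(out[["PropTaxa_lowP"]], 0.5)
  expect_equal(out[["noTaxa_lowP"]], 1)
  expect_equal(out[["PropValves_lowP"]] + out[["PropValves_highP"]], 1)
  expect_equal(out[["PropTaxa_lowP"]] + out[["PropTaxa_highP"]], 1)

  ## all present taxa low P
  out2 <- simple_trait_metrics(c(taxA = 50), c(taxA = "lowP"))
  expect_equal(out2[["PropValves_lowP"]], 1)
  expect_equal(out2[["PropValves_highP"]], 0)

  ## only unassigned taxa present: proportions undefined, counts zero
  expect_warning(
    out3 <- simple_trait_metrics(c(taxC = 10), make_trait_map()),
    "undefined")
  expect_true(is.na(out3[["PropValves_lowP"]]))
  expect_equal(out3[["noTaxa_lowP"]], 0)
})

test_that("RlogA follows the literal double-ratio formula", {
  ## powers of two give exact log ratios: ln8 / (ln8 + ln2) = 3/4
  y <- c(taxA = 8, taxB = 2)
  out <- rloga_metric(y, make_trait_map())
  expect_equal(out[["RlogA_lowP"]], 3 / 4, tolerance = 1e-12)
  expect_equal(out[["RlogA_lowP"]] + out[["RlogA_highP"]], 1)

  ## a single counted valve carries ln(1) = 0 weight
  out2 <- rloga_metric(c(taxA = 1, taxB = 8), make_trait_map())
  expect_equal(out2[["RlogA_lowP"]], 0)

  ## every assigned taxon at count <= 1: denominator zero
  expect_warning(out3 <- rloga_metric(c(taxA = 1, taxB = 1, taxC = 50),
                                      make_trait_map()), "denominator")
  expect_true(all(is.na(out3)))
})

test_that("RlogA double ratio equals the log-sum ratio identity", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    y <- stats::setNames(sample(2:400, n), sprintf("t%02d", seq_len(n)))
    tr <- stats::setNames(sample(c("lowP", "highP", "unassigned"), n,
                                 replace = TRUE, prob = c(.4, .4, .2)),
                          names(y))
    if (!any(tr %in% c("lowP", "highP"))) next
    out <- suppressWarnings(rloga_metric(y, tr))
    sel <- tr %in% c("lowP", "highP")
    expected <- sum(log(y[sel & tr == "lowP"])) / sum(log(y[sel]))
    expect_equal(out[["RlogA_lowP"]], expected, tolerance = 1e-12)
  }
})

test_that("diversity metrics hit their closed forms", {
  out <- diversity_metrics(c(5, 5, 5, 5))
  expect_equal(out[["richness"]], 4)
  expect_equal(out[["shannon"]], log(4), tolerance = 1e-12)
  expect_equal(out[["evenness"]], 1, tolerance = 1e-12)

  out1 <- diversity_metrics(c(10, 0, 0))
  expect_equal(out1[["richness"]], 1)
  expect_equal(out1[["shannon"]], 0)
  expect_true(is.na(out1[["evenness"]]))

  out2 <- diversity_metrics(c(90, 10))
  expect_equal(out2[["shannon"]], -0.9 * log(0.9) - 0.1 * log(0.1),
               tolerance = 1e-12)
  expect_error(diversity_metrics(c(0, 0)), "empty")
})

test_that("weighted-average inference interpolates optima and honors tolerances", {
  opt <- data.frame(taxon = c("a", "b"), optimum = c(100, 300),
                    tolerance = c(50, 50))
  expect_equal(wam_infer(c(a = 10), opt, "simple"), 100)
  y <- c(a = 10, b = 10)
  expect_equal(wam_infer(y, opt, "simple"), 200)
  expect_equal(wam_infer(y, opt, "tol"), 200)

  ## halving a taxon's tolerance pulls the inference toward its optimum
  opt2 <- opt; opt2$tolerance <- c(25, 50)
  expect_lt(wam_infer(y, opt2, "tol"), 200)

  ## single present taxon with the lowest optimum returns it exactly
  opt3 <- data.frame(taxon = "enc", optimum = 112, tolerance = 0)
  expect_equal(wam_infer(c(enc = 600), opt3, "tol"), 112)
  expect_true(is.na(wam_infer(c(zz = 5), opt, "simple")))
})

test_that("the metric matrix carries the full 29-metric suite with metadata", {
  sim <- simulate_assemblage(sim_preset("bcnp_like", 25), seed = 12)
  std <- rarefy_matrix(sim$counts, 600, seed = 1)
  truth <- sim$truth$taxa
  lit <- data.frame(taxon = truth$taxon, trait = truth$trait)
  reg <- assign_traits_regression(std$counts, sim$samples$mat_p)
  traits <- suppressMessages(
    merge_trait_sources(regression = reg, titan = lit, literature = lit))
  opt <- wa_optima(std$counts, sim$samples$mat_p)
  mm <- suppressWarnings(build_metric_matrix(std, traits, opt))

  meta <- metric_metadata(mm)
  expect_equal(nrow(meta), 29)
  expect_equal(sum(!is.na(meta$source)), 24)
  expect_equal(sum(meta$source %in% "titan"), 8)
  expect_length(benchmark_metric_subset(mm), 13)
  expect_true(all(meta$metric %in% names(mm)))

  ## complementarity where defined
  for (s in c("lit", "reg", "titan")) {
    for (ty in c("PropValves", "PropTaxa", "RlogA")) {
      lo <- mm[[paste(ty, s, "lowP", sep = "_")]]
      hi <- mm[[paste(ty, s, "highP", sep = "_")]]
      ok <- !is.na(lo) & !is.na(hi)
      expect_true(all(abs(lo[ok] + hi[ok] - 1) < 1e-12))
    }
  }
  ## proportions bounded, noTaxa integral
  expect_true(all(mm$PropValves_titan_lowP >= 0 &
                    mm$PropValves_titan_lowP <= 1, na.rm = TRUE))
  expect_true(all(mm$noTaxa_reg_lowP == round(mm$noTaxa_reg_lowP)))
})

test_that("metrics are invariant to taxon and sample ordering", {
  sim <- simulate_assemblage(sim_preset("bcnp_like", 15), seed = 4)
  counts <- sim$counts
  truth <- sim$truth$taxa
  lit <- data.frame(taxon = truth$taxon, trait = truth$trait)
  traits <- merge_trait_sources(regression = lit, titan = lit,
                                literature = lit)
  opt <- wa_optima(counts, sim$samples$mat_p)
  m1 <- suppressWarnings(build_metric_matrix(counts, traits, opt))
  set.seed(2)
  perm_t <- sample(nrow(counts)); perm_s <- sample(ncol(counts))
  m2 <- suppressWarnings(
    build_metric_matrix(counts[perm_t, perm_s], traits, opt))
  m2 <- m2[match(m1$sample, m2$sample), ]
  rownames(m2) <- NULL
  expect_equal(as.data.frame(m1), as.data.frame(m2), tolerance = 1e-12)
})

test_that("an empty trait source leaves its 8 metric columns missing", {
  sim <- simulate_assemblage(sim_preset("bcnp_like", 15), seed = 5)
  truth <- sim$truth$taxa
  lit <- data.frame(taxon = truth$taxon, trait = truth$trait)
  traits <- merge_trait_sources(regression = lit, titan = lit,
                                literature = NULL)
  opt <- wa_optima(sim$counts, sim$samples$mat_p)
  expect_warning(mm <- build_metric_matrix(sim$counts, traits, opt),
                 "literature")
  lit_cols <- grep("_lit_", names(mm), value = TRUE)
  expect_length(lit_cols, 8)
  expect_true(all(is.na(as.matrix(mm[, lit_cols]))))
  other <- grep("_(reg|titan)_", names(mm), value = TRUE)
  expect_length(other, 16)
  expect_false(anyNA(as.matrix(mm[, grep("PropValves_(reg|titan)", names(mm))])))
})
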