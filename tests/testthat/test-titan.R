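test_that("indicator values match the defining formula", {
  ## perfect left indicator
  y <- c(3, 2, 4, 0, 0, 0)
  g <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(indval(y, g), c(left = 100, right = 0))

  ## uniform taxon, equal groups: A = 0.5, B = 1 on both sides
  expect_equal(indval(rep(2, 6), g), c(left = 50, right = 50))

  ## {4,0 | 0,4}: A = 0.5 and B = 0.5 per side, so 25 each
  y2 <- c(4, 0, 0, 4)
  g2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(indval(y2, g2), c(left = 25, right = 25))
  expect_equal(indval(y2, g2), oracle_indval(y2, g2))

  expect_warning(z <- indval(c(0, 0, 0, 0), g2), "all-zero")
  expect_equal(unname(z), c(0, 0))
  expect_error(indval(y2, rep(TRUE, 4)), "non-empty")

  ## random agreement with the brute-force oracle
  set.seed(33)
  for (i in 1:25) {
    y <- rpois(10, 3)
    if (all(y == 0)) next
    g <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    if (!any(g) || all(g)) next
    expect_equal(indval(y, g), oracle_indval(y, g), tolerance = 1e-12)
  }
})

test_that("step-response taxa are located at the correct changepoint and direction", {
  x <- seq(100, 800, by = 20)  # 36 samples
  y_low <- ifelse(x < 400, 0.3, 0)
  res <- titan_taxon(y_low, x, n_perm = 100, seed = 1)
  expect_identical(res$direction, "z-")
  expect_equal(res$changepoint, 390)  # midpoint of 380 and 400
  expect_equal(res$indval, 100)

  ## mirror image: same changepoint, opposite direction
  res2 <- titan_taxon(ifelse(x >= 400, 0.3, 0), x, n_perm = 100, seed = 1)
  expect_identical(res2$direction, "z+")
  expect_equal(res2$changepoint, 390)
  expect_lt(res$p, 0.05)
})

test_that("titan_taxon matches the exhaustive IndVal scan", {
  set.seed(88)
  for (i in 1:10) {
    n <- sample(15:40, 1)
    x <- round(2^runif(n, log2(52), log2(1200)))
    y <- rbinom(n, 50, plogis(-(log2(x) - 8) * runif(1, -2, 2))) / 50
    if (sum(y > 0) < 5) next
    sc <- oracle_iv_scan(y, x, min_split = 5)
    res <- titan_taxon(y, x, n_perm = 20, min_split = 5,
                       select_by = "indval", seed = i)
    expect_equal(res$iv_obs, sc$iv_max, tolerance = 1e-10)
    expect_equal(res$candidates, sc$changepoint, tolerance = 1e-10)
    expect_equal(res$indval, max(sc$iv_max), tolerance = 1e-10)
    expect_equal(res$changepoint, sc$changepoint[which.max(sc$iv_max)])
  }
})

test_that("z is invariant to abundance rescaling and runs are seed-deterministic", {
  set.seed(5)
  x <- 2^runif(30, log2(52), log2(1200))
  y <- ifelse(x < 300, runif(30, 0.1, 0.3), 0.01)
  a <- titan_taxon(y, x, n_perm = 50, seed = 77)
  b <- titan_taxon(7.3 * y, x, n_perm = 50, seed = 77)
  expect_equal(a$z_profile, b$z_profile, tolerance = 1e-10)
  expect_identical(a$changepoint, b$changepoint)
  c2 <- titan_taxon(y, x, n_perm = 50, seed = 77)
  expect_identical(a$z, c2$z)

  expect_error(titan_taxon(y[1:8], x[1:8], min_split = 5), "2 \\* min_split")
  expect_error(titan_taxon(rep(c(1, 0), 15) * (seq(30) <= 3), x,
                           min_split = 5), "fewer than min_split")
})

test_that("bootstrap of a noiseless step taxon is pure, reliable and ordered", {
  x <- seq(100, 800, by = 20)
  y <- ifelse(x < 400, 0.3, 0)
  bt <- titan_bootstrap(y, x, n_boot = 30, n_perm = 60, seed = 4)
  expect_equal(bt$purity, 1)
  expect_equal(bt$reliability, 1)
  q <- bt$quantiles
  expect_true(all(diff(q) >= 0))
})

test_that("pure-noise taxa have purity near one half", {
  set.seed(60)
  x <- 2^runif(40, log2(52), log2(1200))
  y <- rbinom(40, 600, 0.05) / 600
  bt <- titan_bootstrap(y, x, n_boot = 60, n_perm = 40, seed = 21)
  ## binomial(60, .5) 99% band
  expect_gt(bt$purity, 0.5 - 2.58 * sqrt(0.25 / 60) - 0.05)
  expect_lt(bt$purity, 0.5 + 2.58 * sqrt(0.25 / 60) + 0.05)
})

test_that("community sum(z) is additive over identical taxa and filters apply", {
  set.seed(9)
  x <- 2^runif(50, log2(52), log2(1200))
  step <- ifelse(x < 350, 40L, 0L)
  noise <- rbinom(50, 30, 0.5)
  counts <- rbind(dec1 = step, dec2 = step, fill = noise)
  colnames(counts) <- sprintf("s%02d", 1:50)
  res <- titan_assemblage(counts, x, n_perm = 80, n_boot = 0, seed = 3)
  prof <- suppressWarnings(
    community_profile(res, purity_min = 0, reliability_min = 0))
  zd <- res$z_profiles
  ## the two identical decreasers contribute identical profiles
  expect_equal(zd["dec1", ], zd["dec2", ], tolerance = 1e-10)
  expected <- colSums(pmax(zd[prof$taxa_used[["z-"]], , drop = FALSE], 0))
  expect_equal(unname(prof$sum_z["z-", ]), unname(expected),
               tolerance = 1e-10)
  ## the duplicated decreaser doubles its own contribution
  only_dupes <- colSums(pmax(zd[c("dec1", "dec2"), , drop = FALSE], 0))
  expect_equal(unname(only_dupes), unname(2 * pmax(zd["dec1", ], 0)),
               tolerance = 1e-10)
  expect_identical(unname(prof$changepoint["z-"]),
                   res$candidates[which.max(prof$sum_z["z-", ])])

  ## filtering everything out of one direction warns and leaves NA
  res$taxa$purity <- ifelse(res$taxa$direction == "z+", 0, 1)
  res$taxa$reliability <- 1
  expect_warning(p2 <- community_profile(res, purity_min = 0.9,
                                         reliability_min = 0),
                 "z\\+")
  expect_true(is.na(p2$changepoint["z+"]))
})

test_that("TITAN trait calls follow direction and bootstrap filters", {
  set.seed(14)
  x <- 2^runif(40, log2(52), log2(1200))
  counts <- rbind(dec = ifelse(x < 300, 50L, 0L),
                  inc = ifelse(x >= 300, 50L, 0L),
                  mid = rbinom(40, 40, 0.5))
  colnames(counts) <- sprintf("s%02d", 1:40)
  res <- titan_assemblage(counts, x, n_perm = 60, n_boot = 0, seed = 2)
  tr0 <- traits_from_titan(res, purity_min = 0, reliability_min = 0)
  expect_identical(tr0$trait[tr0$taxon == "dec"], "lowP")
  expect_identical(tr0$trait[tr0$taxon == "inc"], "highP")
  expect_true(all(tr0$trait != "unassigned"))

  res$taxa$purity <- c(0.8, 1, 1)
  res$taxa$reliability <- c(1, 1, 0.2)
  tr <- traits_from_titan(res, purity_min = 0.95, reliability_min = 0.95)
  expect_identical(tr$trait[tr$taxon == "dec"], "unassigned")  # purity 0.8
  expect_identical(tr$trait[tr$taxon == "inc"], "highP")
  expect_identical(tr$trait[tr$taxon == "mid"], "unassigned")  # reliability
})

test_that("community bootstrap yields nondecreasing cumulative frequencies", {
  set.seed(31)
  x <- 2^runif(40, log2(60), log2(1100))
  counts <- rbind(d1 = ifelse(x < 350, 40L, 1L),
                  d2 = ifelse(x < 420, 30L, 2L),
                  i1 = ifelse(x > 380, 35L, 1L),
                  fill = rbinom(40, 30, 0.4))
  colnames(counts) <- sprintf("s%02d", 1:40)
  res <- titan_assemblage(counts, x, n_perm = 50, n_boot = 0, seed = 6)
  prof <- community_profile(res, purity_min = 0, reliability_min = 0,
                            n_boot = 15, n_perm = 25, seed = 8)
  for (dir in c("z-", "z+")) {
    cdf <- prof$boot_cdf[[dir]]
    expect_false(is.null(cdf))
    expect_true(all(diff(cdf$cumfreq) >= 0))
    expect_gte(min(cdf$cumfreq), 0)
    expect_lte(max(cdf$cumfreq), 1)
  }
})

test_that("a planted community threshold is recovered by the sum(z-) profile", {
  ## all low-P taxa switch off at 400 ug/g; the community changepoint
  ## should land in the candidate-grid interval containing the truth
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_assemblage(sim_preset("step_threshold", 50),
                               seed = 300 + s)
    x <- sim$samples$mat_p
    res <- titan_assemblage(sim$counts, x, n_perm = 60, n_boot = 0,
                            seed = s)
    prof <- suppressWarnings(
      community_profile(res, purity_min = 0, reliability_min = 0))
    ux <- sort(unique(x))
    i <- findInterval(sim$truth$threshold, ux)
    target <- (ux[i] + ux[i + 1]) / 2
    hits <- hits + isTRUE(abs(prof$changepoint["z-"] - target) < 1e-9)
  }
  expect_gte(hits, 16)
})
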