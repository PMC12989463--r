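test_that("gradient regression recovers exact linear relationships", {
  x <- 2^seq(5.7, 10.2, length.out = 30)
  y <- 0.8 - 0.05 * log2(x)
  fit <- suppressWarnings(fit_metric_gradient(y, x))  # exact fit
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -0.05, tolerance = 1e-10)

  fit2 <- fit_metric_gradient(rep(0.3, 30), x)
  expect_equal(fit2$slope, 0)
  expect_true(fit2$constant)

  expect_error(fit_metric_gradient(c(1, 2, 3), c(10, 20, 30)), "at least 4")
})

test_that("null metrics have near-zero mean adjusted R2", {
  set.seed(17)
  r2 <- replicate(300, {
    x <- 2^runif(40, 5.7, 10.2)
    fit_metric_gradient(rnorm(40), x)$adj_r2
  })
  expect_lt(abs(mean(r2)), 0.02)
})

test_that("lat-long model scores exact planes and degenerate designs", {
  set.seed(3)
  lat <- runif(30, 25.7, 26.3); long <- runif(30, -81.5, -80.9)
  y <- 2 * lat - 3 * long
  expect_equal(suppressWarnings(latlong_model(y, lat, long)), 1,
               tolerance = 1e-10)
  ## position-independent values: adj R2 near zero on average
  r2 <- replicate(200, latlong_model(rnorm(30), lat, long))
  expect_lt(abs(mean(r2)), 0.05)
  ## collinear design flagged
  expect_warning(v <- latlong_model(y, lat, lat - 107), "degenerate")
  expect_true(is.na(v))
  expect_error(latlong_model(1:5, runif(5), runif(5)), "at least 6")
})

## A deterministic 24-cell factorial performance table for rank tests.
fake_perf <- function(bias_type = 0.2) {
  g <- expand.grid(type = c("PropValves", "PropTaxa", "noTaxa", "RlogA"),
                   source = c("literature", "regression", "titan"),
                   trait = c("lowP", "highP"), stringsAsFactors = FALSE)
  set.seed(41)
  g$metric <- paste(g$type, g$source, g$trait, sep = "_")
  g$adj_r2 <- runif(24, 0.3, 0.6) + ifelse(g$type == "RlogA", bias_type, 0)
  g$slope <- 1; g$p <- 0.01; g$adj_r2_latlong <- NA_real_
  g
}

test_that("family ANOVA flags separated groups and is flat for identical ones", {
  perf <- fake_perf(0)
  perf$adj_r2 <- rep(c(0.2, 0.4), 12)  # identical distribution per type
  ## force exact equality across types within each source x trait block
  perf$adj_r2 <- rep(c(0.2, 0.4, 0.2, 0.4), 6)
  a0 <- family_anova(perf, "trait")
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_true(all(a0$tukey$`p adj` > 0.999))

  ## fully separated groups: compare against the closed-form F
  perf2 <- fake_perf(0)
  perf2$adj_r2 <- ifelse(perf2$trait == "lowP", 0, 1) +
    rep(seq(0, 0.011, length.out = 12), 2)
  a1 <- family_anova(perf2, "trait")
  grp <- split(perf2$adj_r2, perf2$trait)
  gm <- mean(perf2$adj_r2)
  ssb <- sum(vapply(grp, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(grp, function(v) sum((v - mean(v))^2), 1))
  f_oracle <- (ssb / 1) / (ssw / (24 - 2))
  expect_equal(a1$F, f_oracle, tolerance = 1e-8)
  expect_lt(a1$p, 0.001)

  expect_error(family_anova(perf[perf$trait == "lowP", ], "trait"),
               "fewer than 2")
})

test_that("grouped ranks follow the three grouping schemes with mid-ranked ties", {
  perf <- fake_perf(0)
  ## construct one source x trait group with known ordering
  sel <- perf$source == "titan" & perf$trait == "lowP"
  perf$adj_r2[sel][match(c("PropValves", "PropTaxa", "noTaxa", "RlogA"),
                         perf$type[sel])] <- c(0.2, 0.4, 0.6, 0.8)
  rk <- grouped_ranks(perf)
  got <- rk$rank_type[rk$source == "titan" & rk$trait == "lowP"]
  names(got) <- rk$type[rk$source == "titan" & rk$trait == "lowP"]
  expect_equal(got[c("PropValves", "PropTaxa", "noTaxa", "RlogA")],
               c(PropValves = 1, PropTaxa = 2, noTaxa = 3, RlogA = 4))

  ## all-equal group mid-ranks at 2.5
  perf$adj_r2[sel] <- 0.5
  rk2 <- grouped_ranks(perf)
  expect_true(all(rk2$rank_type[rk2$source == "titan" &
                                  rk2$trait == "lowP"] == 2.5))

  ## exhaustive brute-force oracle over the whole 24-cell table
  rk3 <- grouped_ranks(fake_perf(0.1))
  for (i in seq_len(nrow(rk3))) {
    grp <- rk3[rk3$source == rk3$source[i] & rk3$trait == rk3$trait[i], ]
    expect_equal(rk3$rank_type[i],
                 sum(grp$adj_r2 < grp$adj_r2[grp$type == rk3$type[i]]) + 1)
  }
  ## each scheme's ranks within a group are a permutation of 1..size
  expect_setequal(rk3$rank_source[rk3$type == "RlogA" &
                                    rk3$trait == "lowP"], 1:3)
  expect_setequal(rk3$rank_trait[rk3$type == "RlogA" &
                                   rk3$source == "titan"], 1:2)
})

test_that("Kruskal tests detect a consistently top-ranked metric type", {
  rk <- grouped_ranks(fake_perf(0.5))  # RlogA dominates every group
  expect_true(all(rk$rank_type[rk$type == "RlogA"] == 4))
  kt <- family_kruskal(rk, "type")
  expect_lt(kt$p, 0.01)
  ## closed-form H for the constructed ranks
  d <- rk[!is.na(rk$rank_type), ]
  n <- nrow(d)
  r_all <- rank(d$rank_type)
  h_oracle <- 12 / (n * (n + 1)) *
    sum(tapply(r_all, d$type, function(r) length(r) * mean(r)^2)) -
    3 * (n + 1)
  ties <- table(d$rank_type)
  h_oracle <- h_oracle / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kt$H, h_oracle, tolerance = 1e-8)

  ## null ranks: no signal
  set.seed(10)
  rknull <- grouped_ranks(fake_perf(0))
  ktn <- family_kruskal(rknull, "source")
  expect_gt(ktn$p, 0.01)
})
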