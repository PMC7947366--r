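# Histogram feature extraction: percentiles, printed-formula moments,
# entropy/inhomogeneity and the VOI aggregation rules.

test_that("percentile follows the inclusive linear-interpolation convention", {
  expect_equal(percentile(1:101, 50), 51)
  expect_equal(percentile(c(3, 1, 2), 50), 2)
  set.seed(2)
  x <- runif(200, 40, 120)
  for (q in c(5, 25, 50, 75, 95))
    expect_equal(percentile(x, q), oracle_percentile(x, q))
  expect_lte(percentile(x, 5), percentile(x, 95))
  expect_error(percentile(numeric(0), 50), class = "empty_voi_error")
  expect_error(percentile(x, 0), class = "domain_error")
})

test_that("moments evaluate the printed population formulas", {
  expect_equal(moments(c(1, 2, 3))$skewness, 0)
  m <- moments(c(1, 1, 1, 5))
  expect_equal(m$skewness, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(m$kurtosis, 21 / 9, tolerance = 1e-12)
  expect_equal(m$sd, sqrt(3), tolerance = 1e-12)   # 1/Np, not sample sd
  set.seed(3)
  z <- rnorm(1e6)
  expect_equal(moments(z)$kurtosis, 3, tolerance = 0.05 / 3)
  expect_warning(moments(rep(4, 10)),
                 class = "degenerate_distribution_warning")
  m0 <- suppressWarnings(moments(rep(4, 10)))
  expect_equal(m0$mean, 4)
  expect_equal(m0$sd, 0)
  expect_true(is.na(m0$skewness))
})

test_that("histogram probabilities use fixed-width bins anchored at zero", {
  p1 <- histogram_probabilities(rep(7.3, 5), 1)
  expect_equal(as.numeric(p1), 1)
  expect_equal(attr(p1, "ng"), 1)
  p2 <- histogram_probabilities(c(5, 15), 10)
  expect_equal(as.numeric(p2), c(0.5, 0.5))
  expect_equal(attr(p2, "ng"), 2)
  set.seed(4)
  x <- rnorm(1000, 70, 15)
  p <- histogram_probabilities(x, 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(attr(p, "ng"), length(unique(floor(x))))  # counting oracle
  oracle_counts <- vapply(sort(unique(floor(x))),
                          function(b) sum(floor(x) == b), 0L)
  expect_equal(as.numeric(p), oracle_counts / 1000)
})

test_that("entropy and inhomogeneity match closed forms and attain bounds", {
  expect_equal(entropy(1), 0, tolerance = 1e-12)
  expect_equal(entropy(rep(1 / 8, 8)), 3, tolerance = 1e-9)
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.5, tolerance = 1e-9)
  expect_equal(inhomogeneity(1), 1)
  expect_equal(inhomogeneity(rep(1 / 8, 8)), 0.125)
  expect_equal(inhomogeneity(c(0.5, 0.25, 0.25)), 0.375)
  expect_error(entropy(c(0.7, -0.1, 0.4)), class = "domain_error")
  expect_error(entropy(c(0.5, 0.4)), class = "domain_error")
  # bounds over random histograms: 0 <= H <= log2(Ng), 1/Ng <= U <= 1
  set.seed(6)
  for (i in 1:200) {
    k <- sample(1:40, 1)
    p <- as.numeric(histogram_probabilities(runif(60, 0, k), 1))
    ng <- length(p)
    expect_gte(entropy(p), -1e-12)  # -log2(1+eps) at a single bin
    expect_lte(entropy(p), log2(ng) + 1e-9)
    expect_gte(inhomogeneity(p), 1 / ng - 1e-12)
    expect_lte(inhomogeneity(p), 1)
  }
})

test_that("feature values are invariant to ordering and label renumbering", {
  co <- simulate_cohort(tiny_config())
  p <- co$patients[[1]]
  tm <- fit_t2_map(p$echoes, mask = p$mask)
  f1 <- extract_features(tm, p$mask, co$label_table)
  # renumber labels 1..10 -> 11..20
  mask2 <- p$mask + 10L * (p$mask > 0L)
  lt2 <- co$label_table
  lt2$label <- lt2$label + 10L
  f2 <- extract_features(tm, mask2, lt2)
  expect_equal(f1[, -(1:4)], f2[, -(1:4)], tolerance = 1e-12)
  # voi_values: cardinality and additivity (multiset equality)
  lab <- co$label_table$label[co$label_table$side == "left"][1:2]
  v1 <- voi_values(tm, p$mask, lab[1])
  v2 <- voi_values(tm, p$mask, lab[2])
  v12 <- voi_values(tm, p$mask, lab)
  expect_equal(length(v1), sum(p$mask == lab[1] & tm$valid))
  expect_equal(sort(v12), sort(c(v1, v2)))
  expect_error(voi_values(tm, p$mask, 99), class = "empty_voi_error")
  tm0 <- tm
  tm0$valid[] <- FALSE
  expect_error(voi_values(tm0, p$mask, lab[1]), class = "empty_voi_error")
})

test_that("shift invariances hold for the feature families", {
  set.seed(7)
  x <- runif(500, 50, 90)
  c_shift <- 13                       # a bin-width multiple
  m1 <- moments(x); m2 <- moments(x + c_shift)
  expect_equal(m2$mean, m1$mean + c_shift, tolerance = 1e-9)
  expect_equal(m2$sd, m1$sd, tolerance = 1e-9)
  expect_equal(m2$skewness, m1$skewness, tolerance = 1e-9)
  expect_equal(m2$kurtosis, m1$kurtosis, tolerance = 1e-9)
  expect_equal(percentile(x + c_shift, 95), percentile(x, 95) + c_shift,
               tolerance = 1e-9)
  p1 <- histogram_probabilities(x, 1)
  p2 <- histogram_probabilities(x + c_shift, 1)
  expect_equal(entropy(as.numeric(p1)), entropy(as.numeric(p2)),
               tolerance = 1e-12)
  expect_equal(inhomogeneity(as.numeric(p1)),
               inhomogeneity(as.numeric(p2)), tolerance = 1e-12)
})

test_that("aggregation rules behave as documented", {
  co <- simulate_cohort(tiny_config())
  p <- co$patients[[2]]
  tm <- fit_t2_map(p$echoes, mask = p$mask)
  pooled <- extract_features(tm, p$mask, co$label_table, "pooled_all_eoms")
  expect_equal(nrow(pooled), 2)                      # one row per orbit
  per <- extract_features(tm, p$mask, co$label_table, "per_muscle")
  expect_equal(nrow(per), 10)
  expect_equal(sum(per$n_voxels), sum(pooled$n_voxels))
  mx <- extract_features(tm, p$mask, co$label_table, "max_mean_muscle")
  expect_equal(nrow(mx), 2)
  for (s in c("left", "right"))
    expect_equal(mx$mean_ms[mx$side == s],
                 max(per$mean_ms[per$side == s]))
  # constant T2 field: degenerate histogram
  tmc <- tm
  tmc$t2_ms[p$mask > 0] <- 70
  fc <- extract_features(tmc, p$mask, co$label_table)
  expect_equal(fc$entropy, rep(0, 2), tolerance = 1e-9)
  expect_equal(fc$inhomogeneity, rep(1, 2))
  expect_equal(fc$p5, fc$p95)
  expect_true(all(is.na(fc$skewness)))
  # pooling two identical muscles equals the single muscle
  mask3 <- array(0L, dim(p$mask))
  mask3[1:3, 1:3, 1:2] <- 1L
  mask3[6:8, 1:3, 1:2] <- 2L
  tmi <- tm
  vals <- rep(seq(60, 85, length.out = 18), 2)
  tmi$t2_ms[mask3 == 1L] <- vals[1:18]
  tmi$t2_ms[mask3 == 2L] <- vals[1:18]
  tmi$valid[mask3 > 0L] <- TRUE
  lt3 <- data.frame(label = 1:2, muscle = c("medial", "lateral"),
                    side = "left")
  both <- extract_features(tmi, mask3, lt3, "pooled_all_eoms")
  one <- extract_features(tmi, mask3, lt3, "per_muscle")
  expect_equal(both$entropy, one$entropy[1], tolerance = 1e-12)
  expect_equal(both$skewness, one$skewness[1], tolerance = 1e-12)
  expect_equal(both$mean_ms, one$mean_ms[1], tolerance = 1e-12)
  expect_equal(both$inhomogeneity, one$inhomogeneity[1], tolerance = 1e-12)
  # interpolated order statistics shift by at most one inter-value gap when
  # the sample is duplicated
  expect_equal(both$p95, one$p95[1], tolerance = 5e-3)
})

test_that("a heavier right tail raises skewness and the 95th percentile", {
  set.seed(9)
  wins <- 0
  for (i in 1:30) {
    base <- rnorm(200, 70, 6)
    tail_mix <- c(rnorm(170, 70, 6), rnorm(30, 100, 10))
    if (moments(tail_mix)$skewness > moments(base)$skewness &&
        percentile(tail_mix, 95) > percentile(base, 95))
      wins <- wins + 1
  }
  expect_gte(wins, 28)   # sign test: heavier tail dominates
})
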