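# Logistic regression, nomogram construction/scoring and C-index.

make_2x2_data <- function(a, b, c, d) {
  # exposure x outcome counts (a, b) for x = 1 and (c, d) for x = 0
  data.frame(x = rep(c(1, 1, 0, 0), c(a, b, c, d)),
             y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

test_that("single-predictor fit equals the 2x2 closed-form identity", {
  d <- make_2x2_data(42, 24, 6, 18)
  fit <- fit_logistic(d["x"], d$y)
  expect_true(fit$converged)
  expect_equal(unname(fit$or_), (42 * 18) / (24 * 6), tolerance = 1e-6)
  se <- sqrt(1 / 42 + 1 / 24 + 1 / 6 + 1 / 18)
  expect_equal(unname(fit$se), se, tolerance = 1e-6)
  expect_equal(unname(fit$ci95[, "lower"]), exp(log(5.25) - 1.96 * se),
               tolerance = 1e-6)
  expect_equal(unname(fit$ci95[, "upper"]), exp(log(5.25) + 1.96 * se),
               tolerance = 1e-6)
  expect_equal(round(unname(fit$ci95[, "lower"]), 2), 1.83)
  expect_equal(round(unname(fit$ci95[, "upper"]), 2), 15.02)
  # score equations vanish at the optimum
  p <- fitted(fit$glm)
  expect_lt(max(abs(c(sum(d$y - p), sum((d$y - p) * d$x)))), 1e-8)
})

test_that("null and true coefficients are recovered within 3 SE", {
  set.seed(17)
  n <- 1e4
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.4)                  # independent of x
  fit <- fit_logistic(data.frame(x = x), y)
  expect_lt(abs(unname(fit$beta)) / unname(fit$se), 3)
  # parameter recovery at n = 1e5
  n <- 1e5
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  pr <- plogis(-3.5 + 2.5 * x1 + 1.5 * x2)
  yy <- rbinom(n, 1, pr)
  fit2 <- fit_logistic(data.frame(x1 = x1, x2 = x2), yy)
  expect_lt(abs(fit2$beta[["x1"]] - 2.5) / fit2$se[["x1"]], 3)
  expect_lt(abs(fit2$beta[["x2"]] - 1.5) / fit2$se[["x2"]], 3)
  expect_lt(abs(fit2$intercept + 3.5) / fit2$intercept_se, 3)
})

test_that("degenerate designs are detected", {
  d <- make_2x2_data(20, 5, 4, 20)
  expect_error(fit_logistic(data.frame(x = d$x, x2 = d$x), d$y),
               class = "collinearity_error")
  expect_error(fit_logistic(data.frame(x = rep(1, nrow(d))), d$y),
               class = "collinearity_error")
  # perfect separation flagged, not raised
  sep <- data.frame(x = rep(c(1, 0), c(10, 10)))
  ysep <- rep(c(1, 0), c(10, 10))
  fit <- fit_logistic(sep, ysep)
  expect_false(fit$converged)
  expect_true(fit$separation)
})

test_that("forest table mirrors the fit", {
  d <- make_2x2_data(30, 20, 10, 25)
  d$z <- rbinom(nrow(d), 1, 0.5)
  fit <- fit_logistic(d[, c("x", "z")], d$y)
  tab <- or_forest_table(fit)
  expect_equal(tab$predictor[1:2], c("x", "z"))   # design order
  expect_equal(tab$or[1:2], unname(exp(fit$beta)), tolerance = 1e-12)
  # Wald p within an order of magnitude of the likelihood-ratio p
  g0 <- glm(y ~ z, binomial(), data = d)
  lrt_p <- pchisq(g0$deviance - fit$glm$deviance, 1, lower.tail = FALSE)
  expect_lt(abs(log10(tab$p_value[1]) - log10(lrt_p)), 1)
  expect_error(or_forest_table(list()), class = "state_error")
})

test_that("nomogram scoring equals direct logistic evaluation", {
  set.seed(18)
  n <- 400
  X <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5),
                  c = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-2 + 2 * X$a + 1.2 * X$b + 0.7 * X$c))
  fit <- fit_logistic(X, y)
  nomo <- build_nomogram(fit)
  # exactly one predictor attains 100 points
  expect_equal(sum(abs(nomo$full_scale_points - 100) < 1e-9), 1)
  expect_equal(max(nomo$full_scale_points), 100)
  # scoring equals plogis(eta) on the full lattice and random rows
  lattice <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  sc <- score_nomogram(nomo, lattice)
  eta <- fit$intercept + as.matrix(lattice) %*% fit$beta
  expect_equal(sc$probability, as.numeric(plogis(eta)), tolerance = 1e-9)
  sc2 <- score_nomogram(nomo, X[sample(n, 100), ])
  expect_equal(length(sc2$probability), 100)
  # scaling all betas x2 leaves the points assignment unchanged
  fit2 <- fit
  fit2$beta <- 2 * fit$beta
  nomo2 <- build_nomogram(fit2)
  expect_equal(nomo2$full_scale_points, nomo$full_scale_points,
               tolerance = 1e-12)
  # monotonicity: each extra positive predictor raises the probability
  probs <- score_nomogram(nomo, data.frame(a = c(0, 1, 1, 1),
                                           b = c(0, 0, 1, 1),
                                           c = c(0, 0, 0, 1)))$probability
  expect_true(all(diff(probs) > 0))
  expect_error(score_nomogram(nomo, c(a = 1, b = 0, q = 2)),
               class = "schema_error")
  expect_error(score_nomogram(nomo, data.frame(a = 1)),
               class = "schema_error")
})

test_that("c_index is the rank AUC and matches the pairwise oracle", {
  y <- c(0, 0, 1, 1)
  expect_equal(c_index(c(0.1, 0.2, 0.8, 0.9), y), 1)
  set.seed(19)
  p <- runif(40); yy <- rbinom(40, 1, 0.5)
  expect_equal(c_index(p, yy), oracle_auc(p, yy), tolerance = 1e-12)
  expect_equal(c_index(p, yy), roc_auc(p, yy)$auc)
  expect_error(c_index(p, rep(1, 40)), class = "degenerate_labels_error")
})

test_that("response_nomogram composes fit, retention and scoring", {
  set.seed(20)
  n <- 300
  d <- data.frame(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5),
                  x3 = rbinom(n, 1, 0.5))
  d$outcome <- ifelse(rbinom(n, 1, plogis(-1.5 + 1.8 * d$x1 + 1.2 * d$x2)),
                      "responsive", "unresponsive")
  m <- response_nomogram(outcome ~ x1 + x2 + x3, d)
  expect_s3_class(m, "response_nomogram")
  expect_true(all(c("x1", "x2") %in% m$retained))
  expect_equal(predict(m, d[1:10, ], type = "prob"),
               unname(fitted(m$retained_fit$glm)[1:10]), tolerance = 1e-9)
  expect_equal(unname(coef(m))[-1], unname(m$retained_fit$beta))
  expect_gt(m$c_index, 0.5)
  # simulate is seed-reproducible and residuals have glm length
  s1 <- simulate(m, nsim = 2, seed = 4)
  s2 <- simulate(m, nsim = 2, seed = 4)
  expect_identical(s1, s2)
  expect_length(residuals(m), n)
  expect_output(print(m), "retained predictors")
  expect_output(print(summary(m)), "C-index")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("separated designs fall back to a parsimonious LRT subset", {
  set.seed(22)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x_sep <- y                          # separates perfectly: not a candidate
  x_good <- y
  flip <- sample(n, 12)
  x_good[flip] <- 1 - x_good[flip]    # informative, all four cells occupied
  x_noise <- rbinom(n, 1, 0.5)
  d <- data.frame(x_sep = x_sep, x_good = x_good, x_noise = x_noise,
                  outcome = y)
  m <- response_nomogram(outcome ~ x_sep + x_good + x_noise, d)
  expect_false(m$full$converged)
  expect_true(m$retained_fit$converged)
  expect_true("x_good" %in% m$retained)
  expect_false("x_sep" %in% m$retained)
  expect_match(m$note, "separated")
})
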