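# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# Sort-and-interpolate percentile (inclusive convention, index (n-1)q/100).
oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q / 100
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# All-pairs Mann-Whitney AUC: mean of 1 / 0.5 / 0 over positive-negative
# score pairs.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive threshold scan for the maximal Youden index over both
# directions and every midpoint between adjacent distinct scores.
oracle_max_youden <- function(scores, y) {
  us <- sort(unique(scores))
  thr <- (head(us, -1) + tail(us, -1)) / 2
  best <- -Inf
  for (t in thr) {
    j_gt <- mean(scores[y == 1] > t) + mean(scores[y == 0] <= t) - 1
    best <- max(best, j_gt, -j_gt)
  }
  best
}

# Pearson chi-squared by the textbook closed form n(ad-bc)^2 / products of
# the margins.
oracle_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Analytic mean of a Rician(nu, sigma) variable:
# sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2)), with the Laguerre
# polynomial L_{1/2} expressed through Bessel functions.
oracle_rician_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  l12 <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l12
}

# Grid search for the least-squares T2 with S0 profiled in closed form.
oracle_grid_t2 <- function(signals, te, grid = seq(1, 500, by = 0.01)) {
  sse <- vapply(grid, function(t2) {
    e <- exp(-te / t2)
    s0 <- sum(signals * e) / sum(e * e)
    sum((signals - s0 * e)^2)
  }, 0)
  grid[which.min(sse)]
}

# ICC mean squares via R's anova machinery (independent of the package's
# explicit sums-of-squares implementation).
oracle_icc2_1 <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(r = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  a <- anova(stats::aov(r ~ subj + rater, data = d))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# A small noiseless cohort configuration used by several suites.
tiny_config <- function(...) {
  phantom_config(n_patients = 4, seed = 42, ...)
}
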