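## Cutoff selection, dichotomisation, univariate association tests and
## inter-reader agreement.

#' Rank-estimator AUC with DeLong confidence interval
#'
#' AUC by the Mann-Whitney estimator (half credit for ties) with a
#' normal-approximation confidence interval from DeLong's variance of the
#' paired placements, and a two-sided p-value for the null AUC = 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary outcome (0/1, logical, two-level factor, or
#'   `"responsive"`/`"unresponsive"`; the second is the positive class only
#'   for plain two-level factors).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `ci_lower`, `ci_upper`, `se` and `p_value`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- as_binary_outcome(labels)
  if (length(scores) != length(y))
    stop_t2("scores and labels must have the same length", "shape_error")
  x1 <- scores[y == 1]; x0 <- scores[y == 0]
  n1 <- length(x1); n0 <- length(x0)
  r <- rank(c(x1, x0))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements: psi(X, Y) = 1[X > Y] + 0.5 * 1[X == Y]
  v10 <- vapply(x1, function(s) mean(s > x0) + 0.5 * mean(s == x0), 0)
  v01 <- vapply(x0, function(s) mean(x1 > s) + 0.5 * mean(x1 == s), 0)
  se <- sqrt(max(0, var(v10) / n1 + var(v01) / n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  list(auc = auc,
       ci_lower = max(0, auc - z * se),
       ci_upper = min(1, auc + z * se),
       se = se, p_value = p)
}

#' Youden index from sensitivity and specificity percentages
#'
#' `J = (sensitivity + specificity) / 100 - 1`, reported to 3 decimals.
#'
#' @param sensitivity_pct,specificity_pct Percentages in `[0, 100]`.
#' @return Youden index, rounded to 3 decimals.
#' @examples
#' youden_index(76.56, 63.87)  # 0.404
#' @export
youden_index <- function(sensitivity_pct, specificity_pct) {
  if (any(sensitivity_pct < 0 | sensitivity_pct > 100 |
          specificity_pct < 0 | specificity_pct > 100))
    stop_t2("sensitivity and specificity must lie in [0, 100]",
            "domain_error")
  round((sensitivity_pct + specificity_pct) / 100 - 1, 3)
}

#' Youden-index-optimal cutoff of a continuous score
#'
#' Scans all midpoints between adjacent distinct scores and returns the
#' cutoff maximising `J = sensitivity + specificity - 1`. The direction is
#' chosen so that the positive (responsive) class lies on the enriched side
#' (`"greater"`: positive iff value > cutoff; `"less_equal"`: positive iff
#' value <= cutoff). Ties are broken toward the smallest cutoff, and toward
#' `"greater"` between directions.
#'
#' @inheritParams roc_auc
#' @param feature Optional feature name recorded in the result.
#' @return Object of class `cutoff_result`: `feature`, `auc`, `ci_lower`,
#'   `ci_upper`, `p_value`, `cutoff`, `direction`, `sensitivity`,
#'   `specificity` (percent) and `youden` (unrounded, so that
#'   `youden == (sensitivity + specificity) / 100 - 1` exactly).
#' @export
youden_cutoff <- function(scores, labels, feature = "score") {
  y <- as_binary_outcome(labels)
  roc <- roc_auc(scores, y)
  x1 <- scores[y == 1]; x0 <- scores[y == 0]
  us <- sort(unique(scores))
  if (length(us) < 2L)
    stop_t2("scores are constant: no cutoff exists", "degenerate_labels_error")
  thr <- (us[-length(us)] + us[-1]) / 2
  sens_gt <- vapply(thr, function(t) mean(x1 > t), 0)
  spec_gt <- vapply(thr, function(t) mean(x0 <= t), 0)
  j_gt <- sens_gt + spec_gt - 1
  j_le <- -j_gt
  best_gt <- max(j_gt); best_le <- max(j_le)
  if (best_gt >= best_le) {
    i <- which(j_gt == best_gt)[1L]           # smallest cutoff on ties
    res <- list(cutoff = thr[i], direction = "greater",
                sensitivity = 100 * sens_gt[i], specificity = 100 * spec_gt[i])
  } else {
    i <- which(j_le == best_le)[1L]
    res <- list(cutoff = thr[i], direction = "less_equal",
                sensitivity = 100 * (1 - sens_gt[i]),
                specificity = 100 * (1 - spec_gt[i]))
  }
  structure(c(list(feature = feature, auc = roc$auc,
                   ci_lower = roc$ci_lower, ci_upper = roc$ci_upper,
                   p_value = roc$p_value),
              res,
              list(youden = (res$sensitivity + res$specificity) / 100 - 1)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<="
  cat(sprintf("%s: AUC %.3f (%.3f-%.3f, p = %.3g); cutoff %s%.4g, sens %.1f%%, spec %.1f%%, Youden %.3f\n",
              x$feature, x$auc, x$ci_lower, x$ci_upper, x$p_value, op,
              x$cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Dichotomise continuous features at their cutoffs
#'
#' Flags are 1 iff the value strictly exceeds the cutoff when the direction
#' is `"greater"`, and iff the value is `<=` the cutoff when the direction
#' is `"less_equal"` (mirroring the ">88.1" / "<=56.25" convention of
#' published cutoff tables). Idempotent on already-binary tables when flags
#' are re-cut at 0.5 with direction `"greater"`.
#'
#' @param features Data frame containing the feature columns.
#' @param cutoffs A list of [youden_cutoff()] results (or a data frame with
#'   columns `feature`, `cutoff`, `direction`).
#' @return `features` with the cut columns replaced by 0/1 integer flags.
#' @export
dichotomize <- function(features, cutoffs) {
  if (is.data.frame(cutoffs))
    cutoffs <- lapply(seq_len(nrow(cutoffs)), function(i) as.list(cutoffs[i, ]))
  out <- features
  for (cr in cutoffs) {
    f <- cr$feature
    if (is.null(f) || !f %in% names(out))
      stop_t2(sprintf("no feature column for cutoff '%s'", f %||% "<unnamed>"),
              "configuration_error")
    out[[f]] <- if (cr$direction == "greater")
      as.integer(out[[f]] > cr$cutoff) else as.integer(out[[f]] <= cr$cutoff)
  }
  out
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' Uncorrected by default (Yates continuity correction available via
#' `correct = TRUE`), with the p-value from the 1-df chi-squared survival
#' function.
#'
#' @param tab A 2x2 matrix of counts (rows = exposure category, columns =
#'   outcome), or a length-4 vector `c(a, b, c, d)` filled row-wise.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `p_value`, `df` and the `table`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (!identical(dim(tab), c(2L, 2L)))
    stop_t2("a 2x2 table is required", "shape_error")
  if (any(tab < 0) || sum(tab) <= 0)
    stop_t2("counts must be nonnegative with a positive total", "shape_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_t2("a table margin is zero", "degenerate_table_error")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), table = tab)
}

#' Intraclass correlation coefficient for inter-reader agreement
#'
#' Single-measure ICC from the two-way mean-squares decomposition:
#' `"ICC2_1"` (two-way random effects, absolute agreement; the default) or
#' `"ICC3_1"` (two-way mixed, consistency).
#'
#' @param ratings Numeric matrix or data frame, subjects x raters, no
#'   missing cells.
#' @param type ICC form.
#' @return List with `icc`, `type`, `n`, `k` and the mean squares
#'   (`msr` rows, `msc` columns, `mse` residual).
#' @export
icc_agreement <- function(ratings, type = c("ICC2_1", "ICC3_1")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (k < 2L || n < 3L)
    stop_t2("need >= 2 raters and >= 3 subjects", "incomplete_design_error")
  if (anyNA(x))
    stop_t2("missing cells in the ratings matrix", "incomplete_design_error")
  g <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  sse <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (type == "ICC2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(icc = icc, type = type, n = n, k = k, msr = msr, msc = msc, mse = mse)
}
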