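## Multivariate binary logistic regression, odds ratios, points-based
## nomogram construction/scoring and the concordance index.

#' Fit a binary logistic regression by maximum likelihood
#'
#' Maximum-likelihood fit (iteratively reweighted least squares, via
#' `stats::glm`) with standard errors from the inverse observed information
#' and Wald 95% confidence intervals `exp(beta +/- 1.96 * SE)`. Perfect
#' separation is detected and flagged (`converged = FALSE`) rather than
#' raised as an error; a singular design is an error.
#'
#' @param X Data frame or matrix of numeric predictors (binary 0/1 in the
#'   default pipeline).
#' @param y Binary outcome (see [roc_auc()] for accepted encodings).
#' @return An object of class `logistic_fit`: `predictors`, `beta`, `se`,
#'   `or_`, `ci95` (2-column matrix), `p_value`, `intercept`,
#'   `intercept_se`, `converged`, `separation`, `n_iterations`, and the
#'   underlying `glm` object.
#' @export
fit_logistic <- function(X, y) {
  X <- as.data.frame(X)
  y01 <- as_binary_outcome(y)
  if (nrow(X) != length(y01))
    stop_t2("X and y must have the same number of rows", "shape_error")
  if (any(vapply(X, function(v) length(unique(v)) < 2L, TRUE)))
    stop_t2("constant predictor column in the design", "collinearity_error")
  d <- cbind(data.frame(.y = y01), X)
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = d,
                              control = list(maxit = 100, epsilon = 1e-12)))
  cf <- coef(fit)
  if (anyNA(cf))
    stop_t2(paste("singular design; aliased:",
                  paste(names(cf)[is.na(cf)], collapse = ", ")),
            "collinearity_error")
  Xm <- model.matrix(fit)
  score <- as.vector(crossprod(Xm, y01 - fitted(fit)))
  sm <- summary(fit)$coefficients
  # Boundary / (quasi-)separated fits: coefficients drifting to infinity or
  # exploding standard errors. Finite-sample logistic fits on binary
  # predictors live far below these bounds.
  separation <- max(abs(cf)) > 12 || max(sm[, 2]) > 100 ||
    (any(fitted(fit) > 1 - 1e-8 & y01 == 1) &&
       any(fitted(fit) < 1e-8 & y01 == 0))
  converged <- fit$converged && max(abs(score)) < 1e-8 && !separation
  beta <- cf[-1]; se <- sm[-1, 2]
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  structure(list(predictors = names(beta), beta = beta, se = se,
                 or_ = exp(beta), ci95 = ci, p_value = sm[-1, 4],
                 intercept = unname(cf[1]), intercept_se = sm[1, 2],
                 intercept_p = sm[1, 4],
                 converged = converged, separation = separation,
                 n_iterations = fit$iter, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Binary logistic regression (%d predictors, n = %d)%s\n",
              length(x$beta), length(x$glm$y),
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (x$separation) cat("  warning: perfect separation detected\n")
  print(or_forest_table(x), digits = 4)
  invisible(x)
}

#' Odds-ratio table for a forest plot
#'
#' One row per predictor in design order: odds ratio, Wald 95% CI and Wald
#' p-value, plus the intercept as a final row.
#'
#' @param fit A [fit_logistic()] result.
#' @return Data frame with columns `predictor`, `beta`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
or_forest_table <- function(fit) {
  if (!inherits(fit, "logistic_fit"))
    stop_t2("not a fitted logistic model", "state_error")
  data.frame(
    predictor = c(fit$predictors, "(Intercept)"),
    beta = c(unname(fit$beta), fit$intercept),
    se = c(unname(fit$se), fit$intercept_se),
    or = c(unname(fit$or_), exp(fit$intercept)),
    ci_lower = c(unname(fit$ci95[, "lower"]),
                 exp(fit$intercept - 1.96 * fit$intercept_se)),
    ci_upper = c(unname(fit$ci95[, "upper"]),
                 exp(fit$intercept + 1.96 * fit$intercept_se)),
    p_value = c(unname(fit$p_value), fit$intercept_p),
    stringsAsFactors = FALSE
  )
}

#' Build a points-based nomogram from a fitted logistic model
#'
#' Standard points construction: predictor `i` spanning range `r_i`
#' contributes up to `100 * beta_i * r_i / max_j(beta_j * r_j)` points, so
#' exactly one predictor attains 100 points; the total-points axis maps to
#' probability through the fit's own linear predictor, making nomogram
#' scoring numerically identical to direct logistic evaluation.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param ranges Named numeric vector of predictor ranges (max - min);
#'   defaults to 1 for every predictor (binary design).
#' @return Object of class `nomogram_model`: `points_per_unit` (points for
#'   one unit of each predictor), `scale` (log-odds per 100 points),
#'   `intercept`, `sign_warnings` and the underlying fit.
#' @export
build_nomogram <- function(fit, ranges = NULL) {
  if (!inherits(fit, "logistic_fit"))
    stop_t2("not a fitted logistic model", "state_error")
  if (!fit$converged)
    stop_t2("nomogram requires a converged fit", "state_error")
  if (is.null(ranges)) ranges <- setNames(rep(1, length(fit$beta)),
                                          fit$predictors)
  ranges <- ranges[fit$predictors]
  contrib <- fit$beta * ranges
  sign_warnings <- fit$predictors[contrib <= 0]
  scale <- max(contrib)
  if (scale <= 0)
    stop_t2("no predictor with a positive effect: nomogram undefined",
            "state_error")
  structure(list(points_per_unit = 100 * fit$beta / scale,
                 full_scale_points = 100 * contrib / scale,
                 ranges = ranges, scale = scale,
                 intercept = fit$intercept,
                 sign_warnings = sign_warnings, fit = fit),
            class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat("Nomogram points (full predictor scale):\n")
  pts <- x$full_scale_points
  for (i in seq_along(pts))
    cat(sprintf("  %-24s %6.1f\n", names(pts)[i], pts[i]))
  cat(sprintf("  baseline probability (all zero): %.4f\n",
              plogis(x$intercept)))
  if (length(x$sign_warnings))
    cat("  sign warning (non-positive contribution):",
        paste(x$sign_warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Score a patient on a nomogram
#'
#' @param model A [build_nomogram()] result.
#' @param values Named numeric vector, single-row data frame, or data frame
#'   of predictor values (rows = patients).
#' @return Data frame with `total_points` and `probability`; the
#'   probability equals direct logistic evaluation of the underlying fit.
#' @export
score_nomogram <- function(model, values) {
  if (!inherits(model, "nomogram_model"))
    stop_t2("not a nomogram model", "state_error")
  need <- names(model$points_per_unit)
  if (!is.data.frame(values)) {
    if (is.null(names(values)))
      stop_t2("predictor values must be named", "schema_error")
    extra <- setdiff(names(values), need)
    if (length(extra))
      stop_t2(paste("unknown predictors:", paste(extra, collapse = ", ")),
              "schema_error")
    values <- as.data.frame(as.list(values))
  }
  if (!all(need %in% names(values)))
    stop_t2(paste("missing predictors:",
                  paste(setdiff(need, names(values)), collapse = ", ")),
            "schema_error")
  V <- as.matrix(values[, need, drop = FALSE])
  total <- as.vector(V %*% model$points_per_unit)
  prob <- plogis(model$intercept + model$scale * total / 100)
  data.frame(total_points = total, probability = prob)
}

#' Concordance index of predicted probabilities against binary outcomes
#'
#' For a binary endpoint the C-index is the rank-estimator AUC with half
#' credit for ties.
#'
#' @param probabilities Predicted probabilities (or any monotone score).
#' @param outcomes Binary outcome.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(probabilities, outcomes) {
  roc_auc(probabilities, outcomes)$auc
}

## ---- user-facing modelling interface --------------------------------------

#' Fit a treatment-response nomogram model
#'
#' The package's headline modelling function: fits the full multivariate
#' binary logistic regression of the response label on the (dichotomised)
#' predictors, flags the subset retained at Wald `p < retain_p`, refits on
#' that subset, and builds the points-based nomogram from the refit. The
#' returned object supports `print`, `summary`, `coef`, `predict`, `plot`,
#' `simulate` and `residuals`.
#'
#' When the full model is separated (possible at moderate cohort sizes with
#' many strong dichotomised predictors) its Wald statistics collapse, so the
#' retained subset is instead the top `fallback_k` predictors by
#' single-predictor likelihood-ratio chi-squared, shrunk until the refit
#' converges; the full fit is still reported with its separation flag.
#'
#' @param formula Model formula, e.g. `outcome ~ p95 + skewness + entropy`.
#' @param data Data frame of binary predictors and the outcome.
#' @param retain_p Wald p-value threshold for the retained subset.
#' @param fallback_k Subset size used when the full model is separated.
#' @return Object of class `response_nomogram`: `full` and `retained_fit`
#'   ([fit_logistic()] objects), `retained` (predictor names), `nomogram`
#'   ([build_nomogram()]), `c_index` (apparent, in-sample) and the call.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rbinom(200, 1, 0.5), x2 = rbinom(200, 1, 0.5))
#' d$y <- rbinom(200, 1, plogis(-1 + 1.5 * d$x1 + 1 * d$x2))
#' m <- response_nomogram(y ~ x1 + x2, d)
#' predict(m, d[1:3, ])
#' @export
response_nomogram <- function(formula, data, retain_p = 0.05,
                              fallback_k = 3) {
  mf <- model.frame(formula, data, na.action = na.fail)
  y <- as_binary_outcome(model.response(mf))
  X <- mf[, -1, drop = FALSE]
  full <- fit_logistic(X, y)
  note <- NULL
  if (full$converged) {
    retained <- full$predictors[full$p_value < retain_p]
    if (!length(retained)) {
      retained <- full$predictors[which.min(full$p_value)]
      note <- "no predictor reached the retention threshold; kept the smallest p"
    }
  } else {
    # Separated / non-converged full model: Wald statistics are unusable
    # (Hauck-Donner collapse), so rank predictors by their single-predictor
    # likelihood-ratio chi-squared and keep a parsimonious subset, shrinking
    # it until the refit converges. Flags with an empty 2x2 cell against the
    # outcome (infinite single-predictor MLE) are not candidates.
    cand <- Filter(function(f) {
      x <- X[[f]]
      all(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
            sum(x == 0 & y == 1), sum(x == 0 & y == 0)) > 0)
    }, full$predictors)
    if (!length(cand))
      stop_t2("every dichotomised predictor quasi-separates the outcome",
              "collinearity_error")
    lr <- vapply(cand, function(f) {
      g <- suppressWarnings(glm(y ~ x, binomial(),
                                data = data.frame(y = y, x = X[[f]])))
      g$null.deviance - g$deviance
    }, 0)
    retained <- names(sort(lr, decreasing = TRUE))[seq_len(min(fallback_k,
                                                               length(lr)))]
    note <- paste("full model separated; retained top",
                  length(retained), "predictors by single-predictor LRT")
    while (length(retained) > 1L &&
           !fit_logistic(X[, retained, drop = FALSE], y)$converged)
      retained <- retained[-length(retained)]
  }
  refit <- if (full$converged && length(retained) == length(full$predictors))
             full
           else fit_logistic(X[, retained, drop = FALSE], y)
  nomo <- build_nomogram(refit)
  prob <- unname(fitted(refit$glm))
  structure(list(full = full, retained = retained, retained_fit = refit,
                 nomogram = nomo, c_index = c_index(prob, y),
                 note = note, outcome = y, call = match.call()),
            class = "response_nomogram")
}

#' @export
print.response_nomogram <- function(x, ...) {
  cat("Treatment-response nomogram\n")
  cat("  retained predictors:", paste(x$retained, collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  print(x$nomogram)
  cat(sprintf("  apparent C-index: %.3f\n", x$c_index))
  invisible(x)
}

#' @export
summary.response_nomogram <- function(object, ...) {
  structure(list(full = or_forest_table(object$full),
                 retained = or_forest_table(object$retained_fit),
                 retained_names = object$retained,
                 c_index = object$c_index), class = "summary.response_nomogram")
}

#' @export
print.summary.response_nomogram <- function(x, ...) {
  cat("Full multivariate model:\n"); print(x$full, digits = 4)
  cat("\nRetained model (", paste(x$retained_names, collapse = ", "), "):\n",
      sep = "")
  print(x$retained, digits = 4)
  cat(sprintf("\nApparent C-index: %.3f\n", x$c_index))
  invisible(x)
}

#' @export
coef.response_nomogram <- function(object, ...) {
  c("(Intercept)" = object$retained_fit$intercept, object$retained_fit$beta)
}

#' @export
predict.response_nomogram <- function(object, newdata,
                                      type = c("prob", "points", "link"),
                                      ...) {
  type <- match.arg(type)
  sc <- score_nomogram(object$nomogram, newdata)
  switch(type,
         prob = sc$probability,
         points = sc$total_points,
         link = object$nomogram$intercept +
           object$nomogram$scale * sc$total_points / 100)
}

#' @export
residuals.response_nomogram <- function(object, ...) {
  residuals(object$retained_fit$glm, type = "deviance")
}

#' @export
simulate.response_nomogram <- function(object, nsim = 1, seed = NULL,
                                       newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(newdata)) unname(fitted(object$retained_fit$glm))
       else predict(object, newdata, type = "prob")
  as.data.frame(replicate(nsim, rbinom(length(p), 1, p)))
}

#' Draw the nomogram
#'
#' Base-graphics rendering of the points scale, one axis per retained
#' predictor, the total-points axis and the response-probability axis.
#'
#' @param x A [response_nomogram()] (or `nomogram_model`) object.
#' @param probs Probability ticks drawn on the risk axis.
#' @param ... Unused.
#' @export
plot.response_nomogram <- function(x, probs = c(0.05, 0.1, 0.25, 0.5, 0.75,
                                                0.9, 0.95), ...) {
  nomo <- if (inherits(x, "nomogram_model")) x else x$nomogram
  pts <- nomo$full_scale_points
  k <- length(pts)
  tmax <- max(sum(pmax(pts, 0)), 100)
  op <- par(mar = c(2, 9, 2, 2)); on.exit(par(op))
  plot(NULL, xlim = c(0, tmax), ylim = c(0, k + 3), axes = FALSE,
       xlab = "", ylab = "", main = "Treatment-response nomogram")
  axis(3, at = seq(0, 100, 20), line = -1)
  mtext("Points", side = 2, at = k + 3, las = 1, line = 0.5)
  for (i in seq_len(k)) {
    yy <- k + 2 - i
    segments(0, yy, abs(pts[i]), yy)
    points(c(0, abs(pts[i])), c(yy, yy), pch = 3)
    text(c(0, abs(pts[i])), yy + 0.25, labels = c("0", "1"), cex = 0.8)
    mtext(names(pts)[i], side = 2, at = yy, las = 1, line = 0.5, cex = 0.9)
  }
  segments(0, 1, tmax, 1)
  tt <- pretty(c(0, tmax), 8)
  points(tt, rep(1, length(tt)), pch = 3)
  text(tt, 1.3, labels = tt, cex = 0.8)
  mtext("Total points", side = 2, at = 1, las = 1, line = 0.5)
  tp <- (qlogis_safe(probs) - nomo$intercept) * 100 / nomo$scale
  keep <- tp >= 0 & tp <= tmax
  segments(0, 0, tmax, 0)
  if (any(keep)) {
    points(tp[keep], rep(0, sum(keep)), pch = 3)
    text(tp[keep], -0.35, labels = format(probs[keep]), cex = 0.8, xpd = NA)
  }
  mtext("P(response)", side = 2, at = 0, las = 1, line = 0.5)
  invisible(x)
}

qlogis_safe <- function(p) log(p / (1 - p))
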