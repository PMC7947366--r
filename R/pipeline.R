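## End-to-end pipeline: phantom -> T2 maps -> features -> cutoffs ->
## univariate tests -> logistic model -> nomogram -> per-orbit scores.

#' Pipeline configuration
#'
#' Bundles the per-stage options of [run_pipeline()]. The phantom seed is
#' the single source of randomness for a run.
#'
#' @param phantom A [phantom_config()].
#' @param method,t2_range Relaxometry options ([fit_t2_map()]).
#' @param aggregation,bin_width_ms Feature options ([extract_features()]).
#' @param chi_correct Yates correction flag for the univariate tests.
#' @param icc_type ICC form used when reader agreement is computed.
#' @param retain_p Wald retention threshold for the nomogram model.
#' @param write_nifti Write per-subject NIfTI files into the run directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            method = "loglinear_wls",
                            t2_range = c(1, 500),
                            aggregation = "pooled_all_eoms",
                            bin_width_ms = 1,
                            chi_correct = FALSE,
                            icc_type = "ICC2_1",
                            retain_p = 0.05,
                            write_nifti = TRUE,
                            log_level = c("info", "quiet")) {
  structure(list(phantom = phantom, method = method, t2_range = t2_range,
                 aggregation = aggregation, bin_width_ms = bin_width_ms,
                 chi_correct = chi_correct, icc_type = icc_type,
                 retain_p = retain_p, write_nifti = write_nifti,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

# Schema contract for the features table entering the statistics stages.
features_schema_check <- function(ft) {
  need <- c("patient_id", "outcome", "n_voxels")
  missing <- setdiff(need, names(ft))
  if (length(missing))
    stop_t2(paste("features table is missing required columns:",
                  paste(missing, collapse = ", ")), "schema_error")
  invisible(ft)
}

pipeline_log <- function(state, msg) {
  line <- sprintf("[%s] %s", state$stage, msg)
  if (state$log_level == "info") message(line)
  cat(line, "\n", file = state$logfile, append = TRUE)
}

run_stage <- function(state, stage, fun) {
  state$stage <- stage
  tryCatch(fun(state),
           error = function(e) {
             stop_t2(sprintf("stage '%s' failed: %s", stage,
                             conditionMessage(e)), "pipeline_error")
           })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes phantom simulation, T2 mapping, feature extraction, Youden
#' cutoff selection, chi-squared univariate screening, logistic modelling
#' with nomogram construction, and per-orbit scoring, writing each stage's
#' table to `out_dir` together with a manifest (configuration hash, package
#' version, per-stage row counts). Rerunning with the same configuration
#' reproduces identical tables.
#'
#' @param config A [pipeline_config()] (a bare [phantom_config()] is also
#'   accepted and wrapped with pipeline defaults).
#' @param out_dir Run directory, created if needed.
#' @return Invisibly, a list with the per-stage results (`cohort`,
#'   `features`, `cutoffs`, `univariate`, `model`, `scores`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (inherits(config, "phantom_config"))
    config <- pipeline_config(phantom = config)
  if (!inherits(config, "pipeline_config"))
    stop_t2("config must be a pipeline_config", "configuration_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(c(unclass(config$phantom),
                        config[setdiff(names(config), "phantom")]))
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$hash <- hash
  state$out <- out_dir
  state$log_level <- config$log_level
  state$logfile <- file.path(out_dir, "pipeline.log")
  cat("", file = state$logfile)

  run_stage(state, "phantom", function(s) {
    s$cohort <- simulate_cohort(config$phantom)
    if (config$write_nifti)
      write_cohort_nifti(s$cohort, file.path(s$out, "phantom"))
    pipeline_log(s, sprintf("%d patients simulated (seed %d)",
                            length(s$cohort$patients), config$phantom$seed))
  })

  run_stage(state, "features", function(s) {
    s$features <- cohort_features(s$cohort, method = config$method,
                                  t2_range = config$t2_range,
                                  aggregation = config$aggregation,
                                  bin_width_ms = config$bin_width_ms)
    write_stamped_csv(s$features, file.path(s$out, "features.csv"), s$hash)
    pipeline_log(s, sprintf("%d feature rows", nrow(s$features)))
  })

  run_stage(state, "cutoffs", function(s) {
    ft <- read_stamped_csv(file.path(s$out, "features.csv"), s$hash)
    features_schema_check(ft)
    cols <- intersect(feature_columns(), names(ft))
    s$cutoffs <- lapply(cols, function(f)
      youden_cutoff(ft[[f]], ft$outcome, feature = f))
    names(s$cutoffs) <- cols
    tab2 <- do.call(rbind, lapply(s$cutoffs, function(cr)
      data.frame(feature = cr$feature, auc = cr$auc, ci_lower = cr$ci_lower,
                 ci_upper = cr$ci_upper, p_value = cr$p_value,
                 youden = round(cr$youden, 3), cutoff = cr$cutoff,
                 direction = cr$direction, sensitivity = cr$sensitivity,
                 specificity = cr$specificity)))
    write_stamped_csv(tab2, file.path(s$out, "cutoffs.csv"), s$hash)
    pipeline_log(s, sprintf("%d cutoffs selected", nrow(tab2)))
  })

  run_stage(state, "univariate", function(s) {
    ft <- read_stamped_csv(file.path(s$out, "features.csv"), s$hash)
    flags <- dichotomize(ft, s$cutoffs)
    y <- as_binary_outcome(flags$outcome)
    rows <- list()
    usable <- character(0)
    for (f in names(s$cutoffs)) {
      x <- flags[[f]]
      tab <- matrix(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                      sum(x == 0 & y == 1), sum(x == 0 & y == 0)),
                    2, 2, byrow = TRUE)
      res <- tryCatch(chi_square_2x2(tab, correct = config$chi_correct),
                      degenerate_table_error = function(e) NULL)
      if (is.null(res)) next
      usable <- c(usable, f)
      op <- if (s$cutoffs[[f]]$direction == "greater") ">" else "<="
      rows[[f]] <- data.frame(
        feature = f, level = paste0(op, signif(s$cutoffs[[f]]$cutoff, 6)),
        responsive_high = tab[1, 1], unresponsive_high = tab[1, 2],
        responsive_low = tab[2, 1], unresponsive_low = tab[2, 2],
        pct_responsive_high = round(100 * tab[1, 1] / sum(tab[1, ]), 1),
        pct_responsive_low = round(100 * tab[2, 1] / sum(tab[2, ]), 1),
        statistic = res$statistic, p_value = res$p_value)
    }
    s$flags <- flags
    s$univariate <- do.call(rbind, rows)
    rownames(s$univariate) <- NULL
    write_stamped_csv(s$univariate, file.path(s$out, "univariate.csv"),
                      s$hash)
    s$significant <- s$univariate$feature[s$univariate$p_value < 0.05]
    if (!length(s$significant))
      s$significant <-
        s$univariate$feature[which.min(s$univariate$p_value)]
    pipeline_log(s, sprintf("%d/%d dichotomised features significant",
                            length(s$significant), length(usable)))
  })

  run_stage(state, "model", function(s) {
    X <- s$flags[, s$significant, drop = FALSE]
    # Dichotomised flags can coincide exactly (e.g. adjacent percentiles cut
    # into identical binary vectors); keep the first of each duplicate set.
    dup <- duplicated(as.list(X))
    if (any(dup)) {
      pipeline_log(s, paste("dropping duplicate flag columns:",
                            paste(names(X)[dup], collapse = ", ")))
      X <- X[, !dup, drop = FALSE]
      s$significant <- names(X)
    }
    y <- s$flags$outcome
    fml <- stats::as.formula(paste("outcome ~",
                                   paste(s$significant, collapse = " + ")))
    s$model <- response_nomogram(fml, cbind(X, outcome = y),
                                 retain_p = config$retain_p)
    write_stamped_csv(or_forest_table(s$model$full),
                      file.path(s$out, "model_full.csv"), s$hash)
    write_stamped_csv(or_forest_table(s$model$retained_fit),
                      file.path(s$out, "forest.csv"), s$hash)
    nomo <- s$model$nomogram
    jsonlite::write_json(
      list(predictors = names(nomo$points_per_unit),
           beta = unname(nomo$fit$beta), se = unname(nomo$fit$se),
           ci_lower = unname(nomo$fit$ci95[, "lower"]),
           ci_upper = unname(nomo$fit$ci95[, "upper"]),
           intercept = nomo$intercept,
           points_per_unit = unname(nomo$points_per_unit),
           scale_log_odds_per_100_points = nomo$scale,
           config_hash = s$hash),
      file.path(s$out, "nomogram.json"), auto_unbox = TRUE, digits = NA)
    pipeline_log(s, sprintf("retained: %s (C-index %.3f)",
                            paste(s$model$retained, collapse = ", "),
                            s$model$c_index))
  })

  run_stage(state, "score", function(s) {
    sc <- score_nomogram(s$model$nomogram,
                         s$flags[, s$model$retained, drop = FALSE])
    s$scores <- cbind(s$flags[, c("patient_id", "side", "outcome")], sc)
    write_stamped_csv(s$scores, file.path(s$out, "scores.csv"), s$hash)
    pipeline_log(s, sprintf("%d orbits scored", nrow(s$scores)))
  })

  run_stage(state, "manifest", function(s) {
    manifest <- list(
      config_hash = s$hash,
      package_version = as.character(packageVersion("t2nomo")),
      seed = config$phantom$seed,
      stages = list(phantom = length(s$cohort$patients),
                    features = nrow(s$features),
                    cutoffs = length(s$cutoffs),
                    univariate = nrow(s$univariate),
                    model_retained = s$model$retained,
                    scores = nrow(s$scores)),
      c_index = s$model$c_index)
    jsonlite::write_json(manifest, file.path(s$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log(s, "manifest written")
  })

  invisible(list(cohort = state$cohort, features = state$features,
                 cutoffs = state$cutoffs, univariate = state$univariate,
                 model = state$model, scores = state$scores,
                 manifest = jsonlite::read_json(file.path(out_dir,
                                                          "manifest.json"),
                                                simplifyVector = TRUE)))
}
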