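## Synthetic multi-echo orbital phantom: cohort geometry, ground-truth T2
## fields, echo rendering with magnitude noise, clinical covariates and
## therapy-response labels.

#' Configuration of the synthetic TAO cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a cohort of
#' bilateral TAO patients, a coronal multi-echo acquisition (eight echoes,
#' TE 9.9--79.2 ms), five extraocular-muscle VOIs per orbit, and a
#' three-component ground-truth T2 mixture whose group contrast reproduces
#' the reported feature directions (responders: lower 5th/10th percentiles;
#' higher 75th/90th/95th percentiles, skewness, entropy and inhomogeneity).
#'
#' The voxel-wise T2 of one orbit is drawn from
#' `(1 - w_hi - w_lo) * N(mu, sd) + w_hi * N(mu + tail_shift_ms, tail_sd_ms)
#' + w_lo * N(mu - low_shift_ms, low_sd_ms)`, truncated at positive values.
#' Responders differ from non-responders in three ways: a larger elevated
#' (edema) fraction `w_hi`, a larger low-T2 (fibrotic strand) fraction
#' `w_lo`, and a narrower base component (`base_sd_scale_responder` < 1),
#' i.e. largely normal muscle with focal pathology, against diffusely
#' remodelled tissue in non-responders. Mixture weights are redrawn per
#' orbit from Beta distributions (concentration `fraction_kappa`) and the
#' base mean is jittered per patient and per orbit, so that orbit-level
#' features overlap between groups rather than separating perfectly.
#'
#' @param n_patients Number of bilateral patients (two orbits each).
#' @param responder_fraction Probability that a patient is a responder.
#' @param grid_shape Integer triple, voxel grid of one subject volume.
#' @param voxel_size_mm Numeric triple, voxel spacing in mm.
#' @param echo_times_ms Strictly increasing positive echo times (ms).
#' @param s0_mean Proton-density signal of muscle tissue (arbitrary units).
#' @param noise_model One of `"rician"`, `"gaussian"`, `"none"`.
#' @param snr Signal-to-noise ratio; the noise scale is `s0_mean / snr`.
#' @param t2_base_mean_ms,t2_base_sd_ms Baseline muscle T2 distribution (ms).
#' @param base_sd_scale_responder Multiplier on `t2_base_sd_ms` for the
#'   responder group's base component.
#' @param tail_fraction_responder,tail_fraction_nonresponder Mean fraction of
#'   elevated-T2 (edematous) voxels per orbit, by group.
#' @param tail_shift_ms,tail_sd_ms Location shift and spread of the elevated
#'   component (ms).
#' @param low_fraction_responder,low_fraction_nonresponder Mean fraction of
#'   low-T2 voxels per orbit, by group.
#' @param low_shift_ms,low_sd_ms Location shift (downward) and spread of the
#'   low-T2 component (ms).
#' @param between_patient_sd_ms,between_orbit_sd_ms Biological jitter of the
#'   base T2 mean across patients and orbits (ms).
#' @param fraction_kappa Beta concentration of the per-orbit mixture weights.
#' @param seed Integer master seed; all cohort randomness derives from it.
#' @return An object of class `phantom_config`.
#' @seealso [simulate_cohort()], [render_echoes()]
#' @export
phantom_config <- function(n_patients = 45L,
                           responder_fraction = 24 / 45,
                           grid_shape = c(22L, 14L, 8L),
                           voxel_size_mm = c(0.7, 0.7, 3.6),
                           echo_times_ms = seq(9.9, 79.2, by = 9.9),
                           s0_mean = 1000,
                           noise_model = c("rician", "gaussian", "none"),
                           snr = 100,
                           t2_base_mean_ms = 68,
                           t2_base_sd_ms = 10,
                           base_sd_scale_responder = 0.2,
                           tail_fraction_responder = 0.30,
                           tail_fraction_nonresponder = 0.02,
                           tail_shift_ms = 30,
                           tail_sd_ms = 16,
                           low_fraction_responder = 0.22,
                           low_fraction_nonresponder = 0.02,
                           low_shift_ms = 22,
                           low_sd_ms = 9,
                           between_patient_sd_ms = 3,
                           between_orbit_sd_ms = 2.5,
                           fraction_kappa = 30,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_patients = as.integer(n_patients),
    responder_fraction = responder_fraction,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    echo_times_ms = as.numeric(echo_times_ms),
    s0_mean = s0_mean,
    noise_model = noise_model,
    snr = snr,
    t2_base_mean_ms = t2_base_mean_ms,
    t2_base_sd_ms = t2_base_sd_ms,
    base_sd_scale_responder = base_sd_scale_responder,
    tail_fraction_responder = tail_fraction_responder,
    tail_fraction_nonresponder = tail_fraction_nonresponder,
    tail_shift_ms = tail_shift_ms,
    tail_sd_ms = tail_sd_ms,
    low_fraction_responder = low_fraction_responder,
    low_fraction_nonresponder = low_fraction_nonresponder,
    low_shift_ms = low_shift_ms,
    low_sd_ms = low_sd_ms,
    between_patient_sd_ms = between_patient_sd_ms,
    between_orbit_sd_ms = between_orbit_sd_ms,
    fraction_kappa = fraction_kappa,
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  te <- cfg$echo_times_ms
  if (length(te) < 3L || any(te <= 0) || any(diff(te) <= 0))
    stop_t2("echo_times_ms must be strictly increasing and positive",
            "parameter_error")
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
    stop_t2("responder_fraction must lie in [0, 1]", "parameter_error")
  if (cfg$snr <= 0) stop_t2("snr must be positive", "parameter_error")
  pos <- c(cfg$t2_base_mean_ms, cfg$t2_base_sd_ms, cfg$tail_shift_ms,
           cfg$tail_sd_ms, cfg$low_shift_ms, cfg$low_sd_ms,
           cfg$base_sd_scale_responder)
  if (any(pos <= 0)) stop_t2("all T2 parameters must be positive",
                             "parameter_error")
  if (cfg$tail_fraction_responder < cfg$tail_fraction_nonresponder)
    stop_t2("tail_fraction_responder must be >= tail_fraction_nonresponder",
            "parameter_error")
  fr <- c(cfg$tail_fraction_responder, cfg$tail_fraction_nonresponder,
          cfg$low_fraction_responder, cfg$low_fraction_nonresponder)
  if (any(fr < 0) || any(fr >= 1))
    stop_t2("mixture fractions must lie in [0, 1)", "parameter_error")
  if (cfg$n_patients < 1L) stop_t2("n_patients must be >= 1",
                                   "parameter_error")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Synthetic TAO cohort configuration\n")
  cat(sprintf("  %d bilateral patients, responder fraction %.3f, seed %d\n",
              x$n_patients, x$responder_fraction, x$seed))
  cat(sprintf("  grid %s, %d echoes (TE %.1f-%.1f ms), noise %s (SNR %g)\n",
              paste(x$grid_shape, collapse = "x"), length(x$echo_times_ms),
              min(x$echo_times_ms), max(x$echo_times_ms), x$noise_model,
              x$snr))
  invisible(x)
}

## ---- VOI geometry ---------------------------------------------------------

eom_muscles <- c("superior-group", "inferior", "medial", "lateral",
                 "superior-oblique")

#' Template VOI mask for one bilateral subject
#'
#' Places five axis-aligned boxes (3 x 3 x 5 voxels) per orbit on a fixed
#' template: the four recti around the orbit centre plus the superior
#' oblique on the superior-medial diagonal. The superior rectus and levator
#' are represented by one "superior-group" label. No anatomical realism is
#' attempted; downstream features depend only on voxel value distributions.
#'
#' @param grid_shape Integer triple; must be at least 22 x 14 x 8.
#' @return A list with `labels` (3D integer array, 0 = background, 1--10 =
#'   muscles) and `label_table` (data frame: `label`, `muscle`, `side`).
#' @export
voi_template <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L)
    stop_t2("grid_shape must have three dimensions", "geometry_error")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  half <- c(1L, 1L, 2L)                       # box half-extents -> 3 x 3 x 5
  offs <- list(`superior-group` = c(0L, 4L), inferior = c(0L, -4L),
               medial = c(4L, 0L), lateral = c(-4L, 0L),
               `superior-oblique` = c(3L, 3L))
  cx_left <- 6L
  cx_right <- nx - 5L
  cy <- as.integer(ceiling(ny / 2))
  cz <- as.integer(ceiling(nz / 2))
  span_x <- max(abs(unlist(lapply(offs, `[`, 1)))) + half[1]
  span_y <- max(abs(unlist(lapply(offs, `[`, 2)))) + half[2]
  if (cx_left - span_x < 1L || cx_right + span_x > nx ||
      cx_right - span_x <= cx_left + span_x ||
      cy - span_y < 1L || cy + span_y > ny ||
      cz - half[3] < 1L || cz + half[3] > nz)
    stop_t2(sprintf("grid %s too small to place 10 VOIs (need >= 22 x 14 x 8)",
                    paste(grid_shape, collapse = "x")), "geometry_error")

  labels <- array(0L, dim = grid_shape)
  tab <- data.frame(label = integer(0), muscle = character(0),
                    side = character(0), stringsAsFactors = FALSE)
  lab <- 0L
  for (side in c("left", "right")) {
    cx <- if (side == "left") cx_left else cx_right
    sgn <- if (side == "left") 1L else -1L    # mirror x offsets
    for (m in eom_muscles) {
      lab <- lab + 1L
      dx <- sgn * offs[[m]][1]; dy <- offs[[m]][2]
      labels[(cx + dx - half[1]):(cx + dx + half[1]),
             (cy + dy - half[2]):(cy + dy + half[2]),
             (cz - half[3]):(cz + half[3])] <- lab
      tab <- rbind(tab, data.frame(label = lab, muscle = m, side = side,
                                   stringsAsFactors = FALSE))
    }
  }
  list(labels = labels, label_table = tab)
}

## ---- ground-truth T2 fields ----------------------------------------------

# Draw n voxel T2 values from the three-component mixture, truncated > 0.
draw_t2_mixture <- function(n, base_mean, base_sd, w_hi, tail_shift, tail_sd,
                            w_lo, low_shift, low_sd) {
  u <- runif(n)
  comp <- ifelse(u < w_hi, 2L, ifelse(u < w_hi + w_lo, 3L, 1L))
  mu <- c(base_mean, base_mean + tail_shift, base_mean - low_shift)[comp]
  sdv <- c(base_sd, tail_sd, low_sd)[comp]
  x <- rnorm(n, mu, sdv)
  bad <- which(x <= 0)
  while (length(bad)) {                       # truncation at > 0
    x[bad] <- rnorm(length(bad), mu[bad], sdv[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

# Per-orbit mixture parameters for a latent group, drawn around group means.
orbit_mixture_params <- function(cfg, responder, patient_shift) {
  kap <- cfg$fraction_kappa
  rbeta_mean <- function(mu) {
    if (mu <= 0) return(0)
    rbeta(1, mu * kap, (1 - mu) * kap)
  }
  w_hi <- rbeta_mean(if (responder) cfg$tail_fraction_responder
                     else cfg$tail_fraction_nonresponder)
  w_lo <- rbeta_mean(if (responder) cfg$low_fraction_responder
                     else cfg$low_fraction_nonresponder)
  if (w_hi + w_lo > 0.9) {                    # keep a genuine base component
    s <- 0.9 / (w_hi + w_lo)
    w_hi <- w_hi * s; w_lo <- w_lo * s
  }
  list(
    base_mean = cfg$t2_base_mean_ms + patient_shift +
      rnorm(1, 0, cfg$between_orbit_sd_ms),
    base_sd = cfg$t2_base_sd_ms *
      (if (responder) cfg$base_sd_scale_responder else 1),
    w_hi = w_hi, w_lo = w_lo
  )
}

## ---- echo rendering -------------------------------------------------------

#' Render a multi-echo stack from ground-truth T2 and proton density
#'
#' Evaluates the mono-exponential signal model `S(TE) = S0 * exp(-TE / T2)`
#' at each echo time and optionally adds magnitude (Rician) or Gaussian
#' noise with scale `s0_ref / snr`.
#'
#' @param t2_volume 3D array of T2 values (ms); must be positive wherever
#'   `s0_volume` is positive.
#' @param s0_volume 3D array of proton-density signal (0 outside tissue).
#' @param echo_times_ms Echo times (ms).
#' @param noise_model `"none"`, `"rician"` or `"gaussian"`.
#' @param snr Signal-to-noise ratio (> 0) for the noisy models.
#' @param s0_ref Reference signal defining the noise scale `s0_ref / snr`;
#'   defaults to the mean positive value of `s0_volume`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [simulate_cohort()]'s per-patient substreams).
#' @return A 4D array (x, y, z, echo) with `echo_times_ms` attached as an
#'   attribute, i.e. a multi-echo volume.
#' @export
render_echoes <- function(t2_volume, s0_volume, echo_times_ms,
                          noise_model = c("none", "rician", "gaussian"),
                          snr = Inf, s0_ref = NULL, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!identical(dim(t2_volume), dim(s0_volume)))
    stop_t2("t2_volume and s0_volume dimensions differ", "shape_error")
  if (any(s0_volume > 0 & t2_volume <= 0))
    stop_t2("t2_volume must be positive wherever s0_volume is positive",
            "parameter_error")
  if (noise_model != "none" && (!is.finite(snr) || snr <= 0))
    stop_t2("snr must be positive and finite for noisy models",
            "parameter_error")
  if (!is.null(seed)) set.seed(as.integer(seed))

  dims <- dim(t2_volume)
  nE <- length(echo_times_ms)
  out <- array(0, dim = c(dims, nE))
  idx <- which(s0_volume > 0)
  nvox <- prod(dims)
  for (e in seq_len(nE)) {
    sl <- numeric(nvox)
    sl[idx] <- s0_volume[idx] * exp(-echo_times_ms[e] / t2_volume[idx])
    out[(e - 1L) * nvox + seq_len(nvox)] <- sl
  }
  if (noise_model != "none") {
    sigma <- (s0_ref %||% mean(s0_volume[s0_volume > 0])) / snr
    n <- length(out)
    if (noise_model == "gaussian") {
      out <- out + rnorm(n, 0, sigma)
    } else {
      out <- sqrt((out + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    }
    out <- array(out, dim = c(dims, nE))
  }
  attr(out, "echo_times_ms") <- as.numeric(echo_times_ms)
  out
}

## ---- therapy response -----------------------------------------------------

# A no-change per-eye therapy delta.
null_delta <- function() {
  list(cas_change = 0L, diplopia_grade_change = 0L, motility_change_deg = 0,
       exophthalmos_change_mm = 0, soft_tissue_improved = FALSE,
       visual_acuity_change_snellen = 0, lid_width_change_mm = 0,
       diplopia_improved = FALSE)
}

count_criteria <- function(d) {
  major <- sum(d$cas_change <= -2,
               d$diplopia_grade_change <= -1,
               d$motility_change_deg >= 8)
  minor <- sum(d$exophthalmos_change_mm <= -2,
               isTRUE(d$soft_tissue_improved),
               d$visual_acuity_change_snellen >= 1.0,
               d$cas_change == -1,
               d$lid_width_change_mm <= -2,
               isTRUE(d$diplopia_improved))
  c(major = major, minor = minor)
}

#' Classify therapy response from per-eye pre/post changes
#'
#' Applies the three-major / six-minor criteria: major = CAS improvement of
#' at least 2 points, diplopia improvement of at least 1 grade, motility
#' improvement of at least 8 degrees; minor = exophthalmos reduction of at
#' least 2 mm, soft-tissue remission, visual-acuity improvement of at least
#' 1.0 Snellen, CAS decrease of exactly 1 point, lid-width reduction of at
#' least 2 mm, diplopia improvement. A patient is `"responsive"` iff at
#' least one major or at least two minor criteria are met in any eye.
#'
#' Sign convention: improvements are negative changes for CAS, diplopia
#' grade, exophthalmos and lid width, positive changes for motility and
#' visual acuity.
#'
#' @param deltas A single per-eye delta (a list with the fields of
#'   `null_delta`) or a list of one or two such deltas (both eyes).
#' @return `"responsive"` or `"unresponsive"`.
#' @export
classify_response <- function(deltas) {
  if (!is.null(deltas$cas_change)) deltas <- list(deltas)
  required <- names(null_delta())
  for (d in deltas) {
    if (!all(required %in% names(d)))
      stop_t2(paste("therapy delta missing fields:",
                    paste(setdiff(required, names(d)), collapse = ", ")),
              "schema_error")
    k <- count_criteria(d)
    if (k["major"] >= 1 || k["minor"] >= 2) return("responsive")
  }
  "unresponsive"
}

# Draw a per-eye delta for a responding eye: guaranteed >= 1 major.
draw_delta_responder <- function() {
  d <- null_delta()
  major <- sample.int(3L, 1L, prob = c(0.7, 0.15, 0.15))
  if (major == 1L) {
    d$cas_change <- -sample(2:4, 1L, prob = c(0.6, 0.3, 0.1))
  } else if (major == 2L) {
    d$diplopia_grade_change <- -1L
    d$diplopia_improved <- TRUE
  } else {
    d$motility_change_deg <- 8 + round(rexp(1, 1 / 4))
  }
  if (runif(1) < 0.5) d$exophthalmos_change_mm <- -(2 + round(runif(1, 0, 2)))
  if (runif(1) < 0.4) d$soft_tissue_improved <- TRUE
  if (d$cas_change == 0L && runif(1) < 0.5) d$cas_change <- -1L
  d
}

# Draw a per-eye delta for a non-responding eye: at most one minor, no major.
draw_delta_nonresponder <- function() {
  d <- null_delta()
  if (runif(1) < 0.5) {                       # exactly one minor criterion
    pick <- sample.int(4L, 1L)
    if (pick == 1L) d$cas_change <- -1L
    if (pick == 2L) d$soft_tissue_improved <- TRUE
    if (pick == 3L) d$exophthalmos_change_mm <- -2
    if (pick == 4L) d$diplopia_improved <- TRUE
  }
  d$motility_change_deg <- sample(0:7, 1L)    # sub-threshold changes
  d$visual_acuity_change_snellen <- round(runif(1, 0, 0.5), 1)
  d
}

## ---- clinical covariates --------------------------------------------------

# One patient's baseline clinical record (cohort-level marginals of an
# active moderate-to-severe TAO population).
draw_clinical <- function(patient_id) {
  age <- round(min(80, max(18, rnorm(1, 48.1, 11))))
  data.frame(
    patient_id = patient_id,
    age = age,
    gender = sample(c("female", "male"), 1L, prob = c(25, 20)),
    thyroid_status = sample(c("euthyroid", "hyperthyroid", "hypothyroid"),
                            1L, prob = c(19, 14, 12)),
    trab_abnormal = runif(1) < 36 / 45,
    cas = sample(3:7, 1L, prob = c(0.35, 0.35, 0.18, 0.08, 0.04)),
    duration_months = round(min(60, rexp(1, 1 / 7) + 1), 1),
    proptosis_mm = round(max(12, rnorm(1, 19, 2.9)), 1),
    intraocular_pressure_mmHg = round(max(8, rnorm(1, 19.2, 3.6)), 1),
    stringsAsFactors = FALSE
  )
}

## ---- cohort simulation ----------------------------------------------------

#' Simulate a synthetic bilateral TAO cohort
#'
#' Generates, per patient: a VOI mask (five muscles per orbit), a
#' ground-truth voxel-wise T2 volume, the rendered multi-echo signal stack,
#' a baseline clinical record, per-eye therapy deltas and the resulting
#' response label. The label is obtained by passing the generated deltas
#' through [classify_response()], so labels and criteria are mutually
#' consistent by construction. All randomness flows from `config$seed`
#' through one counter-based substream per patient, so cohorts are
#' bit-reproducible and per-patient reproducible.
#'
#' @param config A [phantom_config()].
#' @return An object of class `tao_cohort`: a list with `config`,
#'   `label_table` and `patients` (one list per patient holding
#'   `patient_id`, `echoes` (4D array with `echo_times_ms` attribute),
#'   `mask`, `truth_t2`, `clinical`, `deltas` (left/right) and `outcome`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop_t2("config must be a phantom_config", "parameter_error")
  tmpl <- voi_template(config$grid_shape)
  labs <- tmpl$labels
  ltab <- tmpl$label_table
  lab_idx <- lapply(seq_len(nrow(ltab)), function(i) which(labs == ltab$label[i]))

  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%03d", i)
    responder <- runif(1) < config$responder_fraction

    truth <- array(0, dim = config$grid_shape)
    patient_shift <- rnorm(1, 0, config$between_patient_sd_ms)
    for (side in c("left", "right")) {
      pars <- orbit_mixture_params(config, responder, patient_shift)
      rows <- which(ltab$side == side)
      for (r in rows) {
        idx <- lab_idx[[r]]
        truth[idx] <- draw_t2_mixture(length(idx), pars$base_mean,
                                      pars$base_sd, pars$w_hi,
                                      config$tail_shift_ms, config$tail_sd_ms,
                                      pars$w_lo, config$low_shift_ms,
                                      config$low_sd_ms)
      }
    }
    s0 <- array(0, dim = config$grid_shape)
    s0[labs > 0] <- config$s0_mean
    echoes <- render_echoes(truth, s0, config$echo_times_ms,
                            noise_model = config$noise_model,
                            snr = config$snr, s0_ref = config$s0_mean)

    clinical <- draw_clinical(pid)
    if (responder) {
      left <- draw_delta_responder()
      right <- if (runif(1) < 0.6) draw_delta_responder()
               else draw_delta_nonresponder()
    } else {
      left <- draw_delta_nonresponder()
      right <- draw_delta_nonresponder()
    }
    if (runif(1) < 0.5) { tmp <- left; left <- right; right <- tmp }
    deltas <- list(left = left, right = right)
    outcome <- classify_response(deltas)

    patients[[i]] <- list(patient_id = pid, echoes = echoes, mask = labs,
                          truth_t2 = truth, clinical = clinical,
                          deltas = deltas, outcome = outcome)
  }
  structure(list(config = config, label_table = ltab, patients = patients),
            class = "tao_cohort")
}

#' @export
print.tao_cohort <- function(x, ...) {
  out <- vapply(x$patients, `[[`, character(1), "outcome")
  cat(sprintf("Synthetic TAO cohort: %d patients (%d orbits), %d responsive / %d unresponsive\n",
              length(x$patients), 2L * length(x$patients),
              sum(out == "responsive"), sum(out == "unresponsive")))
  invisible(x)
}

#' Cohort clinical and outcome table
#'
#' @param cohort A `tao_cohort`.
#' @return Data frame, one row per patient, with the baseline clinical
#'   record and the therapy-response label.
#' @export
cohort_clinical <- function(cohort) {
  df <- do.call(rbind, lapply(cohort$patients, `[[`, "clinical"))
  df$outcome <- vapply(cohort$patients, `[[`, character(1), "outcome")
  df
}
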