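## NIfTI-1 + JSON-sidecar I/O for phantom subjects and T2 maps.
##
## Contract: per subject, a 4D echo stack (4th axis = echo) and a 3D
## integer VOI mask as NIfTI-1 with identity affine in voxel space, plus a
## JSON sidecar holding echo_times_ms and the label table. Arrays are
## written as float64 / int32 so write-then-read round trips are bit-exact.

#' Write a synthetic cohort to disk
#'
#' Per patient: `<id>_echoes.nii.gz` (4D), `<id>_mask.nii.gz` (3D integer),
#' `<id>_t2truth.nii.gz` and `<id>.json` (echo times, label table, outcome);
#' plus a cohort-level `clinical.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    base <- file.path(dir, p$patient_id)
    RNifti::writeNifti(p$echoes, paste0(base, "_echoes.nii.gz"),
                       datatype = "double")
    RNifti::writeNifti(p$mask, paste0(base, "_mask.nii.gz"),
                       datatype = "int32")
    RNifti::writeNifti(p$truth_t2, paste0(base, "_t2truth.nii.gz"),
                       datatype = "double")
    sidecar <- list(patient_id = p$patient_id,
                    echo_times_ms = attr(p$echoes, "echo_times_ms"),
                    label_table = cohort$label_table,
                    outcome = p$outcome)
    jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  write.csv(cohort_clinical(cohort), file.path(dir, "clinical.csv"),
            row.names = FALSE)
  invisible(dir)
}

read_sidecar <- function(path) {
  if (!file.exists(path))
    stop_t2(paste("sidecar not found:", path), "metadata_error")
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(sc$echo_times_ms))
    stop_t2(paste("echo_times_ms missing from sidecar", path),
            "metadata_error")
  sc
}

#' Read a multi-echo stack and its JSON sidecar
#'
#' @param prefix Path prefix of one subject, i.e. `<prefix>_echoes.nii.gz`
#'   and `<prefix>.json` as written by [write_cohort_nifti()].
#' @return List with `echoes` (4D array, `echo_times_ms` attribute
#'   attached), `echo_times_ms` and the full `sidecar`.
#' @export
read_echo_stack <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_echoes.nii.gz"))
  sc <- read_sidecar(paste0(prefix, ".json"))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop_t2("echo stack must be 4D", "shape_error")
  if (dim(arr)[4] != length(sc$echo_times_ms))
    stop_t2(sprintf("stack has %d volumes but sidecar lists %d echo times",
                    dim(arr)[4], length(sc$echo_times_ms)), "shape_error")
  attr(arr, "echo_times_ms") <- as.numeric(sc$echo_times_ms)
  list(echoes = arr, echo_times_ms = as.numeric(sc$echo_times_ms),
       sidecar = sc)
}

#' Read a VOI mask and validate it against the sidecar label table
#'
#' @param prefix Subject path prefix (expects `<prefix>_mask.nii.gz` and
#'   `<prefix>.json`).
#' @return List with `labels` (3D integer array) and `label_table`.
#' @export
read_voi_mask <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  sc <- read_sidecar(paste0(prefix, ".json"))
  labels <- array(as.integer(img), dim = dim(img))
  tab <- as.data.frame(sc$label_table)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, tab$label)
  if (length(unknown))
    stop_t2(paste("mask labels absent from the sidecar label table:",
                  paste(unknown, collapse = ", ")), "label_table_error")
  list(labels = labels, label_table = tab)
}

#' Write a fitted T2 map as NIfTI volumes
#'
#' Writes `<prefix>_t2.nii.gz`, `<prefix>_r2.nii.gz` (invalid voxels as
#' zero) and `<prefix>_valid.nii.gz`.
#'
#' @param t2map A [fit_t2_map()] result.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_t2map <- function(t2map, prefix) {
  t2 <- t2map$t2_ms; t2[!t2map$valid] <- 0
  r2 <- t2map$r_squared; r2[!t2map$valid] <- 0
  RNifti::writeNifti(t2, paste0(prefix, "_t2.nii.gz"), datatype = "double")
  RNifti::writeNifti(r2, paste0(prefix, "_r2.nii.gz"), datatype = "double")
  RNifti::writeNifti(array(as.integer(t2map$valid), dim = dim(t2)),
                     paste0(prefix, "_valid.nii.gz"), datatype = "int32")
  invisible(prefix)
}

# Stamped CSV interchange: every pipeline table carries the config hash so
# stages from different runs cannot be mixed silently.
write_stamped_csv <- function(df, path, hash) {
  df$config_hash <- hash
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path, hash = NULL) {
  if (!file.exists(path))
    stop_t2(paste("missing pipeline table:", path), "configuration_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(hash) && !is.null(df$config_hash) &&
      !all(df$config_hash == hash))
    stop_t2(paste("config hash mismatch in", path,
                  "- table comes from a different run"), "configuration_error")
  df$config_hash <- NULL
  df
}
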