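## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers (and tests) can distinguish failure modes.
stop_t2 <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "t2nomo_error", "error"),
                      call = call))
}

# Coerce an outcome vector to 0/1, erroring unless exactly two classes.
as_binary_outcome <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (identical(lv, c("responsive", "unresponsive"))) {
      labels <- as.integer(labels == "responsive")
    } else if (length(lv) == 2L) {
      labels <- as.integer(labels == lv[2L])
    } else {
      stop_t2("outcome labels must have exactly two classes",
              "degenerate_labels_error")
    }
  }
  y <- as.integer(labels)
  if (anyNA(y)) stop_t2("outcome labels contain NA", "degenerate_labels_error")
  if (!all(y %in% c(0L, 1L)))
    stop_t2("outcome labels must be binary", "degenerate_labels_error")
  if (length(unique(y)) < 2L)
    stop_t2("only one outcome class present", "degenerate_labels_error")
  y
}

# Deterministic per-patient substream: one integer master seed, one counter.
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

# MD5 of a configuration (canonical JSON), used to stamp pipeline outputs.
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
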