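## Voxel-wise mono-exponential T2 estimation from a multi-echo stack.
##
## Model: S(TE) = S0 * exp(-TE / T2). The default estimator is weighted
## log-linear least squares (weights = signal^2, the delta-method weights
## that make log-domain LS match constant-variance noise in the signal
## domain); a Levenberg nonlinear fit initialised from it is available for
## low-SNR magnitude data.

# Vectorised weighted log-linear fit. S: voxels x echoes matrix.
# Nonpositive-signal rule: one nonpositive echo is dropped (weight 0) when
# >= 3 points remain; >= 2 nonpositive signals invalidate the voxel.
fit_loglinear_matrix <- function(S, te, t2_range = c(1, 500)) {
  nE <- length(te)
  pos <- S > 0
  npos <- rowSums(pos)
  ok <- (nE - npos) <= 1L & npos >= 3L
  w <- ifelse(pos, S * S, 0)
  y <- ifelse(pos, log(pmax(S, .Machine$double.xmin)), 0)
  TE <- matrix(te, nrow(S), nE, byrow = TRUE)
  sw <- rowSums(w)
  swx <- rowSums(w * TE)
  swx2 <- rowSums(w * TE * TE)
  swy <- rowSums(w * y)
  swxy <- rowSums(w * y * TE)
  den <- sw * swx2 - swx * swx
  slope <- (sw * swxy - swx * swy) / den
  intercept <- (swy - slope * swx) / sw
  t2 <- -1 / slope
  s0 <- exp(intercept)
  yhat <- intercept + slope * TE
  ybar <- swy / sw
  ssres <- rowSums(w * (y - yhat)^2)
  sstot <- rowSums(w * (y - ybar)^2)
  r2 <- ifelse(sstot > 0, pmax(0, pmin(1, 1 - ssres / sstot)), NA_real_)
  valid <- ok & is.finite(slope) & slope < 0 &
    is.finite(t2) & t2 >= t2_range[1] & t2 <= t2_range[2]
  t2[!valid] <- NA_real_
  s0[!valid] <- NA_real_
  r2[!valid] <- NA_real_
  list(t2_ms = t2, s0 = s0, r_squared = r2, valid = valid)
}

# Nonlinear least squares for one voxel, initialised from the log-linear
# solution (Levenberg-Marquardt via minpack.lm).
fit_nls_voxel <- function(signals, te, start, t2_range) {
  df <- data.frame(s = signals, te = te)
  fit <- try(minpack.lm::nlsLM(
    s ~ s0 * exp(-te / t2), data = df,
    start = list(s0 = start$s0, t2 = start$t2),
    lower = c(s0 = 0, t2 = t2_range[1] / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- coef(fit)
  res <- signals - cf[["s0"]] * exp(-te / cf[["t2"]])
  sstot <- sum((signals - mean(signals))^2)
  r2 <- if (sstot > 0) max(0, min(1, 1 - sum(res^2) / sstot)) else NA_real_
  list(t2_ms = cf[["t2"]], s0 = cf[["s0"]], r_squared = r2)
}

#' Fit the mono-exponential T2 model to one voxel's echo signals
#'
#' @param signals Signal intensities, one per echo.
#' @param echo_times_ms Echo times (ms), same length as `signals`.
#' @param method `"loglinear_wls"` (weighted least squares of log signal on
#'   TE, weights = signal^2) or `"nls"` (Levenberg minimisation of the
#'   signal-domain sum of squares, initialised from the log-linear fit).
#' @param t2_range Acceptance window (ms); fits outside it are invalid.
#' @return A list with `t2_ms`, `s0`, `r_squared` and `valid`. When the
#'   voxel is invalid (two or more nonpositive signals, fewer than three
#'   usable echoes, or a fit outside `t2_range`) the estimates are `NA` and
#'   `valid` is `FALSE`; no error is thrown.
#' @examples
#' te <- seq(9.9, 79.2, by = 9.9)
#' fit_t2_voxel(1000 * exp(-te / 50), te)
#' @export
fit_t2_voxel <- function(signals, echo_times_ms,
                         method = c("loglinear_wls", "nls"),
                         t2_range = c(1, 500)) {
  method <- match.arg(method)
  if (length(signals) != length(echo_times_ms))
    stop_t2("signals and echo_times_ms must have the same length",
            "shape_error")
  if (length(signals) < 3L)
    stop_t2("need at least 3 echoes", "shape_error")
  ll <- fit_loglinear_matrix(matrix(signals, nrow = 1L), echo_times_ms,
                             t2_range)
  out <- lapply(ll, `[`, 1L)
  if (method == "loglinear_wls") return(out)

  if (sum(signals <= 0) >= 2L || sum(signals > 0) < 3L) return(out)
  start <- if (out$valid) list(t2 = out$t2_ms, s0 = out$s0)
           else list(t2 = 50, s0 = max(signals))
  nl <- fit_nls_voxel(signals, echo_times_ms, start, t2_range)
  if (is.null(nl)) return(out)
  valid <- nl$t2_ms >= t2_range[1] && nl$t2_ms <= t2_range[2]
  list(t2_ms = if (valid) nl$t2_ms else NA_real_,
       s0 = if (valid) nl$s0 else NA_real_,
       r_squared = if (valid) nl$r_squared else NA_real_,
       valid = valid)
}

#' Fit a voxel-wise T2 map over a multi-echo volume
#'
#' Vectorised application of [fit_t2_voxel()] over a 4D stack. With a mask,
#' only in-mask voxels are fitted and everything else is marked invalid;
#' in-mask estimates are identical to the unmasked fit.
#'
#' @param echoes 4D array (x, y, z, echo), e.g. from [render_echoes()] or
#'   [read_echo_stack()]. Echo times are taken from the `echo_times_ms`
#'   attribute unless given explicitly.
#' @param echo_times_ms Echo times (ms); required if `echoes` carries no
#'   `echo_times_ms` attribute.
#' @param mask Optional 3D array; voxels with `mask > 0` are fitted.
#' @param method,t2_range Passed to [fit_t2_voxel()].
#' @return An object of class `t2map`: a list of 3D arrays `t2_ms`, `s0`,
#'   `r_squared` and logical `valid`, plus the fitting metadata.
#' @export
fit_t2_map <- function(echoes, echo_times_ms = NULL, mask = NULL,
                       method = c("loglinear_wls", "nls"),
                       t2_range = c(1, 500)) {
  method <- match.arg(method)
  echo_times_ms <- echo_times_ms %||% attr(echoes, "echo_times_ms")
  if (is.null(echo_times_ms))
    stop_t2("echo times missing: supply echo_times_ms or an attribute",
            "metadata_error")
  dims <- dim(echoes)
  if (length(dims) != 4L)
    stop_t2("echoes must be a 4D array (x, y, z, echo)", "shape_error")
  if (dims[4] != length(echo_times_ms))
    stop_t2(sprintf("4th axis length %d does not match %d echo times",
                    dims[4], length(echo_times_ms)), "shape_error")
  vdim <- dims[1:3]
  nvox <- prod(vdim)
  S <- matrix(echoes, nrow = nvox, ncol = dims[4])
  sel <- if (is.null(mask)) seq_len(nvox) else {
    if (!identical(as.integer(dim(mask)), as.integer(vdim)))
      stop_t2("mask dimensions do not match the volume", "shape_error")
    which(mask > 0)
  }

  t2 <- array(NA_real_, vdim); s0 <- array(NA_real_, vdim)
  r2 <- array(NA_real_, vdim); valid <- array(FALSE, vdim)
  if (length(sel)) {
    if (method == "loglinear_wls") {
      ft <- fit_loglinear_matrix(S[sel, , drop = FALSE], echo_times_ms,
                                 t2_range)
      t2[sel] <- ft$t2_ms; s0[sel] <- ft$s0
      r2[sel] <- ft$r_squared; valid[sel] <- ft$valid
    } else {
      for (v in sel) {
        ft <- fit_t2_voxel(S[v, ], echo_times_ms, method = "nls",
                           t2_range = t2_range)
        t2[v] <- ft$t2_ms; s0[v] <- ft$s0
        r2[v] <- ft$r_squared; valid[v] <- ft$valid
      }
    }
  }
  structure(list(t2_ms = t2, s0 = s0, r_squared = r2, valid = valid,
                 method = method, t2_range = t2_range,
                 echo_times_ms = as.numeric(echo_times_ms)),
            class = "t2map")
}

#' @export
print.t2map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("T2 map (%s): %s voxels, %d valid fits\n", x$method,
              paste(dim(x$t2_ms), collapse = "x"), nv))
  if (nv) cat(sprintf("  T2 median %.1f ms (IQR %.1f-%.1f), acceptance window [%g, %g] ms\n",
                      median(x$t2_ms[x$valid]),
                      quantile(x$t2_ms[x$valid], 0.25),
                      quantile(x$t2_ms[x$valid], 0.75),
                      x$t2_range[1], x$t2_range[2]))
  invisible(x)
}
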