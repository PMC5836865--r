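#' Spoiled gradient echo (SPGR) steady-state signal
#'
#' Evaluates the SPGR signal equation
#' \deqn{S = S_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
#'       \quad E_1 = e^{-TR/T_1},}
#' the forward model used throughout for variable flip angle T1 estimation
#' and for converting dynamic signals to R1 changes.
#'
#' All arguments are vectorized and recycled against each other.
#'
#' @param s0 Equilibrium signal (arbitrary signal units), `s0 >= 0`.
#' @param t1 Longitudinal relaxation time in seconds, `t1 > 0`.
#' @param alpha Flip angle in degrees, in `[0, 180)`.
#' @param tr Repetition time in milliseconds, `tr > 0`.
#' @return Signal in the units of `s0`.
#' @examples
#' spgr_signal(1000, 1.5, 20, 30)
#' @export
spgr_signal <- function(s0, t1, alpha, tr) {
  if (any(!is.finite(t1)) || any(t1 <= 0)) stop("t1 must be positive")
  if (any(!is.finite(tr)) || any(tr <= 0)) stop("tr must be positive")
  if (any(alpha < 0 | alpha >= 180)) stop("alpha must be in [0, 180) degrees")
  a <- alpha * pi / 180
  e1 <- exp(-(tr / 1000) / t1)
  s0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# Invert the SPGR equation for E1 given signal, S0 and flip angle.
# Returns NA where the inversion leaves E1 outside (0, 1).
spgr_invert_e1 <- function(s, s0, alpha) {
  a <- alpha * pi / 180
  e1 <- (s0 * sin(a) - s) / (s0 * sin(a) - s * cos(a))
  e1[!is.finite(e1) | e1 <= 0 | e1 >= 1] <- NA_real_
  e1
}

#' Multi-flip-angle baseline set
#'
#' Bundles the variable flip angle (VFA) volumes acquired before a dynamic
#' series, used to estimate the native T1 (`T10`) and equilibrium signal
#' (`S0`) maps.
#'
#' @param volumes 4D numeric array `x * y * z * n_angles` of signal volumes.
#' @param angles Flip angles in degrees, one per 4th-dimension slab; at least
#'   two distinct angles.
#' @param tr Repetition time in ms.
#' @param te Echo time in ms (metadata only).
#' @return An object of class `vfa_set`.
#' @export
vfa_set <- function(volumes, angles, tr, te = NA_real_) {
  stopifnot(length(dim(volumes)) == 4L, dim(volumes)[4] == length(angles))
  if (length(unique(angles)) < 2L) stop("need at least 2 distinct flip angles")
  stop_if_not_scalar_pos(tr, "tr")
  structure(list(volumes = volumes, angles = as.numeric(angles),
                 tr = tr, te = te),
            class = "vfa_set")
}

#' @export
print.vfa_set <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<vfa_set> %dx%dx%d grid, angles %s deg, TR %.2f ms\n",
              d[1], d[2], d[3], paste(x$angles, collapse = "/"), x$tr))
  invisible(x)
}

#' Variable flip angle T1 fitting
#'
#' Estimates per-voxel native `T10` and `S0` by nonlinear least squares on the
#' SPGR signal equation across flip angles, initialized from the linearized
#' DESPOT1 regression (`S/sin(a)` on `S/tan(a)`). `T10` is constrained to
#' `[0.05, 10]` s.
#'
#' @param vfa A [vfa_set].
#' @param mask Logical/0-1 3D array selecting voxels to fit.
#' @return Object of class `t1_fit`: 3D arrays `t10` (s), `s0` (signal
#'   units), `rss` (residual sum of squares), and logical `ok` flagging voxels
#'   where a fit was obtained. All-zero voxels are flagged failed.
#' @export
fit_vfa_t1 <- function(vfa, mask) {
  stopifnot(inherits(vfa, "vfa_set"))
  dims <- dim(vfa$volumes)[1:3]
  stopifnot(all(dim(mask) == dims))
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("empty mask")
  n_ang <- length(vfa$angles)
  sig <- matrix(vfa$volumes, ncol = n_ang)[idx, , drop = FALSE]

  t10 <- array(NA_real_, dims)
  s0 <- array(NA_real_, dims)
  rss <- array(NA_real_, dims)
  ok <- array(FALSE, dims)

  a_rad <- vfa$angles * pi / 180
  tr_s <- vfa$tr / 1000
  lo <- c(1e-9, 0.05)
  hi <- c(Inf, 10)

  for (i in seq_along(idx)) {
    y <- sig[i, ]
    if (all(y == 0) || any(!is.finite(y)) || any(y < 0)) next
    # DESPOT1 linearization: y/sin(a) = E1 * y/tan(a) + S0 (1 - E1)
    fit_lin <- stats::lm.fit(cbind(1, y / tan(a_rad)), y / sin(a_rad))
    e1 <- min(max(fit_lin$coefficients[2], 1e-8), 1 - 1e-8)
    t1_init <- min(max(-tr_s / log(e1), 0.05), 10)
    s0_init <- max(fit_lin$coefficients[1] / (1 - e1), max(y))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ spgr_signal(s0v, t1v, ang, trv),
        data = list(y = y, ang = vfa$angles, trv = vfa$tr),
        start = list(s0v = s0_init, t1v = t1_init),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    t10[idx[i]] <- cf[["t1v"]]
    s0[idx[i]] <- cf[["s0v"]]
    rss[idx[i]] <- sum(residuals(fit)^2)
    ok[idx[i]] <- TRUE
  }
  structure(list(t10 = t10, s0 = s0, rss = rss, ok = ok),
            class = "t1_fit")
}

#' OE baseline drift model
#'
#' Fits an exponentially time-varying effective flip angle
#' \deqn{\alpha(t) = \alpha_0 (1 + A (1 - e^{-t/\tau}))}
#' to the pre-gas-switch ROI-mean OE signal through the SPGR equation,
#' \eqn{S(t) = \mathrm{SPGR}(S_0, T_{10}, \alpha(t), TR)}. Only pre-event
#' frames enter the residuals; the fitted \eqn{\alpha(t)} is extrapolable over
#' the whole series and is later used voxel-wise when converting OE signals to
#' R1 changes.
#'
#' @param signal ROI-mean signal per frame (full series).
#' @param times Frame times in seconds (t = 0 at first frame).
#' @param n_pre Number of pre-event frames to fit (>= 5).
#' @param t10 ROI-mean native T1 (s), held fixed.
#' @param alpha0 Nominal flip angle (deg).
#' @param tr Repetition time (ms).
#' @return Object of class `drift_model`: `s0`, `a_drift`, `tau_drift`,
#'   `alpha0`, `converged`, and `alpha_of_t(t)` returning the effective flip
#'   angle at time `t`. On a degenerate fit the model falls back to
#'   `a_drift = 0` with a warning.
#' @export
fit_drift_baseline <- function(signal, times, n_pre, t10, alpha0, tr) {
  stopifnot(length(signal) == length(times))
  if (n_pre < 5) stop("need at least 5 pre-event frames")
  y <- signal[seq_len(n_pre)]
  tt <- times[seq_len(n_pre)]

  # S0 start from inverting the nominal-alpha SPGR at the first frame
  e1 <- exp(-(tr / 1000) / t10)
  a0r <- alpha0 * pi / 180
  s0_init <- y[1] * (1 - e1 * cos(a0r)) / (sin(a0r) * (1 - e1))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ spgr_signal(s0v, t10v, alpha0v * (1 + a * (1 - exp(-tt / tau))), trv),
      data = list(y = y, tt = tt, t10v = t10, alpha0v = alpha0, trv = tr),
      start = list(s0v = s0_init, a = 0.01, tau = 200),
      lower = c(1e-9, -0.5, 1),
      upper = c(Inf, 0.5, 1e5),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)

  degenerate <- is.null(fit)
  if (!degenerate) {
    cf <- coef(fit)
    at_bound <- cf[["tau"]] <= 1 + 1e-9 || cf[["tau"]] >= 1e5 - 1e-6 ||
      abs(cf[["a"]]) >= 0.5 - 1e-9
    amax <- alpha0 * (1 + max(0, cf[["a"]]))
    if (at_bound || amax >= 90 || amax <= 0) degenerate <- TRUE
  }
  if (degenerate) {
    warning("degenerate drift fit; falling back to a_drift = 0")
    cf <- c(s0v = s0_init, a = 0, tau = 1)
  }
  a_drift <- unname(cf[["a"]])
  tau_drift <- unname(cf[["tau"]])
  model <- list(
    s0 = unname(cf[["s0v"]]), a_drift = a_drift, tau_drift = tau_drift,
    alpha0 = alpha0, converged = !degenerate,
    alpha_of_t = function(t) alpha0 * (1 + a_drift * (1 - exp(-t / tau_drift))))
  class(model) <- "drift_model"
  model
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "<drift_model> alpha0 %.2f deg, A_drift %.4g, tau %.4g s (%s)\n",
    x$alpha0, x$a_drift, x$tau_drift,
    if (x$converged) "converged" else "fallback"))
  invisible(x)
}

#' Convert a dynamic signal matrix to delta-R1
#'
#' Inverts the SPGR equation frame by frame to obtain `T1(t)`, hence
#' `R1(t) = 1/T1(t)` and `dR1(t) = R1(t) - 1/T10`. Frames where the inversion
#' leaves `E1` outside `(0, 1)` are set to `NA`; voxels with more than 50%
#' such frames are flagged erratic.
#'
#' @param values Voxel x time signal matrix (masked voxels only).
#' @param s0 Per-voxel equilibrium signal (length = rows of `values`).
#' @param t10 Per-voxel native T1 in seconds.
#' @param alpha Flip angle in degrees: scalar (constant, e.g. DCE) or a
#'   vector over frames (drift-corrected OE, from a [fit_drift_baseline]
#'   model's `alpha_of_t`).
#' @param tr Repetition time (ms).
#' @param times Frame times (s).
#' @param event_frame 1-based index of the first post-event frame (injection
#'   or gas switch).
#' @param coords Integer matrix of voxel coordinates (x, y, z), one row per
#'   voxel, 1-based.
#' @param modality `"DCE"` or `"OE"`.
#' @return Object of class `delta_r1_matrix`: `values` (s^-1), `times`,
#'   `event_frame`, `coords`, `modality`, and logical `erratic` per voxel.
#' @export
signal_to_delta_r1 <- function(values, s0, t10, alpha, tr, times,
                               event_frame, coords, modality = c("DCE", "OE")) {
  modality <- match.arg(modality)
  n <- nrow(values); m <- ncol(values)
  stopifnot(length(s0) == n, length(t10) == n, length(times) == m,
            nrow(coords) == n)
  if (event_frame < 1 || event_frame > m) stop("event_frame out of range")
  if (length(alpha) == 1L) alpha <- rep(alpha, m)
  stopifnot(length(alpha) == m)

  alpha_mat <- matrix(alpha, n, m, byrow = TRUE)
  e1 <- spgr_invert_e1(values, s0, alpha_mat)
  t1 <- -(tr / 1000) / log(e1)
  dr1 <- 1 / t1 - 1 / t10
  erratic <- rowMeans(!is.finite(dr1)) > 0.5
  delta_r1_matrix(dr1, times, event_frame, coords, modality, erratic)
}

#' Construct a delta-R1 matrix
#'
#' Container for masked voxel-by-time R1 changes (s^-1) with retained voxel
#' coordinates, frame timing and the event frame. Rows follow the canonical
#' (z, y, x) lexicographic voxel order used across the package.
#'
#' @param values Voxel x time matrix (s^-1).
#' @param times Frame times (s).
#' @param event_frame 1-based first post-event frame.
#' @param coords Voxel coordinate matrix (x, y, z), 1-based.
#' @param modality `"DCE"` or `"OE"`.
#' @param erratic Logical vector flagging unreliable voxels.
#' @return Object of class `delta_r1_matrix`.
#' @export
delta_r1_matrix <- function(values, times, event_frame, coords,
                            modality = c("DCE", "OE"),
                            erratic = rep(FALSE, nrow(values))) {
  modality <- match.arg(modality)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) == nrow(values),
            length(times) == ncol(values), length(erratic) == nrow(values))
  if (event_frame < 1 || event_frame > ncol(values)) {
    stop("event_frame out of range")
  }
  if (anyDuplicated(coords)) stop("duplicate voxel coordinates")
  colnames(coords) <- c("x", "y", "z")
  structure(list(values = values, times = times,
                 event_frame = as.integer(event_frame),
                 coords = coords, modality = modality, erratic = erratic),
            class = "delta_r1_matrix")
}

#' @export
print.delta_r1_matrix <- function(x, ...) {
  cat(sprintf(
    "<delta_r1_matrix> %s: %d voxels x %d frames, event frame %d, %d erratic\n",
    x$modality, nrow(x$values), ncol(x$values), x$event_frame,
    sum(x$erratic)))
  invisible(x)
}

#' Convert a phantom/in-vivo dynamic series to delta-R1 using fitted maps
#'
#' Convenience wrapper: extracts masked voxels from a 4D dynamic series in
#' canonical (z, y, x) order and calls [signal_to_delta_r1] with per-voxel
#' `S0`/`T10` from a [fit_vfa_t1] result and, for OE, the drift-corrected
#' flip angle profile.
#'
#' @param series A `dynamic_series` (see [dynamic_series]).
#' @param t1fit A `t1_fit` from [fit_vfa_t1].
#' @param mask Logical/0-1 3D array.
#' @param drift Optional `drift_model` (OE only); `NULL` uses the nominal
#'   constant flip angle.
#' @return A [delta_r1_matrix]. Voxels where the T1 fit failed are dropped.
#' @export
series_to_delta_r1 <- function(series, t1fit, mask, drift = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(t1fit, "t1_fit"))
  dims <- dim(series$data)[1:3]
  idx <- mask_index(mask)
  keep <- t1fit$ok[idx]
  idx <- idx[keep]
  vals <- matrix(series$data, ncol = dim(series$data)[4])[idx, , drop = FALSE]
  times <- frame_times(series$n_frames, series$frame_interval)
  alpha <- if (is.null(drift)) series$flip_angle else drift$alpha_of_t(times)
  signal_to_delta_r1(
    vals, s0 = t1fit$s0[idx], t10 = t1fit$t10[idx], alpha = alpha,
    tr = series$tr, times = times, event_frame = series$event_frame,
    coords = index_to_coords(idx, dims), modality = series$modality)
}

# Masked linear indices in canonical (z, y, x) lexicographic order: this is
# exactly R's column-major order for an x-fastest array, so which() suffices.
mask_index <- function(mask) {
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("empty mask")
  idx
}

index_to_coords <- function(idx, dims) {
  cbind(x = ((idx - 1L) %% dims[1]) + 1L,
        y = ((idx - 1L) %/% dims[1]) %% dims[2] + 1L,
        z = (idx - 1L) %/% (dims[1] * dims[2]) + 1L)
}

coords_to_index <- function(coords, dims) {
  (coords[, 1] - 1L) + dims[1] * ((coords[, 2] - 1L) +
                                    dims[2] * (coords[, 3] - 1L)) + 1L
}
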