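# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage child seeds derived from one global seed.
# Kept below .Machine$integer.max so set.seed() always accepts them.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

# Frame times in seconds, t = 0 at the first frame.
frame_times <- function(n_frames, frame_interval) {
  (seq_len(n_frames) - 1) * frame_interval
}

# Trapezoid quadrature weights for an arbitrary monotone time grid, so that
# sum(w * y) equals trapezoidal integration of y over t.
trapz_weights <- function(t) {
  m <- length(t)
  stopifnot(m >= 2)
  dt <- diff(t)
  w <- numeric(m)
  w[1] <- dt[1] / 2
  w[m] <- dt[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (dt[-1] + dt[-(m - 1)]) / 2
  w
}

# Row-wise trapezoidal AUC of a voxel x time matrix; non-finite entries are
# replaced by local linear interpolation along the time axis first.
row_trapz <- function(values, t) {
  bad <- !is.finite(values)
  if (any(bad)) {
    for (i in which(rowSums(bad) > 0)) {
      ok <- is.finite(values[i, ])
      if (sum(ok) < 2) stop("voxel has fewer than 2 finite frames")
      values[i, ] <- stats::approx(t[ok], values[i, ok], xout = t,
                                   rule = 2)$y
    }
  }
  drop(values %*% trapz_weights(t))
}

# Per-row (temporal) standard deviation of a voxel x time matrix.
row_sds <- function(x) {
  m <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (m - 1))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
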