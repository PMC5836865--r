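#' Akaike information criterion of a GMM fit
#'
#' `AIC = 2k - 2 lnL` with `k = N_C d + N_C d(d+1)/2 + (N_C - 1)` free
#' parameters (component means, full covariances, mixing weights).
#'
#' @param fit A [fit_gmm] result.
#' @return The AIC value.
#' @export
gmm_aic <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  2 * gmm_n_params(fit$k, fit$d) - 2 * fit$loglik
}

# Free-parameter count of a full-covariance GMM.
gmm_n_params <- function(k, d) {
  k * d + k * d * (d + 1) / 2 + (k - 1)
}

#' Count connected regions of a label volume
#'
#' Sums, over labels `1..N_C`, the number of 26-connected components
#' (3 x 3 x 3 connection kernel) of each label's voxel set.
#'
#' @param map A [build_region_map] object or a 3D integer array (0 =
#'   background).
#' @return Integer component count (0 for an empty map).
#' @export
count_connected_regions <- function(map) {
  vol <- if (inherits(map, "region_map")) map$labels else map
  stopifnot(length(dim(vol)) == 3L)
  count_connected_cpp(as.integer(vol), dim(vol))
}

#' Spatial contiguity z-score of a region map
#'
#' Compares the observed connected-region count with a bootstrap null in
#' which the in-mask labels are redrawn with replacement from the observed
#' label multiset while spatial positions stay fixed — destroying spatial
#' structure but preserving label marginals. The z-score is
#' `(mean_null - observed) / sd_null`, so maps more contiguous than chance
#' give positive z.
#'
#' @param map A [build_region_map] object (at least 2 labels present).
#' @param n_boot Bootstrap realizations.
#' @param seed RNG seed.
#' @return The z-score; `+Inf` with a warning if the null has zero spread.
#' @export
contiguity_zscore <- function(map, n_boot = 100, seed = NULL) {
  stopifnot(inherits(map, "region_map"))
  vol <- map$labels
  idx <- which(vol > 0)
  labels <- vol[idx]
  if (length(unique(labels)) < 2) stop("need at least 2 labels present")
  obs <- count_connected_regions(map)
  nulls <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    v <- vol
    v[idx] <- sample(labels, length(labels), replace = TRUE)
    count_connected_cpp(as.integer(v), dim(v))
  }, numeric(1)))
  s <- sd(nulls)
  if (s == 0) {
    warning("degenerate contiguity null (zero spread); z reported as +Inf")
    return(Inf)
  }
  (mean(nulls) - obs) / s
}

#' Optimal matching of two cluster-center sets
#'
#' Solves the linear assignment problem minimizing the total Euclidean
#' distance between rows of `centers_a` and permuted rows of `centers_b`
#' (Hungarian algorithm; optimal assignment guaranteed).
#'
#' @param centers_a,centers_b Numeric `k x d` matrices, equal `k`.
#' @return List: `perm` (for each row of `centers_a`, the matched row of
#'   `centers_b`) and `cost` (total matched distance).
#' @export
hungarian_match <- function(centers_a, centers_b) {
  centers_a <- as.matrix(centers_a); centers_b <- as.matrix(centers_b)
  if (nrow(centers_a) != nrow(centers_b) ||
      ncol(centers_a) != ncol(centers_b)) {
    stop("center sets must have matching dimensions")
  }
  k <- nrow(centers_a)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    d <- sweep(centers_b, 2, centers_a[i, ])
    cost[i, ] <- sqrt(rowSums(d^2))
  }
  perm <- solve_assignment(cost)
  list(perm = perm, cost = sum(cost[cbind(seq_len(k), perm)]))
}

# Jonker-style shortest-augmenting-path solver for the square assignment
# problem; returns, per row, the assigned column of minimal total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # index 1 is the dummy column/row 0 of the classical formulation
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in which(!used)) {
        if (j == 1L) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assignment[p[j]] <- j - 1L
  assignment
}

#' Silhouette values
#'
#' For each point, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' Euclidean distance to other points of its own label and `b_i` the
#' smallest mean distance to the points of any other label. Points in
#' singleton labels get `s_i = 0`, as do degenerate points with
#' `a_i = b_i = 0`.
#'
#' @param points Numeric matrix (n x d).
#' @param labels Integer/factor labels, at least two distinct.
#' @return Numeric vector of silhouette values in `[-1, 1]`.
#' @export
silhouette_values <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  n <- nrow(points)
  stopifnot(length(labels) == n)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("need at least 2 labels")
  dm <- as.matrix(dist(points))
  s <- numeric(n)
  sizes <- tabulate(labels)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1L) {
      s[i] <- 0
      next
    }
    a <- sum(dm[i, labels == li]) / (sizes[li] - 1)  # excludes self (d=0)
    b <- min(vapply(ulab[ulab != li], function(l) {
      mean(dm[i, labels == l])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Bootstrap cluster-stability analysis
#'
#' For each candidate cluster number, fits a reference GMM, then `n_boot`
#' times resamples the voxels with replacement, refits the GMM with the same
#' restart policy, and matches the realization's cluster centers to the
#' reference centers with the Hungarian algorithm. All `n_boot * N_C`
#' matched centers, labeled by their matched reference cluster, are pooled
#' and silhouette values computed on that pooled center set: values near +1
#' indicate that bootstrap refits reproduce the reference centers (perfect
#' stability), low values that centers wander between reference positions.
#'
#' @param features A [feature_set] or numeric matrix.
#' @param nc_range Integer vector of cluster numbers to assess (each >= 2).
#' @param n_boot Bootstrap realizations.
#' @param n_restarts Restarts per GMM fit (reference and refits).
#' @param seed RNG seed.
#' @return List: `scores` — long data frame (`nc`, `boot`, `cluster`,
#'   `silhouette`); `summary` — per `nc` median/mean silhouette and the
#'   number of failed refits; `reference` — the reference fits.
#'   More than 20% failed refits at any `nc` raises a warning.
#' @export
stability_analysis <- function(features, nc_range, n_boot = 100,
                               n_restarts = 10, seed = NULL) {
  x <- if (inherits(features, "feature_set")) features$x else as.matrix(features)
  n <- nrow(x)
  scores <- list()
  refs <- list()
  summ <- list()
  for (nc in nc_range) {
    ref <- fit_gmm(x, nc, n_restarts, seed = child_seed(seed, 1000L + nc))
    refs[[as.character(nc)]] <- ref
    centers <- matrix(NA_real_, n_boot * nc, ncol(x))
    group <- integer(n_boot * nc)
    boot_id <- integer(n_boot * nc)
    failed <- 0L
    row <- 0L
    for (b in seq_len(n_boot)) {
      sb <- child_seed(seed, nc * 100000L + b)
      idx <- with_seed(sb, sample.int(n, n, replace = TRUE))
      fit <- tryCatch(
        fit_gmm(x[idx, , drop = FALSE], nc, n_restarts,
                seed = child_seed(sb, 7L)),
        error = function(e) NULL)
      if (is.null(fit)) {
        failed <- failed + 1L
        next
      }
      mt <- hungarian_match(ref$means, fit$means)
      centers[row + seq_len(nc), ] <- fit$means[mt$perm, , drop = FALSE]
      group[row + seq_len(nc)] <- seq_len(nc)
      boot_id[row + seq_len(nc)] <- b
      row <- row + nc
    }
    if (failed > 0.2 * n_boot) {
      warning(sprintf("%d/%d bootstrap refits failed at nc = %d",
                      failed, n_boot, nc))
    }
    keep <- seq_len(row)
    sil <- silhouette_values(centers[keep, , drop = FALSE], group[keep])
    scores[[as.character(nc)]] <- data.frame(
      nc = nc, boot = boot_id[keep], cluster = group[keep], silhouette = sil)
    summ[[as.character(nc)]] <- data.frame(
      nc = nc, median_silhouette = median(sil), mean_silhouette = mean(sil),
      n_failed = failed)
  }
  list(scores = do.call(rbind, scores), summary = do.call(rbind, summ),
       reference = refs)
}

#' Select the optimal feature set and cluster number
#'
#' Codifies the model-selection rule over the three metrics: among
#' (feature set, N_C) combinations whose median stability silhouette is at
#' least `s_min` and whose median per-tumor contiguity z-score is at least
#' `z_min`, choose the largest `N_C`; if both feature sets qualify at that
#' `N_C`, take the one with lower AIC there. If no combination qualifies,
#' the most stable combination is returned with a warning.
#'
#' @param report Data frame with one row per (feature set, N_C): columns
#'   `feature_set`, `nc`, `aic`, `z_median` (median over tumors of the
#'   contiguity z-scores), `stability_median`.
#' @param s_min Minimum median stability silhouette.
#' @param z_min Minimum median contiguity z-score.
#' @return List: `feature_set`, `nc`, and `trace` — the annotated report
#'   with the candidate flags and the decision path.
#' @export
select_optimum <- function(report, s_min = 0.8, z_min = 3) {
  req <- c("feature_set", "nc", "aic", "z_median", "stability_median")
  stopifnot(all(req %in% names(report)))
  report$stable <- report$stability_median >= s_min
  report$contiguous <- report$z_median >= z_min
  report$candidate <- report$stable & report$contiguous
  if (!any(report$candidate)) {
    warning("no (feature set, N_C) met both thresholds; ",
            "falling back to the most stable combination")
    i <- which.max(report$stability_median)
    return(list(feature_set = report$feature_set[i], nc = report$nc[i],
                trace = report, fallback = TRUE))
  }
  cand <- report[report$candidate, ]
  nc_star <- max(cand$nc)
  at <- cand[cand$nc == nc_star, ]
  i <- which.min(at$aic)
  list(feature_set = at$feature_set[i], nc = nc_star, trace = report,
       fallback = FALSE)
}
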