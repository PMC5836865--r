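#' Gaussian mixture model fit with random restarts
#'
#' Fits a full-covariance Gaussian mixture by expectation-maximization from
#' `n_restarts` random initializations (means drawn from distinct data
#' points, covariances initialized to the pooled sample covariance, uniform
#' weights) and retains the restart with the highest log-likelihood.
#' Covariances carry a small ridge (`reg` times the mean per-dimension
#' variance) on the diagonal; restarts that still degenerate (singular
#' covariance or emptied component) are discarded. Deterministic given
#' `seed`. Convergence: relative log-likelihood change below `tol` or
#' `max_iter` EM iterations.
#'
#' @param features A [feature_set] or a plain numeric matrix (voxel x d).
#' @param n_clusters Number of mixture components (2..25 is the intended
#'   sweep range; 1 is allowed and gives the closed-form single Gaussian).
#' @param n_restarts Random restarts.
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule.
#' @param reg Relative covariance regularization.
#' @return Object of class `gmm_fit`: `means` (k x d), `covs` (d x d x k),
#'   `weights`, `loglik`, `labels` (argmax responsibility, 1..k), `resp`
#'   (n x k), `k`, `d`, `n`, `n_restarts_ok`, `permutation` (relabeling
#'   applied; identity until [relabel_by_dce_auc]).
#' @export
fit_gmm <- function(features, n_clusters, n_restarts = 10, seed = NULL,
                    max_iter = 500, tol = 1e-7, reg = 1e-6) {
  x <- if (inherits(features, "feature_set")) features$x else as.matrix(features)
  n <- nrow(x); d <- ncol(x)
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (n <= n_clusters) stop("need more voxels than clusters")
  pooled <- cov(x)
  reg_abs <- reg * mean(diag(pooled))
  cov0 <- pooled
  diag(cov0) <- diag(cov0) + reg_abs

  best <- NULL
  n_ok <- 0L
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      means0 <- x[sample.int(n, n_clusters), , drop = FALSE]
      covs0 <- array(cov0, c(d, d, n_clusters))
      fit <- gmm_em_cpp(x, means0, covs0, rep(1 / n_clusters, n_clusters),
                        max_iter, tol, reg_abs)
      if (!fit$ok || !is.finite(fit$loglik)) next
      n_ok <- n_ok + 1L
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) stop("all GMM restarts failed")
  structure(list(
    means = best$means, covs = best$covs, weights = drop(best$weights),
    loglik = best$loglik, resp = best$resp,
    labels = max.col(best$resp, ties.method = "first"),
    k = as.integer(n_clusters), d = d, n = n,
    n_restarts = n_restarts, n_restarts_ok = n_ok,
    permutation = seq_len(n_clusters)),
    class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> k = %d, d = %d, n = %d, loglik = %.3f (%d/%d restarts ok)\n",
              x$k, x$d, x$n, x$loglik, x$n_restarts_ok, x$n_restarts))
  invisible(x)
}

#' Relabel clusters by ascending mean DCE AUC
#'
#' Reorders the mixture components so cluster 1..k run from lowest to
#' highest within-cluster mean DCE AUC, keeping labels comparable across
#' fits. All fields (means, covariances, weights, responsibilities, labels)
#' are permuted consistently; exact ties keep their pre-permutation order.
#' Idempotent.
#'
#' @param fit A [fit_gmm] result.
#' @param auc_dce Per-voxel DCE AUC values aligned with the fit's rows.
#' @return The relabeled `gmm_fit`, with `permutation[j]` = old index of new
#'   cluster `j`.
#' @export
relabel_by_dce_auc <- function(fit, auc_dce) {
  stopifnot(inherits(fit, "gmm_fit"), length(auc_dce) == fit$n)
  mean_auc <- vapply(seq_len(fit$k), function(j) {
    mean(auc_dce[fit$labels == j])
  }, numeric(1))
  mean_auc[is.nan(mean_auc)] <- Inf  # empty clusters sort last, stably
  perm <- order(mean_auc, seq_len(fit$k))  # new j <- old perm[j]
  inv <- integer(fit$k)
  inv[perm] <- seq_len(fit$k)
  fit$means <- fit$means[perm, , drop = FALSE]
  fit$covs <- fit$covs[, , perm, drop = FALSE]
  fit$weights <- fit$weights[perm]
  fit$resp <- fit$resp[, perm, drop = FALSE]
  fit$labels <- inv[fit$labels]
  fit$permutation <- perm
  fit
}

#' Build a 3D region map from cluster labels
#'
#' Transfers per-voxel labels into image space: a 3D integer volume with 0
#' outside the labeled voxel set (off-mask and excluded/erratic voxels) and
#' 1..k inside.
#'
#' @param labels Integer labels per voxel.
#' @param coords Voxel coordinate matrix (x, y, z), 1-based.
#' @param grid Grid shape (x, y, z).
#' @param n_clusters Number of labels in the legend (defaults to max label).
#' @param tumor_id Identifier.
#' @return Object of class `region_map`: `labels` (3D array), `n_clusters`,
#'   `tumor_id`.
#' @export
build_region_map <- function(labels, coords, grid,
                             n_clusters = max(labels), tumor_id = "tumor01") {
  coords <- as.matrix(coords)
  stopifnot(length(labels) == nrow(coords), ncol(coords) == 3L)
  if (any(coords < 1) || any(coords > matrix(grid, nrow(coords), 3,
                                             byrow = TRUE))) {
    stop("coordinates outside grid")
  }
  idx <- coords_to_index(coords, grid)
  if (anyDuplicated(idx)) stop("duplicate voxel coordinates")
  vol <- array(0L, grid)
  vol[idx] <- as.integer(labels)
  structure(list(labels = vol, n_clusters = as.integer(n_clusters),
                 tumor_id = tumor_id),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> '%s': %d labeled voxels, %d clusters, grid %s\n",
              x$tumor_id, sum(x$labels > 0), x$n_clusters,
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

# Labels of a region map at given coordinates
region_map_labels <- function(map, coords) {
  map$labels[coords_to_index(as.matrix(coords), dim(map$labels))]
}

#' Mean within-cluster enhancement curves
#'
#' Per cluster and frame, the mean and standard error of the mean (SEM,
#' SD/sqrt(n); 0 for single-member clusters) of the delta-R1 curves of the
#' member voxels, for both modalities.
#'
#' @param labels Cluster labels per voxel (1..k).
#' @param dce,oe [delta_r1_matrix] objects aligned with `labels`.
#' @param n_clusters Number of clusters (defaults to max label).
#' @return Long data frame: `modality`, `cluster`, `frame`, `time`, `mean`,
#'   `sem`, `n`. Empty clusters are absent from the table.
#' @export
mean_cluster_curves <- function(labels, dce, oe, n_clusters = max(labels)) {
  one <- function(m, modality) {
    do.call(rbind, lapply(seq_len(n_clusters), function(j) {
      rows <- which(labels == j)
      if (length(rows) == 0L) return(NULL)
      v <- m$values[rows, , drop = FALSE]
      mu <- colMeans(v)
      sem <- if (nrow(v) > 1) {
        apply(v, 2, sd) / sqrt(nrow(v))
      } else {
        rep(0, ncol(v))
      }
      data.frame(modality = modality, cluster = j,
                 frame = seq_along(m$times), time = m$times,
                 mean = mu, sem = sem, n = length(rows))
    }))
  }
  rbind(one(dce, "DCE"), one(oe, "OE"))
}
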