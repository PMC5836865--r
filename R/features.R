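#' Feature set container
#'
#' Voxel-by-feature matrix with provenance: the 2-feature AUC set or the
#' principal-component weighting set derived from scaled, concatenated
#' DCE+OE enhancement curves.
#'
#' @param x Numeric matrix (voxel x feature), finite entries.
#' @param names Feature names.
#' @param coords Voxel coordinate matrix (x, y, z), 1-based.
#' @param tumor_id Character vector, tumor id per voxel.
#' @param scale_factor OE scale factor used before concatenation (PCA set).
#' @param pca Optional PCA model: `rotation`, `center`,
#'   `explained_variance` (fractions, non-increasing).
#' @return Object of class `feature_set`.
#' @export
feature_set <- function(x, names, coords, tumor_id = NULL,
                        scale_factor = NULL, pca = NULL) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(names), nrow(coords) == nrow(x))
  if (any(!is.finite(x))) stop("feature matrix must be finite")
  colnames(x) <- names
  structure(list(x = x, names = names, coords = as.matrix(coords),
                 tumor_id = tumor_id %||% rep("tumor01", nrow(x)),
                 scale_factor = scale_factor, pca = pca),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d voxels x %d features (%s), %d tumor(s)\n",
              nrow(x$x), ncol(x$x), paste(x$names, collapse = ", "),
              length(unique(x$tumor_id))))
  invisible(x)
}

#' AUC feature set
#'
#' Two signed features per voxel: the trapezoidal area under the DCE
#' delta-R1 curve over the first `window_dce` seconds post-injection
#' (frames with `0 <= t - t_inj <= window_dce`; no partial-frame
#' interpolation at the endpoint) and under all post-gas-switch OE frames.
#' Signs are preserved so oxygen-refractory (flat or negative OE) voxels are
#' representable; units are s^-1 * s.
#'
#' @param dce,oe [delta_r1_matrix] objects over the same voxels.
#' @param window_dce DCE integration window (s) post injection.
#' @param tumor_id Optional per-voxel tumor id.
#' @return A [feature_set] with features `auc_dce`, `auc_oe`.
#' @export
auc_features <- function(dce, oe, window_dce = 90, tumor_id = NULL) {
  stopifnot(inherits(dce, "delta_r1_matrix"), inherits(oe, "delta_r1_matrix"))
  t_inj <- dce$times[dce$event_frame]
  sel_dce <- which(dce$times - t_inj >= 0 & dce$times - t_inj <= window_dce)
  sel_oe <- which(seq_along(oe$times) >= oe$event_frame)
  if (length(sel_dce) < 2 || length(sel_oe) < 2) {
    stop("fewer than 2 frames in integration window")
  }
  a_dce <- row_trapz(dce$values[, sel_dce, drop = FALSE], dce$times[sel_dce])
  a_oe <- row_trapz(oe$values[, sel_oe, drop = FALSE], oe$times[sel_oe])
  feature_set(cbind(a_dce, a_oe), c("auc_dce", "auc_oe"), dce$coords,
              tumor_id)
}

#' Scale and concatenate DCE and OE curves
#'
#' Rescales the OE curves by `s = mean(per-voxel temporal SD of DCE) /
#' mean(per-voxel temporal SD of OE)` so both modalities contribute equal
#' mean variability, then concatenates each voxel's DCE and scaled OE curve
#' into one composite row.
#'
#' @param dce,oe [delta_r1_matrix] objects — or plain voxel x time matrices
#'   (e.g. rows pooled over a cohort) — over the same voxels.
#' @return List: `composite` (voxel x (n_dce + n_oe) matrix) and
#'   `scale_factor` `s`.
#' @export
scale_and_concatenate <- function(dce, oe) {
  vd <- if (inherits(dce, "delta_r1_matrix")) dce$values else as.matrix(dce)
  vo <- if (inherits(oe, "delta_r1_matrix")) oe$values else as.matrix(oe)
  if (nrow(vd) != nrow(vo)) stop("voxel sets differ")
  mean_sd_oe <- mean(row_sds(vo))
  if (mean_sd_oe <= 0) stop("zero OE temporal variability")
  s <- mean(row_sds(vd)) / mean_sd_oe
  list(composite = cbind(vd, s * vo), scale_factor = s)
}

#' PCA feature set from composite curves
#'
#' Mean-centered principal component analysis over the pooled cohort of
#' voxels' composite DCE+OE curves. Component signs are fixed so that each
#' component's largest-magnitude loading is positive, making the
#' decomposition deterministic.
#'
#' @param composite Voxel x time composite matrix from
#'   [scale_and_concatenate].
#' @param n_components Number of leading components to keep.
#' @param coords Voxel coordinates (x, y, z).
#' @param tumor_id Optional per-voxel tumor id.
#' @param scale_factor OE scale factor, stored as provenance.
#' @return A [feature_set] with features `pc1..pcK`; the `pca` element holds
#'   the component vectors, center, and the explained-variance fractions of
#'   all components (their cumulative sum reaches 1 at full rank).
#' @export
pca_features <- function(composite, n_components = 4, coords,
                         tumor_id = NULL, scale_factor = NULL) {
  composite <- as.matrix(composite)
  n <- nrow(composite)
  if (n < n_components) stop("fewer voxels than components")
  p <- prcomp(composite, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (rank < n_components) stop("data rank below n_components")
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  sco <- p$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  feature_set(sco, paste0("pc", seq_len(n_components)), coords, tumor_id,
              scale_factor = scale_factor,
              pca = list(rotation = rot, center = p$center,
                         explained_variance = ev / sum(ev)))
}
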