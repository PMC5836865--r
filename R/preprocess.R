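#' Exclude erratically enhancing voxels
#'
#' Computes the trapezoidal AUC of the modulus of each voxel's DCE and OE
#' delta-R1 curve over the full series and removes, per modality, the voxels
#' with the highest `ceiling(fraction * N)` modulus-AUCs; the union of the
#' two removal sets is dropped. Voxels flagged erratic upstream (failed
#' signal inversion) are always removed. Ties are broken by the canonical
#' (z, y, x) voxel order, i.e. by row index. Non-finite frames are bridged by
#' local linear interpolation before integration.
#'
#' Re-running the operation on its own output removes further voxels; the
#' exclusion is a one-shot preprocessing step, not an idempotent filter.
#'
#' @param dce,oe [delta_r1_matrix] objects covering the same voxels in the
#'   same order.
#' @param fraction Fraction to remove per modality, in `[0, 0.5)`.
#' @return List: `dce`, `oe` (reduced matrices), `keep` (logical over input
#'   rows), and `report` — a data frame with coordinates (1-based), both
#'   modulus-AUCs and the removal reason for every removed voxel.
#' @export
exclude_erratic_voxels <- function(dce, oe, fraction = 0.01) {
  stopifnot(inherits(dce, "delta_r1_matrix"), inherits(oe, "delta_r1_matrix"))
  if (!isTRUE(all.equal(dce$coords, oe$coords))) {
    stop("dce and oe must cover the same voxels in the same order")
  }
  if (fraction < 0 || fraction >= 0.5) stop("fraction must be in [0, 0.5)")
  n <- nrow(dce$values)

  auc_dce <- row_trapz(abs(dce$values), dce$times)
  auc_oe <- row_trapz(abs(oe$values), oe$times)

  k <- if (fraction > 0) ceiling(fraction * n) else 0L
  top_k <- function(auc) {
    if (k == 0L) return(integer(0))
    order(-auc, seq_len(n))[seq_len(k)]
  }
  rm_dce <- top_k(auc_dce)
  rm_oe <- top_k(auc_oe)
  rm_flag <- which(dce$erratic | oe$erratic)
  removed <- sort(unique(c(rm_dce, rm_oe, rm_flag)))
  keep <- !(seq_len(n) %in% removed)
  if (!any(keep)) stop("exclusion removed every voxel")

  reason <- vapply(removed, function(i) {
    paste(c(if (i %in% rm_dce) "dce_auc", if (i %in% rm_oe) "oe_auc",
            if (i %in% rm_flag) "erratic"), collapse = "+")
  }, character(1))
  report <- data.frame(dce$coords[removed, , drop = FALSE],
                       auc_abs_dce = auc_dce[removed],
                       auc_abs_oe = auc_oe[removed],
                       reason = reason, row.names = NULL)

  subset_dr1 <- function(m) {
    delta_r1_matrix(m$values[keep, , drop = FALSE], m$times, m$event_frame,
                    m$coords[keep, , drop = FALSE], m$modality,
                    m$erratic[keep])
  }
  list(dce = subset_dr1(dce), oe = subset_dr1(oe), keep = keep,
       report = report)
}
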