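#' Threshold-based three-class map (TBM)
#'
#' Reference three-class segmentation from binarized enhancement: per voxel
#' and modality an enhancement call is made by a one-sided Welch t-test of
#' the post-event delta-R1 frames against the pre-event frames (enhancing
#' when `p < alpha_level`). Classes: 1 = DCE non-enhancing (any OE status;
#' necrosis interpretation), 2 = DCE-enhancing / OE-refractory (the
#' putatively hypoxic "perfused Oxy-R" pattern), 3 = enhancing in both.
#'
#' The binarization statistic is configurable via `alpha_level`; the Welch
#' test is this package's documented stand-in for the enhancement call of
#' the original threshold-based scheme.
#'
#' @param dce,oe [delta_r1_matrix] objects over the same voxels.
#' @param grid Grid shape used to embed the map.
#' @param alpha_level One-sided significance threshold per modality.
#' @param tumor_id Identifier.
#' @return A `region_map` with labels in `{0, 1, 2, 3}` and attribute-level
#'   `method = "TBM"`; also carries the per-voxel class vector as
#'   `voxel_class`.
#' @export
tbm_classify <- function(dce, oe, grid, alpha_level = 0.05,
                         tumor_id = "tumor01") {
  stopifnot(inherits(dce, "delta_r1_matrix"), inherits(oe, "delta_r1_matrix"))
  dce_pos <- enhancement_call(dce, alpha_level)
  oe_pos <- enhancement_call(oe, alpha_level)
  cls <- ifelse(!dce_pos, 1L, ifelse(oe_pos, 3L, 2L))
  map <- build_region_map(cls, dce$coords, grid, n_clusters = 3L,
                          tumor_id = tumor_id)
  map$method <- "TBM"
  map$voxel_class <- cls
  map
}

# One-sided Welch t enhancement call per voxel: mean(post) > mean(pre).
enhancement_call <- function(m, alpha_level) {
  pre <- seq_len(m$event_frame - 1)
  post <- seq(m$event_frame, ncol(m$values))
  if (length(pre) < 3) stop("too few pre-event frames for enhancement test")
  welch_p(m$values[, post, drop = FALSE],
          m$values[, pre, drop = FALSE]) < alpha_level
}

# Vectorized one-sided Welch t-test p-values for H1: mean(a) > mean(b),
# rows = voxels, columns = frames. NA frames are ignored per voxel.
welch_p <- function(a, b) {
  na_mean <- function(x) rowMeans(x, na.rm = TRUE)
  na_var <- function(x, mu, n) {
    rowSums((x - mu)^2, na.rm = TRUE) / (n - 1)
  }
  n1 <- rowSums(is.finite(a)); n2 <- rowSums(is.finite(b))
  m1 <- na_mean(a); m2 <- na_mean(b)
  v1 <- na_var(a, m1, n1); v2 <- na_var(b, m2, n2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- pt(tstat, df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p
}

#' Concatenate habitat clusters into three classes
#'
#' Substitutes region-map labels according to a grouping, e.g. the default
#' six-cluster grouping `{1} -> 1, {2,3} -> 2, {4,5,6} -> 3` that merges the
#' modestly DCE-enhancing clusters and the strongly enhancing clusters so a
#' habitat map can be compared against the three-class TBM. For a
#' three-cluster map the default grouping is the identity.
#'
#' @param map A `region_map`.
#' @param grouping List of integer vectors: `grouping[[g]]` holds the input
#'   labels mapped to class `g`. Defaults to [default_grouping] of the map's
#'   cluster count.
#' @return A `region_map` with labels `{0, 1, .., length(grouping)}` and
#'   `method = "ODD-concatenated"`.
#' @export
concatenate_clusters <- function(map, grouping = NULL) {
  stopifnot(inherits(map, "region_map"))
  grouping <- grouping %||% default_grouping(map$n_clusters)
  lut <- integer(map$n_clusters)
  for (g in seq_along(grouping)) lut[grouping[[g]]] <- g
  present <- sort(unique(map$labels[map$labels > 0]))
  if (any(!present %in% unlist(grouping))) {
    stop("map contains labels outside the grouping domain")
  }
  vol <- map$labels
  vol[vol > 0] <- lut[vol[vol > 0]]
  out <- map
  out$labels <- vol
  out$n_clusters <- length(grouping)
  out$method <- "ODD-concatenated"
  out$voxel_class <- NULL
  out
}

#' Default cluster-to-class grouping
#'
#' Identity for three clusters; for six clusters, the canonical grouping
#' `{1}, {2,3}, {4,5,6}` (non-enhancing; modest DCE-only enhancement;
#' strong dual enhancement) justified by the mean within-cluster
#' enhancement curves.
#'
#' @param n_clusters 3 or 6; other counts require an explicit grouping.
#' @return List of integer vectors.
#' @export
default_grouping <- function(n_clusters) {
  if (n_clusters == 3) return(list(1L, 2L, 3L))
  if (n_clusters == 6) return(list(1L, c(2L, 3L), c(4L, 5L, 6L)))
  stop("no default grouping for ", n_clusters,
       " clusters; supply one explicitly")
}

#' Proportional agreement between two label maps
#'
#' Fraction of in-mask voxels assigned the same class by both maps.
#'
#' @param a,b `region_map`s on the same mask, or equal-length label vectors.
#' @return Proportion in `[0, 1]`.
#' @export
proportional_agreement <- function(a, b) {
  v <- aligned_labels(a, b)
  mean(v$a == v$b)
}

#' Cohen's kappa between two label maps
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the proportional agreement and `p_e` the expected agreement from
#' the marginal class frequencies. In the degenerate case `p_e = 1` (both
#' maps constant), kappa is defined as 1 when the maps are identical and 0
#' otherwise, with a warning: chance correction is uninformative when one
#' method yields a single class.
#'
#' @param a,b `region_map`s on the same mask, or equal-length label vectors.
#' @return Kappa (`<= 1`).
#' @export
cohens_kappa <- function(a, b) {
  v <- aligned_labels(a, b)
  n <- length(v$a)
  p_o <- mean(v$a == v$b)
  cls <- sort(unique(c(v$a, v$b)))
  p_e <- sum(vapply(cls, function(c) {
    mean(v$a == c) * mean(v$b == c)
  }, numeric(1)))
  if (p_e >= 1 - 1e-12) {
    warning("both maps are constant; kappa degenerate")
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Confusion matrix and agreement summary of two maps
#'
#' @param a,b `region_map`s on the same mask, or equal-length label vectors.
#' @param classes Class values to tabulate (default: union observed).
#' @return List: `confusion` (a-rows x b-cols), `phi`
#'   (proportional agreement), `kappa`, `n`.
#' @export
compare_maps <- function(a, b, classes = NULL) {
  v <- aligned_labels(a, b)
  classes <- classes %||% sort(unique(c(v$a, v$b)))
  conf <- table(factor(v$a, levels = classes), factor(v$b, levels = classes))
  list(confusion = unclass(conf), phi = proportional_agreement(v$a, v$b),
       kappa = cohens_kappa(v$a, v$b), n = length(v$a))
}

# Extract aligned in-mask label vectors from two maps (or pass vectors).
aligned_labels <- function(a, b) {
  if (inherits(a, "region_map") && inherits(b, "region_map")) {
    ma <- a$labels > 0
    mb <- b$labels > 0
    if (!identical(dim(a$labels), dim(b$labels)) || !identical(ma, mb)) {
      stop("maps are not on the same mask")
    }
    list(a = a$labels[ma], b = b$labels[mb])
  } else {
    a <- as.vector(a); b <- as.vector(b)
    if (length(a) != length(b)) stop("label vectors differ in length")
    list(a = a, b = b)
  }
}

#' Bland-Altman agreement on per-class voxel counts
#'
#' Paired-difference analysis of the number of voxels per class between two
#' methods across tumors: per class, differences `d_i = a - b`, bias =
#' mean(d), 95% limits of agreement = bias +/- 1.96 SD(d), and bias as a
#' percentage of the mean tumor size. With a single pair the limits are
#' undefined (`NA`), bias only.
#'
#' @param counts_a,counts_b Numeric matrices (tumor x class) of voxel
#'   counts, same shape; rows are paired tumors.
#' @param mean_size Mean tumor size (voxels) used for the percentage;
#'   defaults to the mean of the row sums of `counts_a`.
#' @return Data frame per class: `class`, `bias`, `loa_lower`, `loa_upper`,
#'   `pct_of_mean_size`.
#' @export
bland_altman <- function(counts_a, counts_b, mean_size = NULL) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  stopifnot(all(dim(counts_a) == dim(counts_b)))
  n <- nrow(counts_a)
  mean_size <- mean_size %||% mean(rowSums(counts_a))
  d <- counts_a - counts_b
  bias <- colMeans(d)
  sdd <- if (n >= 2) apply(d, 2, sd) else rep(NA_real_, ncol(d))
  data.frame(class = seq_len(ncol(d)),
             bias = bias,
             loa_lower = bias - 1.96 * sdd,
             loa_upper = bias + 1.96 * sdd,
             pct_of_mean_size = bias / mean_size * 100,
             row.names = NULL)
}

#' Composition ratio of two voxel counts
#'
#' Majority-to-minority ratio of voxels contributed by two groups (e.g. two
#' tumor lines) to a set of clusters.
#'
#' @param counts Length-2 numeric vector of voxel counts.
#' @return `max(counts) / min(counts)`.
#' @export
composition_ratio <- function(counts) {
  stopifnot(length(counts) == 2, all(counts > 0))
  unname(max(counts) / min(counts))
}

#' Per-cluster composition by group
#'
#' Cross-tabulates cluster labels against a per-voxel grouping (e.g. tumor
#' line) and reports each cluster's majority ratio.
#'
#' @param labels Cluster labels per voxel.
#' @param group Group membership per voxel (two or more groups).
#' @return List: `counts` (cluster x group table) and, when there are
#'   exactly two groups, `ratio` per cluster.
#' @export
habitat_composition <- function(labels, group) {
  counts <- table(cluster = labels, group = group)
  out <- list(counts = unclass(counts))
  if (ncol(counts) == 2) {
    out$ratio <- apply(counts, 1, function(r) {
      if (min(r) == 0) Inf else max(r) / min(r)
    })
  }
  out
}
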