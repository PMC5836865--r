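test_that("AIC uses the full-covariance GMM parameter count", {
  craft <- function(k, d, loglik) {
    structure(list(k = as.integer(k), d = d, loglik = loglik),
              class = "gmm_fit")
  }
  # parameter counting: means + covariances + weights
  expect_equal(habitatmri:::gmm_n_params(1, 2), 5)
  expect_equal(habitatmri:::gmm_n_params(6, 4), 89)
  # arithmetic: lnL = -100, k = 5 -> AIC = 210
  expect_equal(gmm_aic(craft(1, 2, -100)), 210)
  # AIC decreases when lnL increases at fixed k
  expect_lt(gmm_aic(craft(3, 2, -50)), gmm_aic(craft(3, 2, -80)))
})

test_that("connected-region counting implements 26-connectivity", {
  # one solid single-label ellipsoid
  cfg <- exact_phantom_config()
  vol <- array(0L, cfg$grid)
  vol[render_phantom(cfg, seed = 1)$mask] <- 1L
  expect_equal(count_connected_regions(vol), 1)

  # two diagonal-touching voxels join through a corner
  v <- array(0L, c(3, 3, 3))
  v[1, 1, 1] <- 1L
  v[2, 2, 2] <- 1L
  expect_equal(count_connected_regions(v), 1)
  # different labels never join
  v[2, 2, 2] <- 2L
  expect_equal(count_connected_regions(v), 2)

  # empty map
  expect_equal(count_connected_regions(array(0L, c(4, 4, 4))), 0)

  # random multi-label volumes agree with the union-find oracle
  set.seed(41)
  for (r in 1:20) {
    vol <- array(sample(0:4, 6 * 6 * 4, replace = TRUE), c(6, 6, 4))
    expect_equal(count_connected_regions(vol),
                 oracle_count_components(vol))
  }
})

test_that("contiguity z-scores separate structured from random maps", {
  cfg <- exact_phantom_config()
  ph <- render_phantom(cfg, seed = 2)
  idx <- which(ph$mask)
  coords <- habitatmri:::index_to_coords(idx, cfg$grid)
  true_map <- build_region_map(ph$truth_map[idx], coords, cfg$grid)

  # concentric habitats are far more contiguous than chance
  z_true <- contiguity_zscore(true_map, n_boot = 100, seed = 8)
  expect_gt(z_true, 3)

  # a randomized map is consistent with its own null
  shuf <- withr::with_seed(9, sample(ph$truth_map[idx]))
  z_null <- contiguity_zscore(build_region_map(shuf, coords, cfg$grid),
                              n_boot = 100, seed = 8)
  expect_lt(abs(z_null), 3)

  # determinism and label-permutation invariance
  expect_identical(z_true, contiguity_zscore(true_map, 100, seed = 8))
  perm_lab <- c(3L, 1L, 2L)[ph$truth_map[idx]]
  z_perm <- contiguity_zscore(build_region_map(perm_lab, coords, cfg$grid),
                              n_boot = 100, seed = 8)
  expect_identical(z_true, z_perm)

  expect_error(contiguity_zscore(build_region_map(rep(1L, length(idx)),
                                                  coords, cfg$grid)),
               "2 labels")
})

test_that("Hungarian matching is optimal and invariant to row swaps", {
  # identical sets: identity permutation at zero cost
  a <- matrix(rnorm(8), 4, 2)
  m <- hungarian_match(a, a)
  expect_identical(m$perm, 1:4)
  expect_equal(m$cost, 0)

  # agreement with exhaustive search for k <= 5
  set.seed(42)
  for (k in 2:5) {
    for (r in 1:10) {
      ca <- matrix(rnorm(k * 3), k, 3)
      cb <- matrix(rnorm(k * 3), k, 3)
      got <- hungarian_match(ca, cb)
      cost <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
        sqrt(sum((ca[i, ] - cb[j, ])^2))
      }))
      want <- oracle_assignment(cost)
      expect_equal(got$cost, want$cost, tolerance = 1e-12)
    }
  }

  # swapping two rows of b is compensated at identical cost
  b <- a[c(2, 1, 3, 4), ]
  m2 <- hungarian_match(a, b)
  expect_identical(m2$perm, c(2L, 1L, 3L, 4L))
  expect_equal(m2$cost, 0)

  expect_error(hungarian_match(a, a[1:3, ]), "matching dimensions")
})

test_that("silhouette values match hand computation and invariants", {
  # two tight, far-apart groups: all values near +1
  set.seed(43)
  pts <- rbind(matrix(rnorm(40, 0, 0.01), 20, 2),
               matrix(rnorm(40, 50, 0.01), 20, 2))
  s <- silhouette_values(pts, rep(1:2, each = 20))
  expect_true(all(s > 0.99))
  expect_true(all(s >= -1 & s <= 1))

  # 4-point instance against the direct double-loop oracle
  p4 <- rbind(c(0, 0), c(0, 1), c(4, 0), c(5, 0))
  l4 <- c(1, 1, 2, 2)
  expect_equal(silhouette_values(p4, l4), oracle_silhouette(p4, l4),
               tolerance = 1e-12)
  # explicit hand values for the first point: a = 1, b = (4 + 5)/2
  expect_equal(silhouette_values(p4, l4)[1], (4.5 - 1) / 4.5,
               tolerance = 1e-12)

  # all points identical: a = b = 0 -> s = 0
  same <- matrix(1, 6, 2)
  expect_equal(silhouette_values(same, rep(1:2, 3)), rep(0, 6))

  # singleton label convention: s = 0
  s5 <- silhouette_values(rbind(c(0, 0), c(1, 0), c(9, 9)), c(1, 1, 2))
  expect_equal(s5[3], 0)

  # isometry invariance (rotation + translation)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- pts %*% rot + 100
  expect_equal(silhouette_values(moved, rep(1:2, each = 20)), s,
               tolerance = 1e-10)

  expect_error(silhouette_values(pts, rep(1, 40)), "2 labels")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(44)
  pts <- matrix(rnorm(120), 40, 3)
  lab <- sample(1:3, 40, replace = TRUE)
  ours <- silhouette_values(pts, lab)
  ref <- cluster::silhouette(lab, dist(pts))[, "sil_width"]
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("bootstrap stability is near +1 for separable data and lower otherwise", {
  set.seed(45)
  sep <- rbind(matrix(rnorm(300, 0, 0.5), 150, 2),
               matrix(rnorm(300, 20, 0.5), 150, 2))
  st_sep <- stability_analysis(sep, 2, n_boot = 15, n_restarts = 5, seed = 6)
  expect_gt(st_sep$summary$median_silhouette, 0.95)
  # matched-center groups carry the reference labels
  expect_setequal(unique(st_sep$scores$cluster), 1:2)
  expect_equal(nrow(st_sep$scores), 15 * 2)

  # a single Gaussian offers no support for 4 clusters
  blob <- matrix(rnorm(600), 300, 2)
  st_blob <- stability_analysis(blob, 4, n_boot = 15, n_restarts = 5,
                                seed = 6)
  expect_lt(st_blob$summary$median_silhouette,
            st_sep$summary$median_silhouette - 0.2)

  # determinism
  st_rep <- stability_analysis(sep, 2, n_boot = 15, n_restarts = 5, seed = 6)
  expect_identical(st_rep$scores$silhouette, st_sep$scores$silhouette)
})

test_that("optimum selection applies thresholds, size preference and AIC ties", {
  rep_df <- data.frame(
    feature_set = rep(c("auc", "pca"), each = 4),
    nc = rep(2:5, 2),
    aic = c(100, 90, 80, 70, 95, 85, 75, 65),
    z_median = c(5, 5, 5, 5, 5, 5, 5, 2),
    stability_median = c(0.95, 0.9, 0.7, 0.5, 0.96, 0.92, 0.85, 0.9))
  # pca qualifies at nc = 4 (auc fails stability there); nc = 5 fails z
  sel <- select_optimum(rep_df)
  expect_equal(sel$nc, 4)
  expect_equal(sel$feature_set, "pca")
  expect_false(sel$fallback)

  # tie at the same nc resolves toward lower AIC
  rep_tie <- rep_df
  rep_tie$stability_median <- rep(0.9, 8)
  rep_tie$z_median <- rep(5, 8)
  sel_tie <- select_optimum(rep_tie)
  expect_equal(sel_tie$nc, 5)
  expect_equal(sel_tie$feature_set, "pca")  # aic 65 < 70

  # nothing qualifies: fallback to the most stable combination, with warning
  rep_bad <- rep_df
  rep_bad$stability_median <- c(0.5, 0.4, 0.3, 0.2, 0.6, 0.5, 0.4, 0.3)
  expect_warning(sel_bad <- select_optimum(rep_bad), "fallback|stable")
  expect_true(sel_bad$fallback)
  expect_equal(sel_bad$feature_set, "pca")
  expect_equal(sel_bad$nc, 2)
})
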