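test_that("GMM recovers well-separated components and is deterministic", {
  set.seed(31)
  n <- 400
  truth <- rep(1:2, each = n / 2)
  x <- rbind(matrix(rnorm(n, 0, 1), n / 2, 2),
             matrix(rnorm(n, 10, 1), n / 2, 2))
  fit <- fit_gmm(x, 2, n_restarts = 10, seed = 3)

  # label recovery up to permutation
  acc <- max(mean(fit$labels == truth), mean(fit$labels == 3 - truth))
  expect_gte(acc, 0.999)
  # fitted means recover the component sample means within 0.05 SD
  m <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(m[1, ] - colMeans(x[truth == 1, ]))), 0.05)
  expect_lt(max(abs(m[2, ] - colMeans(x[truth == 2, ]))), 0.05)

  # determinism given seed
  fit2 <- fit_gmm(x, 2, n_restarts = 10, seed = 3)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$labels, fit2$labels)

  # structural invariants
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
  expect_equal(rowSums(fit$resp), rep(1, n), tolerance = 1e-10)
  expect_identical(fit$labels, max.col(fit$resp, ties.method = "first"))
})

test_that("single-component fit equals the closed-form Gaussian MLE", {
  set.seed(32)
  x <- matrix(rnorm(600), 200, 3)
  fit <- fit_gmm(x, 1, n_restarts = 1, seed = 1)
  expect_equal(drop(fit$means), colMeans(x), tolerance = 1e-10)
  # EM fixed point: covariance with denominator n (plus the tiny ridge)
  s_ml <- cov(x) * (nrow(x) - 1) / nrow(x)
  expect_equal(fit$covs[, , 1], s_ml, tolerance = 1e-4)

  # duplicating every voxel leaves parameters unchanged, doubles loglik
  fit2 <- fit_gmm(rbind(x, x), 1, n_restarts = 1, seed = 1)
  expect_equal(drop(fit2$means), drop(fit$means), tolerance = 1e-8)
  expect_equal(fit2$loglik, 2 * fit$loglik, tolerance = 1e-6)
})

test_that("GMM log-likelihood agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(33)
  x <- rbind(matrix(rnorm(300, 0, 1), 150, 2),
             matrix(rnorm(300, 5, 1.5), 150, 2))
  fit <- fit_gmm(x, 2, n_restarts = 10, seed = 2)
  mc <- Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  # same maximum up to convergence tolerance and the diagonal ridge
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
  perm <- hungarian_match(t(mc$parameters$mean), fit$means)$perm
  expect_equal(fit$means[perm, ], unname(t(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("larger mixtures never fit worse on the same data", {
  set.seed(34)
  x <- rbind(matrix(rnorm(300), 150, 2), matrix(rnorm(300, 4), 150, 2))
  ll <- vapply(1:4, function(k) {
    fit_gmm(x, k, n_restarts = 10, seed = 5)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-3))
})

test_that("relabeling orders clusters by mean DCE AUC consistently", {
  set.seed(35)
  n <- 300
  lab <- sample(1:3, n, replace = TRUE)
  x <- cbind(c(5, 1, 3)[lab] + rnorm(n, sd = 0.05), rnorm(n, sd = 0.05))
  fit <- fit_gmm(x, 3, n_restarts = 10, seed = 1)
  auc <- x[, 1]
  rel <- relabel_by_dce_auc(fit, auc)

  # cluster means ascend in DCE AUC after relabeling
  m_auc <- vapply(1:3, function(j) mean(auc[rel$labels == j]), numeric(1))
  expect_true(all(diff(m_auc) > 0))
  # relabeling preserves the likelihood and the partition
  expect_identical(rel$loglik, fit$loglik)
  expect_equal(gmm_aic(rel), gmm_aic(fit))
  # cluster sizes preserved as a multiset
  expect_setequal(as.integer(table(rel$labels)),
                  as.integer(table(fit$labels)))
  # responsibilities stay aligned with labels
  expect_identical(rel$labels, max.col(rel$resp, ties.method = "first"))

  # idempotence
  rel2 <- relabel_by_dce_auc(rel, auc)
  expect_identical(rel2$labels, rel$labels)
  expect_identical(rel2$permutation, seq_len(3L))

  # worked permutation: cluster means (5, 1, 3) -> new order (2, 3, 1)
  craft <- fit
  craft$labels <- lab
  craft$resp <- diag(3)[lab, ]
  rel3 <- relabel_by_dce_auc(craft, c(5, 1, 3)[lab])
  expect_identical(rel3$permutation, c(2L, 3L, 1L))
})

test_that("region maps embed labels exactly and reject duplicates", {
  coords <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(2, 2, 2))
  labels <- c(1L, 2L, 2L, 1L)
  map <- build_region_map(labels, coords, grid = c(2, 2, 2))
  # round trip map -> labels
  expect_identical(habitatmri:::region_map_labels(map, coords), labels)
  expect_equal(sum(map$labels > 0), 4)
  expect_equal(sum(map$labels == 0), 4)

  # checker pattern preserved exactly
  g <- c(4, 4, 1)
  cc <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1))
  lab <- 1L + (cc[, 1] + cc[, 2]) %% 2L
  map2 <- build_region_map(lab, cc, g)
  expect_identical(as.integer(map2$labels[cbind(cc)]), as.integer(lab))

  # single-voxel tumor
  map3 <- build_region_map(1L, cbind(1, 1, 1), c(3, 3, 3))
  expect_equal(sum(map3$labels > 0), 1)

  expect_error(build_region_map(c(1, 2), rbind(c(1, 1, 1), c(1, 1, 1)),
                                c(2, 2, 2)), "duplicate")
  expect_error(build_region_map(1L, cbind(5, 1, 1), c(2, 2, 2)), "grid")
})

test_that("mean cluster curves summarize members with SEM conventions", {
  vals <- rbind(c(1, 2, 3), c(-1, -2, -3), c(5, 5, 5))
  dce <- toy_dr1(vals)
  oe <- toy_dr1(vals, modality = "OE")
  labels <- c(1L, 1L, 2L)
  cur <- mean_cluster_curves(labels, dce, oe, n_clusters = 3)

  # antisymmetric pair averages to zero at every frame
  c1 <- cur[cur$modality == "DCE" & cur$cluster == 1, ]
  expect_equal(c1$mean, c(0, 0, 0))
  expect_equal(c1$sem, apply(vals[1:2, ], 2, sd) / sqrt(2))

  # single-member cluster: SEM 0 by convention
  c2 <- cur[cur$modality == "DCE" & cur$cluster == 2, ]
  expect_equal(c2$sem, c(0, 0, 0))
  expect_equal(c2$mean, c(5, 5, 5))

  # empty cluster absent from the table
  expect_false(any(cur$cluster == 3))
})
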