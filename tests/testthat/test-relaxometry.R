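test_that("SPGR signal equation matches its closed form and limits", {
  # frozen value from arbitrary-precision evaluation of the closed form
  expect_equal(spgr_signal(1000, 1.5, 20, 30), 85.8200860288442,
               tolerance = 1e-12)
  # sin(0) = 0
  expect_equal(spgr_signal(500, 2, 0, 30), 0)
  # TR/T1 -> Inf: full recovery S0 sin(alpha)
  expect_equal(spgr_signal(800, 0.001, 30, 5000), 800 * sin(30 * pi / 180),
               tolerance = 1e-8)
  # strictly increasing in S0
  s <- spgr_signal(c(100, 200, 300), 1.5, 20, 30)
  expect_true(all(diff(s) > 0))
  # invalid inputs
  expect_error(spgr_signal(100, -1, 20, 30), "t1")
  expect_error(spgr_signal(100, 1, 20, -5), "tr")
})

test_that("SPGR signal is consistent with the Ernst relation", {
  # at fixed TR/T1 the signal peaks at the Ernst angle cos(a) = exp(-TR/T1)
  t1 <- 1.5
  tr <- 30
  a_star <- acos(exp(-(tr / 1000) / t1)) * 180 / pi
  a_grid <- seq(0.1, 90, length.out = 20001)
  sig <- spgr_signal(1000, t1, a_grid, tr)
  expect_equal(a_grid[which.max(sig)], a_star, tolerance = 1e-3)
  # and decreases monotonically with T1 at fixed TR/alpha (less recovery)
  sig_t1 <- spgr_signal(1000, seq(0.5, 5, by = 0.1), 15, tr)
  expect_true(all(diff(sig_t1) < 0))
})

test_that("VFA T1 fitting recovers noiseless parameters exactly", {
  cfg <- exact_phantom_config()
  ph <- render_phantom(cfg, seed = 1)
  fit <- fit_vfa_t1(ph$vfa_oe, ph$mask)
  idx <- which(ph$mask)
  t10_true <- vapply(cfg$habitats, function(h) h$t10,
                     numeric(1))[ph$truth_map[idx]]
  expect_true(all(fit$ok[idx]))
  expect_lt(max(abs(fit$t10[idx] - t10_true) / t10_true), 1e-6)
  expect_lt(max(abs(fit$s0[idx] - cfg$s0) / cfg$s0), 1e-6)
})

test_that("VFA fit is scale-equivariant in S0 and flags dead voxels", {
  angles <- c(5, 10, 20)
  sig <- spgr_signal(500, 1.8, angles, 30)
  vols <- array(0, c(2, 1, 1, 3))
  vols[1, 1, 1, ] <- sig
  vols[2, 1, 1, ] <- 3 * sig  # scaled copy
  mask <- array(TRUE, c(2, 1, 1))
  fit <- fit_vfa_t1(vfa_set(vols, angles, 30), mask)
  expect_equal(fit$t10[1, 1, 1], fit$t10[2, 1, 1], tolerance = 1e-8)
  expect_equal(fit$s0[2, 1, 1] / fit$s0[1, 1, 1], 3, tolerance = 1e-8)

  vols[2, 1, 1, ] <- 0  # all-zero voxel must be flagged failed
  fit0 <- fit_vfa_t1(vfa_set(vols, angles, 30), mask)
  expect_false(fit0$ok[2, 1, 1])
  expect_true(fit0$ok[1, 1, 1])
})

test_that("noisy VFA T1 estimates are unbiased within Monte-Carlo bounds", {
  angles <- c(5, 10, 20)
  t1_true <- 1.8
  sig0 <- spgr_signal(500, t1_true, angles, 30)
  n_rep <- 200
  est <- withr::with_seed(11, {
    vapply(seq_len(n_rep), function(r) {
      vols <- array(sig0 + rnorm(3, 0, 2), c(1, 1, 1, 3))
      fit <- fit_vfa_t1(vfa_set(vols, angles, 30), array(TRUE, c(1, 1, 1)))
      fit$t10[1]
    }, numeric(1))
  })
  # Monte-Carlo reference at this SNR/seed: relative bias 1.5%, SD 0.23 s
  expect_lt(abs(mean(est) - t1_true) / t1_true, 0.03)
  expect_lt(sd(est) / t1_true, 0.15)
})

test_that("drift fitting recovers injected drift and ignores post-event data", {
  times <- (0:41) * 28.8
  t10 <- 1.7
  s0 <- 1000
  a_true <- 0.05
  tau_true <- 300
  alpha_t <- 20 * (1 + a_true * (1 - exp(-times / tau_true)))
  sig <- spgr_signal(s0, t10, alpha_t, 30)

  dm <- fit_drift_baseline(sig, times, n_pre = 18, t10 = t10, alpha0 = 20,
                           tr = 30)
  expect_true(dm$converged)
  expect_lt(abs(dm$a_drift - a_true), 1e-6)
  expect_lt(abs(dm$tau_drift - tau_true) / tau_true, 1e-6)

  # post-event frames do not enter the fit
  sig2 <- sig
  sig2[19:42] <- sig2[19:42] * 5
  dm2 <- fit_drift_baseline(sig2, times, 18, t10, 20, 30)
  expect_equal(dm2$a_drift, dm$a_drift, tolerance = 1e-10)
  expect_equal(dm2$tau_drift, dm$tau_drift, tolerance = 1e-10)

  # drift-free input: a_drift ~ 0
  sig3 <- spgr_signal(s0, t10, 20, 30) + numeric(42)
  dm3 <- suppressWarnings(fit_drift_baseline(sig3, times, 18, t10, 20, 30))
  expect_lt(abs(dm3$a_drift), 1e-3)

  expect_error(fit_drift_baseline(sig, times, 3, t10, 20, 30), "pre-event")
})

test_that("signal-to-delta-R1 conversion is the exact SPGR inverse", {
  # constant baseline signal: delta-R1 identically zero
  t10 <- c(1.5, 2)
  s0 <- c(900, 1100)
  base <- spgr_signal(s0, t10, 10, 6.02)
  vals <- matrix(base, 2, 10)
  coords <- cbind(1:2, 1, 1)
  d <- signal_to_delta_r1(vals, s0, t10, 10, 6.02, (0:9) * 5.78, 3, coords)
  expect_lt(max(abs(d$values)), 1e-12)
  expect_false(any(d$erratic))

  # known delta-R1 step round trip
  dr1 <- matrix(0, 2, 10)
  dr1[, 6:10] <- c(1.2, 0.4)
  t1_t <- 1 / (1 / t10 + dr1)
  sig <- spgr_signal(matrix(s0, 2, 10), t1_t, 10, 6.02)
  d2 <- signal_to_delta_r1(sig, s0, t10, 10, 6.02, (0:9) * 5.78, 6, coords)
  expect_lt(max(abs(d2$values - dr1)), 1e-8)

  # unphysical frames are flagged NA, heavily corrupted voxels erratic
  sig3 <- sig
  sig3[1, ] <- 1e6  # far above the SPGR ceiling for this S0
  d3 <- signal_to_delta_r1(sig3, s0, t10, 10, 6.02, (0:9) * 5.78, 6, coords)
  expect_true(d3$erratic[1])
  expect_false(d3$erratic[2])
  expect_true(all(is.na(d3$values[1, ])))
})

test_that("drift correction removes the OE baseline artifact", {
  ph <- render_phantom(uniform_phantom_config(a_drift = 0.05), seed = 3)
  corrected <- phantom_to_dr1(ph, drift_correct = TRUE)
  uncorrected <- phantom_to_dr1(ph, drift_correct = FALSE)
  err_corr <- max(abs(corrected$oe$values - ph$truth_oe_voxel))
  # uncorrected conversion shows a systematic late-series offset
  late <- 30:42
  bias_unc <- mean(abs(uncorrected$oe$values[, late] -
                         ph$truth_oe_voxel[, late]))
  expect_lt(err_corr, 1e-8)
  expect_gt(bias_unc, 100 * err_corr)
})
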