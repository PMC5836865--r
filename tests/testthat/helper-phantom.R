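# Shared phantom configurations for tests.

# Noiseless, drift-free, no biological spread: exact-recovery regime.
exact_phantom_config <- function(...) {
  habs <- default_habitats()
  for (i in seq_along(habs)) {
    habs[[i]]$dce$a_sd <- 0
    habs[[i]]$oe$a_sd <- 0
  }
  phantom_config(noise_sd = 0, drift = list(a_drift = 0, tau_drift = 300),
                 habitats = habs, ...)
}

# Two well-separated habitats (rim/core), parameter-identical voxels.
two_habitat_config <- function(noise_sd = 0, ...) {
  habs <- list(
    list(name = "core",
         rule = list(type = "shell", r_min = 0, r_max = 0.6),
         dce = list(a = 0.3, a_sd = 0, k_in = 2, k_out = 0.1),
         oe = list(a = 0, a_sd = 0, tau = 60, sign = 0),
         t10 = 1.9),
    list(name = "rim",
         rule = list(type = "shell", r_min = 0.6, r_max = 1),
         dce = list(a = 2.5, a_sd = 0, k_in = 3, k_out = 0.2),
         oe = list(a = 0.06, a_sd = 0, tau = 60, sign = 1),
         t10 = 1.6))
  phantom_config(habitats = habs, noise_sd = noise_sd,
                 drift = list(a_drift = 0, tau_drift = 300), ...)
}

# Homogeneous single-habitat tumor (uniform T10): the regime where the
# ROI-mean drift model is exact.
uniform_phantom_config <- function(a_drift = 0.05, tau_drift = 300,
                                   noise_sd = 0) {
  hab <- list(list(name = "uniform",
                   rule = list(type = "shell", r_min = 0, r_max = 1),
                   dce = list(a = 1.5, a_sd = 0, k_in = 3, k_out = 0.2),
                   oe = list(a = 0.05, a_sd = 0, tau = 60, sign = 1),
                   t10 = 1.7))
  phantom_config(habitats = hab, noise_sd = noise_sd,
                 drift = list(a_drift = a_drift, tau_drift = tau_drift))
}

# Masked delta-R1 matrices (DCE + OE) straight from a phantom via the full
# relaxometry path.
phantom_to_dr1 <- function(ph, drift_correct = TRUE) {
  t1_dce <- fit_vfa_t1(ph$vfa_dce, ph$mask)
  t1_oe <- fit_vfa_t1(ph$vfa_oe, ph$mask)
  okmask <- ph$mask & t1_dce$ok & t1_oe$ok
  drift <- NULL
  if (drift_correct) {
    idx <- which(okmask)
    sig <- colMeans(matrix(ph$oe$data, ncol = ph$oe$n_frames)[idx, ,
                                                              drop = FALSE])
    drift <- fit_drift_baseline(
      sig, (seq_len(ph$oe$n_frames) - 1) * ph$oe$frame_interval,
      n_pre = ph$oe$event_frame - 1, t10 = mean(t1_oe$t10[idx]),
      alpha0 = ph$oe$flip_angle, tr = ph$oe$tr)
  }
  list(dce = series_to_delta_r1(ph$dce, t1_dce, okmask),
       oe = series_to_delta_r1(ph$oe, t1_oe, okmask, drift = drift),
       t1_dce = t1_dce, t1_oe = t1_oe, drift = drift, mask = okmask)
}

# Synthetic delta_r1_matrix from an explicit value matrix (uniform grid).
toy_dr1 <- function(values, frame_interval = 1, event_frame = 2,
                    modality = "DCE") {
  n <- nrow(values)
  coords <- cbind(x = seq_len(n), y = rep(1L, n), z = rep(1L, n))
  delta_r1_matrix(values, (seq_len(ncol(values)) - 1) * frame_interval,
                  event_frame, coords, modality)
}
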