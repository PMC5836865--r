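#' Dynamic series container
#'
#' A 4D dynamic acquisition plus its timing and acquisition metadata.
#'
#' @param data 4D array `x * y * z * n_frames` (signal units).
#' @param frame_interval Seconds per frame.
#' @param event_frame 1-based index of the first post-event frame
#'   (contrast injection for DCE, gas switch for OE).
#' @param flip_angle Nominal dynamic flip angle (deg).
#' @param tr Repetition time (ms).
#' @param modality `"DCE"` or `"OE"`.
#' @return Object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, frame_interval, event_frame, flip_angle,
                           tr, modality = c("DCE", "OE")) {
  modality <- match.arg(modality)
  stopifnot(length(dim(data)) == 4L)
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(tr, "tr")
  n_frames <- dim(data)[4]
  if (event_frame < 1 || event_frame > n_frames) {
    stop("event_frame must lie within the series")
  }
  structure(list(data = data, n_frames = n_frames,
                 frame_interval = frame_interval,
                 event_frame = as.integer(event_frame),
                 flip_angle = flip_angle, tr = tr, modality = modality),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_series> %s: %dx%dx%d grid, %d frames @ %.2f s, event %d, alpha %g deg, TR %.2f ms\n",
    x$modality, d[1], d[2], d[3], x$n_frames, x$frame_interval,
    x$event_frame, x$flip_angle, x$tr))
  invisible(x)
}

#' Default digital-phantom habitat layout
#'
#' Three concentric habitats emulating the canonical xenograft structure:
#' a non-enhancing necrotic core, a DCE-enhancing but oxygen-refractory
#' (putatively hypoxic) intermediate shell, and a well-perfused,
#' well-oxygenated rim enhancing in both modalities. DCE kinetics are
#' uptake-washout (`A (1 - e^(-k_in t)) e^(-k_out t)`, rates per minute);
#' OE kinetics are a saturating exponential plateau
#' (`sign * A (1 - e^(-t/tau))`).
#'
#' Each habitat carries per-voxel amplitude variability emulating biology:
#' a radial gradient (`a_ramp`, the amplitude change from the habitat's
#' inner to outer edge — perfusion varies smoothly with depth) plus a
#' random spread (`a_sd`). Real enhancement-feature distributions form
#' overlapping density modes, not isolated islands, and the defaults are
#' chosen so neighboring habitats overlap in their tails; the radial
#' gradient additionally places ambiguous voxels next to the habitat they
#' resemble, as in real rim-core structures. Zero spread and ramp give
#' parameter-identical voxels (useful for exact-recovery tests).
#'
#' @return List of habitat definitions usable in [phantom_config].
#' @export
default_habitats <- function() {
  list(
    list(name = "necrotic_core",
         rule = list(type = "shell", r_min = 0, r_max = 0.45),
         dce = list(a = 0, a_sd = 0.05, k_in = 1, k_out = 0),
         oe = list(a = 0, a_sd = 0.005, tau = 60, sign = 0),
         t10 = 2.0),
    list(name = "hypoxic_shell",
         rule = list(type = "shell", r_min = 0.45, r_max = 0.8),
         dce = list(a = 0.5, a_sd = 0.25, a_ramp = 0.3, k_in = 2,
                    k_out = 0.1),
         oe = list(a = 0, a_sd = 0.012, tau = 60, sign = 0),
         t10 = 1.8),
    list(name = "perfused_rim",
         rule = list(type = "shell", r_min = 0.8, r_max = 1),
         dce = list(a = 1.6, a_sd = 0.55, a_ramp = 0.3, k_in = 3,
                    k_out = 0.2),
         oe = list(a = 0.05, a_sd = 0.022, a_ramp = 0.012, tau = 60,
                   sign = 1),
         t10 = 1.6))
}

#' Digital phantom configuration
#'
#' Defines the synthetic acquisition used to validate the pipeline end to
#' end: an ellipsoidal tumor on a regular grid, partitioned into habitats
#' with distinct enhancement kinetics, imaged with the same acquisition
#' geometry and timing as the OE/DCE protocols the package targets
#' (OE: 42 frames at 28.80 s, gas switch at frame 19, 20 deg/TR 30 ms,
#' VFA 5/10/20 deg; DCE: 96 frames at 5.78 s, injection at frame 25,
#' 10 deg/TR 6.02 ms, VFA 2/5/10 deg).
#'
#' @param grid Grid shape (x, y, z) in voxels.
#' @param center Ellipsoid center (defaults to grid center).
#' @param radii Ellipsoid radii in voxels (all > 0).
#' @param habitats Habitat list as in [default_habitats]: each habitat has a
#'   spatial `rule` (`shell` with `r_min`/`r_max` on normalized ellipsoidal
#'   radius, or `wedge` with additional `theta_min`/`theta_max` in radians on
#'   the in-plane azimuth), DCE kinetics `a` (s^-1), `k_in`, `k_out`
#'   (min^-1), OE kinetics `a` (s^-1), `tau` (s), `sign` in {-1, 0, 1},
#'   and native `t10` (s).
#' @param s0 Equilibrium signal (signal units).
#' @param noise_sd Additive Gaussian noise SD (signal units) on dynamic
#'   frames; VFA volumes get `noise_sd / sqrt(vfa_averages)`.
#' @param field_smoothness Spatial correlation length (Gaussian kernel SD,
#'   voxels) of the within-habitat amplitude fields: biological variability
#'   varies smoothly in space, so amplitude deviations form patches rather
#'   than voxel-wise speckle. `0` gives independent per-voxel amplitudes.
#' @param vfa_averages Number of signal averages emulated for VFA volumes.
#' @param drift OE baseline drift: list `a_drift` (unitless), `tau_drift`
#'   (s); drift enters as an exponentially time-varying effective flip angle
#'   on the OE series only.
#' @param oe,dce Acquisition timing/geometry lists: `n_frames`,
#'   `frame_interval` (s), `event_frame`, `flip_angle` (deg), `tr` (ms),
#'   `vfa_angles` (deg).
#' @param seed RNG seed used by [render_phantom].
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(24, 24, 10),
                           center = NULL,
                           radii = c(6.5, 6.5, 3.8),
                           habitats = default_habitats(),
                           s0 = 1000,
                           noise_sd = 2,
                           field_smoothness = 0,
                           vfa_averages = 5,
                           drift = list(a_drift = 0.03, tau_drift = 300),
                           oe = list(n_frames = 42, frame_interval = 28.80,
                                     event_frame = 19, flip_angle = 20,
                                     tr = 30.00, vfa_angles = c(5, 10, 20)),
                           dce = list(n_frames = 96, frame_interval = 5.78,
                                      event_frame = 25, flip_angle = 10,
                                      tr = 6.02, vfa_angles = c(2, 5, 10)),
                           seed = NULL) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1))
  center <- center %||% ((grid + 1) / 2)
  stopifnot(length(center) == 3L, length(radii) == 3L)
  if (any(radii <= 0)) stop("radii must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (tm in list(oe, dce)) {
    stop_if_not_scalar_pos(tm$frame_interval, "frame_interval")
    stop_if_not_scalar_pos(tm$tr, "tr")
    if (tm$event_frame < 1 || tm$event_frame > tm$n_frames) {
      stop("event frame must lie within the series")
    }
  }
  for (h in habitats) {
    pars <- c(unlist(h$dce), unlist(h$oe), h$t10)
    if (any(!is.finite(pars))) stop("non-finite habitat parameters")
  }
  if (field_smoothness < 0) stop("field_smoothness must be >= 0")
  structure(list(grid = grid, center = center, radii = radii,
                 habitats = habitats, s0 = s0, noise_sd = noise_sd,
                 field_smoothness = field_smoothness,
                 vfa_averages = vfa_averages, drift = drift,
                 oe = oe, dce = dce, seed = seed),
            class = "phantom_config")
}

# Per-voxel position across its habitat's radial span, scaled to [-1, 1]
# (-1 at the habitat's inner edge, +1 at its outer edge); 0 for habitats
# without a shell rule span.
habitat_radial_position <- function(config, idx, lab) {
  geo <- phantom_geometry(config)
  r <- geo$r[idx]
  g <- numeric(length(idx))
  for (i in seq_along(config$habitats)) {
    rule <- config$habitats[[i]]$rule
    span <- rule$r_max - rule$r_min
    if (span <= 0) next
    sel <- lab == i
    g[sel] <- pmin(1, pmax(-1, 2 * (r[sel] - rule$r_min) / span - 1))
  }
  g
}

# Smooth standard-normal random field on the grid: iid Gaussian noise
# convolved with a separable Gaussian kernel (SD `sigma` voxels), then
# rescaled to unit variance over `idx`. sigma = 0 returns the iid field.
smooth_field <- function(grid, sigma, idx) {
  f <- array(rnorm(prod(grid)), grid)
  if (sigma > 0) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    k <- k / sum(k)
    conv_along <- function(a, dim_i) {
      ap <- aperm(a, c(dim_i, setdiff(1:3, dim_i)))
      d <- dim(ap)
      m <- matrix(ap, d[1])
      # reflect-pad so tumor-edge voxels keep full kernel mass
      mp <- rbind(m[r:1, , drop = FALSE], m, m[d[1]:(d[1] - r + 1), ,
                                               drop = FALSE])
      sm <- apply(mp, 2, function(col) {
        stats::convolve(col, rev(k), type = "filter")
      })
      aperm(array(sm, d), order(c(dim_i, setdiff(1:3, dim_i))))
    }
    for (dim_i in 1:3) f <- conv_along(f, dim_i)
  }
  s <- sd(f[idx])
  if (s > 0) f <- f / s
  f
}

# Normalized ellipsoidal radius and azimuth for every voxel.
phantom_geometry <- function(config) {
  g <- config$grid
  xyz <- expand.grid(x = seq_len(g[1]), y = seq_len(g[2]), z = seq_len(g[3]))
  dx <- (xyz$x - config$center[1]) / config$radii[1]
  dy <- (xyz$y - config$center[2]) / config$radii[2]
  dz <- (xyz$z - config$center[3]) / config$radii[3]
  list(r = sqrt(dx^2 + dy^2 + dz^2), theta = atan2(dy, dx))
}

# Ground-truth habitat label volume (0 outside tumor).
phantom_truth_map <- function(config) {
  geo <- phantom_geometry(config)
  lab <- integer(length(geo$r))
  in_tumor <- geo$r <= 1
  for (i in seq_along(config$habitats)) {
    rule <- config$habitats[[i]]$rule
    sel <- in_tumor & lab == 0L & geo$r >= rule$r_min & geo$r <= rule$r_max
    if (identical(rule$type, "wedge")) {
      sel <- sel & geo$theta >= rule$theta_min & geo$theta <= rule$theta_max
    }
    lab[sel] <- i
  }
  if (any(in_tumor & lab == 0L)) {
    stop("habitat rules leave tumor voxels unlabeled")
  }
  array(lab, config$grid)
}

#' Ground-truth delta-R1 templates per habitat
#'
#' Evaluates each habitat's DCE and OE kinetics on the configured frame
#' grids. Templates are zero before the event frame; after it,
#' DCE follows `A (1 - e^(-k_in t')) e^(-k_out t')` (`t'` in minutes since
#' injection) and OE follows `sign * A (1 - e^(-t'/tau))` (`t'` in seconds
#' since gas switch).
#'
#' @param config A [phantom_config].
#' @return List with matrices `dce` and `oe` (habitat x frame, s^-1) and the
#'   corresponding `times` vectors.
#' @export
ground_truth_curves <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  unit <- unit_curves(config)
  a_dce <- vapply(config$habitats, function(h) h$dce$a, numeric(1))
  a_oe <- vapply(config$habitats, function(h) h$oe$sign * h$oe$a, numeric(1))
  dce <- a_dce * unit$dce
  oe <- a_oe * unit$oe
  rn <- vapply(config$habitats, function(h) h$name, character(1))
  rownames(dce) <- rn; rownames(oe) <- rn
  list(dce = dce, oe = oe, times_dce = unit$times_dce,
       times_oe = unit$times_oe)
}

# Unit-amplitude kinetic shapes per habitat on the configured frame grids.
unit_curves <- function(config) {
  t_dce <- frame_times(config$dce$n_frames, config$dce$frame_interval)
  t_oe <- frame_times(config$oe$n_frames, config$oe$frame_interval)
  tp_dce <- t_dce - t_dce[config$dce$event_frame]
  tp_oe <- t_oe - t_oe[config$oe$event_frame]
  nh <- length(config$habitats)
  dce <- matrix(0, nh, length(t_dce))
  oe <- matrix(0, nh, length(t_oe))
  for (i in seq_len(nh)) {
    h <- config$habitats[[i]]
    post <- tp_dce >= 0
    tm <- tp_dce[post] / 60  # rates are per minute
    dce[i, post] <- (1 - exp(-h$dce$k_in * tm)) * exp(-h$dce$k_out * tm)
    post <- tp_oe >= 0
    oe[i, post] <- 1 - exp(-tp_oe[post] / h$oe$tau)
  }
  list(dce = dce, oe = oe, times_dce = t_dce, times_oe = t_oe)
}

#' Render a digital phantom
#'
#' Generates raw DCE and OE dynamic series, VFA baseline sets for both
#' protocols, the tumor mask, the ground-truth habitat map and the
#' ground-truth delta-R1 templates. Per voxel, `R1(t) = 1/T10 + dR1(t)` with
#' the habitat's template, pushed through the SPGR forward model at the
#' configured flip angle/TR; the OE series is rendered with the
#' exponentially time-varying effective flip angle of the drift model;
#' additive Gaussian noise is applied everywhere (`noise_sd = 0` for a
#' noiseless phantom). Deterministic given `seed`.
#'
#' @param config A [phantom_config].
#' @param seed Overrides `config$seed` when given.
#' @param tumor_id Identifier attached to the output.
#' @return Object of class `phantom_output`: `dce`, `oe`
#'   ([dynamic_series]), `vfa_dce`, `vfa_oe` ([vfa_set]), `mask`,
#'   `truth_map`, `truth_curves`, `config`, `tumor_id`.
#' @export
render_phantom <- function(config, seed = NULL, tumor_id = "phantom1") {
  stopifnot(inherits(config, "phantom_config"))
  seed <- seed %||% config$seed
  truth <- phantom_truth_map(config)
  curves <- ground_truth_curves(config)
  mask <- truth > 0
  idx <- which(mask)
  lab <- truth[idx]
  t10 <- vapply(config$habitats, function(h) h$t10, numeric(1))[lab]

  # unit-amplitude kinetic shapes per habitat; per-voxel delta-R1 is the
  # voxel's amplitude times its habitat's shape
  unit <- unit_curves(config)

  render_series <- function(dr1_vox, timing, alpha_t) {
    nt <- ncol(dr1_vox)
    r1 <- outer(1 / t10, rep(1, nt)) + dr1_vox
    sig <- spgr_signal(config$s0, 1 / r1,
                       matrix(alpha_t, length(idx), nt, byrow = TRUE),
                       timing$tr)
    arr <- array(0, c(config$grid, nt))
    flat <- matrix(arr, ncol = nt)
    flat[idx, ] <- sig
    flat
  }

  t_oe <- curves$times_oe
  alpha_oe <- config$oe$flip_angle *
    (1 + config$drift$a_drift * (1 - exp(-t_oe / config$drift$tau_drift)))
  with_seed(seed, {
    # biological within-habitat amplitude variability (deterministic per
    # seed): a radial gradient across each habitat's span plus random
    # spread (iid by default; spatially smooth if field_smoothness > 0)
    a_dce <- vapply(config$habitats, function(h) h$dce$a, numeric(1))
    sd_dce <- vapply(config$habitats, function(h) h$dce$a_sd %||% 0,
                     numeric(1))
    rp_dce <- vapply(config$habitats, function(h) h$dce$a_ramp %||% 0,
                     numeric(1))
    a_oe <- vapply(config$habitats, function(h) h$oe$sign * h$oe$a,
                   numeric(1))
    sd_oe <- vapply(config$habitats, function(h) h$oe$a_sd %||% 0,
                    numeric(1))
    rp_oe <- vapply(config$habitats, function(h) h$oe$a_ramp %||% 0,
                    numeric(1))
    g <- habitat_radial_position(config, idx, lab)
    f_dce <- smooth_field(config$grid, config$field_smoothness, idx)
    f_oe <- smooth_field(config$grid, config$field_smoothness, idx)
    amp_dce <- pmax(0, a_dce[lab] + rp_dce[lab] * g +
                      sd_dce[lab] * f_dce[idx])
    amp_oe <- a_oe[lab] + rp_oe[lab] * g + sd_oe[lab] * f_oe[idx]
    truth_dce_voxel <- amp_dce * unit$dce[lab, , drop = FALSE]
    truth_oe_voxel <- amp_oe * unit$oe[lab, , drop = FALSE]

    dce_flat <- render_series(truth_dce_voxel, config$dce,
                              rep(config$dce$flip_angle, config$dce$n_frames))
    oe_flat <- render_series(truth_oe_voxel, config$oe, alpha_oe)
    if (config$noise_sd > 0) {
      dce_flat <- dce_flat + rnorm(length(dce_flat), 0, config$noise_sd)
      oe_flat <- oe_flat + rnorm(length(oe_flat), 0, config$noise_sd)
    }
    make_vfa <- function(timing) {
      ang <- timing$vfa_angles
      arr <- array(0, c(config$grid, length(ang)))
      flat <- matrix(arr, ncol = length(ang))
      for (j in seq_along(ang)) {
        col <- numeric(prod(config$grid))
        col[idx] <- spgr_signal(config$s0, t10, ang[j], timing$tr)
        flat[, j] <- col
      }
      if (config$noise_sd > 0) {
        vsd <- config$noise_sd / sqrt(config$vfa_averages)
        flat[idx, ] <- flat[idx, ] + rnorm(length(idx) * length(ang), 0, vsd)
      }
      vfa_set(array(flat, c(config$grid, length(ang))), ang, timing$tr)
    }
    vfa_dce <- make_vfa(config$dce)
    vfa_oe <- make_vfa(config$oe)

    out <- list(
      dce = dynamic_series(array(dce_flat, c(config$grid, config$dce$n_frames)),
                           config$dce$frame_interval, config$dce$event_frame,
                           config$dce$flip_angle, config$dce$tr, "DCE"),
      oe = dynamic_series(array(oe_flat, c(config$grid, config$oe$n_frames)),
                          config$oe$frame_interval, config$oe$event_frame,
                          config$oe$flip_angle, config$oe$tr, "OE"),
      vfa_dce = vfa_dce, vfa_oe = vfa_oe,
      mask = mask, truth_map = truth, truth_curves = curves,
      truth_dce_voxel = truth_dce_voxel, truth_oe_voxel = truth_oe_voxel,
      truth_amp = data.frame(index_to_coords(idx, config$grid),
                             habitat = lab, amp_dce = amp_dce,
                             amp_oe = amp_oe),
      config = config, tumor_id = tumor_id)
    class(out) <- "phantom_output"
    out
  })
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> '%s': %d tumor voxels, %d habitats, grid %s\n",
              x$tumor_id, sum(x$mask), length(x$config$habitats),
              paste(x$config$grid, collapse = "x")))
  invisible(x)
}

#' Render a cohort of phantoms
#'
#' Produces `n_tumors` phantoms sharing the habitat kinetics of `config` but
#' with deterministically jittered ellipsoid radii (within +/- 10%), so the
#' cohort has tumor-to-tumor size variation while voxels remain poolable in
#' one feature space. Each tumor gets an independent child seed.
#'
#' @param n_tumors Number of tumors.
#' @param config Base [phantom_config].
#' @param seed Cohort seed.
#' @return List of `phantom_output`, one per tumor.
#' @export
phantom_cohort <- function(n_tumors = 4, config = phantom_config(), seed = 1) {
  jit <- with_seed(child_seed(seed, 0),
                   matrix(runif(3 * n_tumors, 1.0, 1.15), n_tumors, 3))
  lapply(seq_len(n_tumors), function(i) {
    cf <- config
    cf$radii <- config$radii * jit[i, ]
    render_phantom(cf, seed = child_seed(seed, i),
                   tumor_id = sprintf("tumor%02d", i))
  })
}
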