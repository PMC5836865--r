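#' Pipeline configuration
#'
#' All stage parameters of the end-to-end habitat-mapping pipeline. Defaults
#' reproduce the validation setup used throughout the package: a 4-tumor,
#' 3-habitat phantom cohort, 1% erratic-voxel exclusion, a 90 s DCE AUC
#' window, 4 principal components, a cluster sweep over `nc_range`, 10 EM
#' restarts, and the stability/contiguity thresholds of the selection rule.
#'
#' @param n_tumors Number of phantom tumors.
#' @param phantom A [phantom_config] shared by the cohort.
#' @param drift_correct Apply OE baseline drift correction.
#' @param fraction Erratic-voxel exclusion fraction per modality.
#' @param window_dce DCE AUC window (s).
#' @param n_components Principal components kept in the PCA feature set.
#' @param nc_range Cluster numbers swept.
#' @param n_restarts GMM restarts.
#' @param n_boot_stability Bootstrap refits per cluster number.
#' @param n_boot_contiguity Bootstrap realizations of the contiguity null.
#' @param s_min,z_min Selection thresholds (median stability silhouette,
#'   median contiguity z).
#' @param alpha_level Enhancement-call threshold of the reference
#'   threshold-based method.
#' @param grouping Cluster-to-class grouping for the comparison stage
#'   (`NULL`: [default_grouping] of the selected cluster number).
#' @param seed Global seed; expanded deterministically into per-stage seeds.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return Object of class `pipeline_config`.
#' @export
habitat_pipeline_config <- function(n_tumors = 4,
                                    phantom = phantom_config(),
                                    drift_correct = TRUE,
                                    fraction = 0.01,
                                    window_dce = 90,
                                    n_components = 4,
                                    nc_range = 2:5,
                                    n_restarts = 10,
                                    n_boot_stability = 50,
                                    n_boot_contiguity = 100,
                                    s_min = 0.8,
                                    z_min = 3,
                                    alpha_level = 0.05,
                                    grouping = NULL,
                                    seed = 1,
                                    out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(inherits(cfg$phantom, "phantom_config"))
  if (cfg$fraction < 0 || cfg$fraction >= 0.5) stop("invalid fraction")
  if (any(cfg$nc_range < 2)) stop("nc_range entries must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys are arguments of
#' [habitat_pipeline_config] (plus an optional `phantom` block of
#' [phantom_config] arguments). Unknown keys are rejected before any stage
#' runs.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(habitat_pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$phantom)) {
    pk <- names(formals(phantom_config))
    bad <- setdiff(names(raw$phantom), pk)
    if (length(bad)) stop("unknown phantom keys: ", paste(bad, collapse = ", "))
    raw$phantom <- do.call(phantom_config, raw$phantom)
  }
  if (!is.null(raw$nc_range)) raw$nc_range <- as.integer(unlist(raw$nc_range))
  do.call(habitat_pipeline_config, raw)
}

#' Run the habitat-mapping pipeline end to end
#'
#' Executes, in order: phantom generation; VFA T1 fitting, OE drift
#' correction and signal-to-delta-R1 conversion per tumor; erratic-voxel
#' exclusion; AUC and PCA feature extraction over the pooled cohort; the
#' GMM cluster sweep with canonical relabeling; the three evaluation
#' metrics (AIC, per-tumor contiguity z-scores, bootstrap stability
#' silhouettes); selection of the optimal feature set and cluster number;
#' habitat maps and mean within-cluster curves for the selected model; and
#' the quantitative comparison against the threshold-based three-class
#' maps. Deterministic given `config$seed`. When `config$out_dir` is set,
#' all artifacts are written with a content-hash manifest.
#'
#' @param config A [habitat_pipeline_config].
#' @return List: `tumors` (per-tumor data incl. `habitat_map`, `tbm_map`),
#'   `features` (`auc`, `pca` [feature_set]s), `report` (metric table),
#'   `stability_scores`, `selection`, `fits` (selected fit per feature
#'   set), `cluster_curves`, `comparison` (`per_tumor`, `pooled`,
#'   `bland_altman`), `config`.
#' @export
run_habitat_pipeline <- function(config = habitat_pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  grid <- config$phantom$grid

  ## 1. phantom cohort -------------------------------------------------
  phantoms <- phantom_cohort(config$n_tumors, config$phantom,
                             seed = child_seed(seed, 1))

  ## 2. relaxometry + 3. exclusion per tumor ---------------------------
  tumors <- lapply(phantoms, function(ph) {
    t1_dce <- fit_vfa_t1(ph$vfa_dce, ph$mask)
    t1_oe <- fit_vfa_t1(ph$vfa_oe, ph$mask)
    okmask <- ph$mask & t1_dce$ok & t1_oe$ok
    drift <- NULL
    if (config$drift_correct) {
      idx <- which(okmask)
      sig <- colMeans(matrix(ph$oe$data, ncol = ph$oe$n_frames)[idx, ,
                                                                drop = FALSE])
      drift <- fit_drift_baseline(
        sig, frame_times(ph$oe$n_frames, ph$oe$frame_interval),
        n_pre = ph$oe$event_frame - 1, t10 = mean(t1_oe$t10[idx]),
        alpha0 = ph$oe$flip_angle, tr = ph$oe$tr)
    }
    dce <- series_to_delta_r1(ph$dce, t1_dce, okmask)
    oe <- series_to_delta_r1(ph$oe, t1_oe, okmask, drift = drift)
    excl <- exclude_erratic_voxels(dce, oe, config$fraction)
    list(tumor_id = ph$tumor_id, phantom = ph, mask = ph$mask,
         truth_map = build_region_map(
           ph$truth_map[ph$truth_map > 0],
           index_to_coords(which(ph$truth_map > 0), grid), grid,
           n_clusters = length(ph$config$habitats), tumor_id = ph$tumor_id),
         t1_dce = t1_dce, t1_oe = t1_oe, drift = drift,
         dce = excl$dce, oe = excl$oe, exclusion = excl$report)
  })

  ## 4. pooled feature extraction --------------------------------------
  pool <- function(field) do.call(rbind, lapply(tumors, function(tm) {
    tm[[field]]$values
  }))
  dce_pool <- pool("dce")
  oe_pool <- pool("oe")
  coords_pool <- do.call(rbind, lapply(tumors, function(tm) tm$dce$coords))
  tumor_id_pool <- unlist(lapply(tumors, function(tm) {
    rep(tm$tumor_id, nrow(tm$dce$values))
  }))

  auc_list <- lapply(tumors, function(tm) {
    auc_features(tm$dce, tm$oe, config$window_dce,
                 tumor_id = rep(tm$tumor_id, nrow(tm$dce$values)))
  })
  fs_auc <- feature_set(do.call(rbind, lapply(auc_list, function(f) f$x)),
                        c("auc_dce", "auc_oe"), coords_pool, tumor_id_pool)
  cc <- scale_and_concatenate(dce_pool, oe_pool)
  fs_pca <- pca_features(cc$composite, config$n_components, coords_pool,
                         tumor_id_pool, scale_factor = cc$scale_factor)
  features <- list(auc = fs_auc, pca = fs_pca)

  ## 5. cluster sweep + 6. evaluation ----------------------------------
  auc_dce_vec <- fs_auc$x[, "auc_dce"]
  report <- list()
  sweep_fits <- list()
  stability_scores <- list()
  for (fs_name in names(features)) {
    fs <- features[[fs_name]]
    stab <- stability_analysis(
      fs, config$nc_range, n_boot = config$n_boot_stability,
      n_restarts = config$n_restarts,
      seed = child_seed(seed, if (fs_name == "auc") 20 else 30))
    stab$scores$feature_set <- fs_name
    stability_scores[[fs_name]] <- stab$scores
    for (nc in config$nc_range) {
      fit <- relabel_by_dce_auc(stab$reference[[as.character(nc)]],
                                auc_dce_vec)
      sweep_fits[[paste(fs_name, nc, sep = "_")]] <- fit
      z <- vapply(seq_along(tumors), function(i) {
        rows <- tumor_id_pool == tumors[[i]]$tumor_id
        map <- build_region_map(fit$labels[rows],
                                fs$coords[rows, , drop = FALSE], grid,
                                n_clusters = nc,
                                tumor_id = tumors[[i]]$tumor_id)
        contiguity_zscore(map, config$n_boot_contiguity,
                          seed = child_seed(seed, 40 + i))
      }, numeric(1))
      report[[paste(fs_name, nc)]] <- data.frame(
        feature_set = fs_name, nc = nc, aic = gmm_aic(fit),
        z_median = median(z),
        stability_median = stab$summary$median_silhouette[
          stab$summary$nc == nc])
    }
  }
  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  selection <- select_optimum(report, config$s_min, config$z_min)

  ## 7. selected model: habitat maps, curves, comparison ---------------
  sel_fit <- sweep_fits[[paste(selection$feature_set, selection$nc,
                               sep = "_")]]
  for (i in seq_along(tumors)) {
    rows <- tumor_id_pool == tumors[[i]]$tumor_id
    tumors[[i]]$habitat_map <- build_region_map(
      sel_fit$labels[rows],
      features[[selection$feature_set]]$coords[rows, , drop = FALSE],
      grid, n_clusters = selection$nc, tumor_id = tumors[[i]]$tumor_id)
    tumors[[i]]$habitat_map$method <- "habitat-GMM"
    tumors[[i]]$tbm_map <- tbm_classify(tumors[[i]]$dce, tumors[[i]]$oe,
                                        grid, config$alpha_level,
                                        tumor_id = tumors[[i]]$tumor_id)
  }
  cluster_curves <- mean_cluster_curves(
    sel_fit$labels,
    list(values = dce_pool, times = tumors[[1]]$dce$times),
    list(values = oe_pool, times = tumors[[1]]$oe$times),
    n_clusters = selection$nc)

  comparison <- NULL
  grouping <- config$grouping %||% tryCatch(
    default_grouping(selection$nc), error = function(e) NULL)
  if (is.null(grouping)) {
    warning("no grouping available for ", selection$nc,
            " clusters; comparison stage skipped")
  } else {
    odd_labels <- list(); tbm_labels <- list()
    per_tumor <- list()
    counts_odd <- matrix(0, length(tumors), length(grouping))
    counts_tbm <- matrix(0, length(tumors), length(grouping))
    for (i in seq_along(tumors)) {
      cat_map <- concatenate_clusters(tumors[[i]]$habitat_map, grouping)
      tumors[[i]]$habitat_map_3class <- cat_map
      a <- cat_map$labels[cat_map$labels > 0]
      b <- tumors[[i]]$tbm_map$labels[tumors[[i]]$tbm_map$labels > 0]
      odd_labels[[i]] <- a; tbm_labels[[i]] <- b
      cmp <- compare_maps(a, b, classes = seq_along(grouping))
      per_tumor[[i]] <- data.frame(tumor_id = tumors[[i]]$tumor_id,
                                   phi = cmp$phi, kappa = cmp$kappa,
                                   n = cmp$n)
      counts_odd[i, ] <- tabulate(a, length(grouping))
      counts_tbm[i, ] <- tabulate(b, length(grouping))
    }
    pooled <- compare_maps(unlist(odd_labels), unlist(tbm_labels),
                           classes = seq_along(grouping))
    comparison <- list(
      per_tumor = do.call(rbind, per_tumor), pooled = pooled,
      counts_odd = counts_odd, counts_tbm = counts_tbm,
      bland_altman = bland_altman(counts_odd, counts_tbm))
  }

  result <- list(tumors = tumors, features = features, report = report,
                 stability_scores = do.call(rbind, stability_scores),
                 selection = selection, fits = sweep_fits,
                 selected_fit = sel_fit, cluster_curves = cluster_curves,
                 comparison = comparison, config = config)
  class(result) <- "habitat_pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.habitat_pipeline_result <- function(x, ...) {
  cat(sprintf("<habitat_pipeline_result> %d tumors, selected %s / N_C = %d\n",
              length(x$tumors), x$selection$feature_set, x$selection$nc))
  if (!is.null(x$comparison)) {
    cat(sprintf("  vs TBM (pooled): phi = %.3f, kappa = %.3f\n",
                x$comparison$pooled$phi, x$comparison$pooled$kappa))
  }
  invisible(x)
}
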