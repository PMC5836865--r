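# NIfTI / JSON / CSV output layer. Volumes go through RNifti; any affine on
# an input image is passed through untouched.

#' Write a volume as NIfTI with a JSON metadata sidecar
#'
#' @param vol 3D or 4D numeric array (or `region_map` / `dynamic_series`).
#' @param path Output path (`.nii.gz` appended if absent).
#' @param metadata Named list written to a `.json` sidecar (timing, flip
#'   angles, event frames, ...). `NULL` writes no sidecar.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, metadata = NULL) {
  if (inherits(vol, "region_map")) {
    metadata <- metadata %||% list(tumor_id = vol$tumor_id,
                                   n_clusters = vol$n_clusters,
                                   method = vol$method %||% "habitat")
    vol <- vol$labels
  } else if (inherits(vol, "dynamic_series")) {
    metadata <- metadata %||% list(
      modality = vol$modality, frame_interval_s = vol$frame_interval,
      event_frame = vol$event_frame, flip_angle_deg = vol$flip_angle,
      tr_ms = vol$tr)
    vol <- vol$data
  }
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a NIfTI volume (with optional JSON sidecar)
#'
#' @param path NIfTI path.
#' @return List: `data` (array), `image` (the `niftiImage`, affine intact),
#'   `metadata` (sidecar contents or `NULL`).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  metadata <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  list(data = as.array(img), image = img, metadata = metadata)
}

# Write every artifact of a pipeline run plus a manifest of content hashes.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  for (tm in result$tumors) {
    stub <- file.path(out_dir, tm$tumor_id)
    add(write_volume(array(as.integer(tm$mask), dim(tm$mask)),
                     paste0(stub, "_mask")))
    add(write_volume(tm$truth_map, paste0(stub, "_truth"),
                     metadata = list(tumor_id = tm$tumor_id,
                                     kind = "ground_truth")))
    add(write_volume(tm$habitat_map, paste0(stub, "_habitats")))
    add(write_volume(tm$tbm_map, paste0(stub, "_tbm")))
    p <- paste0(stub, "_exclusion.csv")
    write.csv(tm$exclusion, p, row.names = FALSE)
    add(p)
  }
  drift_tab <- do.call(rbind, lapply(result$tumors, function(tm) {
    if (is.null(tm$drift)) return(NULL)
    data.frame(tumor_id = tm$tumor_id, s0 = tm$drift$s0,
               a_drift = tm$drift$a_drift, tau_drift = tm$drift$tau_drift,
               converged = tm$drift$converged)
  }))
  if (!is.null(drift_tab)) {
    p <- file.path(out_dir, "drift_fits.csv")
    write.csv(drift_tab, p, row.names = FALSE)
    add(p)
  }
  p <- file.path(out_dir, "evaluation_report.csv")
  write.csv(result$report, p, row.names = FALSE)
  add(p)
  p <- file.path(out_dir, "stability_scores.csv")
  write.csv(result$stability_scores, p, row.names = FALSE)
  add(p)
  p <- file.path(out_dir, "cluster_curves.csv")
  write.csv(result$cluster_curves, p, row.names = FALSE)
  add(p)
  p <- file.path(out_dir, "agreement.json")
  jsonlite::write_json(
    list(selection = result$selection[c("feature_set", "nc")],
         pooled = result$comparison$pooled[c("phi", "kappa", "n")],
         per_tumor = result$comparison$per_tumor,
         bland_altman = result$comparison$bland_altman),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add(p)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         row.names = NULL)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = result$config$seed, package_version =
           as.character(utils::packageVersion("habitatmri")),
         files = manifest),
    mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mpath))
}
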