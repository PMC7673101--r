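#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti with an identity-scaled affine by default,
#' used to exchange 3D maps, masks and 4D series with external tools.
#'
#' @param volume numeric 3D or 4D array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge length(s) in mm.
#' @return `write_volume` returns the path invisibly; `read_volume`
#'   returns a plain numeric array.
#' @export
write_volume <- function(volume, path, voxel_size = 1) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep_len(voxel_size, min(length(dim(volume)), 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Read and write motion traces as whitespace-delimited text
#'
#' One row per timepoint, six columns (three translations in mm, three
#' rotations); the rotation unit is recorded in a comment header so it
#' is never lost.
#'
#' @param trace a [motion_trace()].
#' @param path text file path.
#' @return `write_motion_trace` returns the path invisibly;
#'   `read_motion_trace` returns a [motion_trace()].
#' @export
write_motion_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rotation_unit: %s", attr(trace, "rotation_unit")),
             con)
  utils::write.table(unclass(trace), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  header <- readLines(path, n = 1L)
  unit <- sub("^#\\s*rotation_unit:\\s*", "", header)
  if (!unit %in% c("radians", "degrees"))
    stop("motion trace file has no rotation-unit header")
  params <- as.matrix(utils::read.table(path, skip = 1L))
  motion_trace(params, rotation_unit = unit)
}

#' Write a QC report as CSV
#'
#' @param results named list of `qc_result` objects (names are subject
#'   ids).
#' @param path CSV path.
#' @return the report data frame, invisibly.
#' @export
write_qc_report <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(subject_id = id, mean_fd = r$mean_fd,
               max_translation = r$max_translation,
               max_rotation = r$max_rotation, passed = r$passed,
               reasons = paste(r$reasons, collapse = ";"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read and write phenotype tables as CSV
#'
#' @param cohort a phenotype table ([make_cohort()] layout).
#' @param path CSV path.
#' @return `write_cohort` returns the path invisibly; `read_cohort`
#'   returns the table with `site`, `group` and `handedness` restored as
#'   factors.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$site <- factor(df$site)
  df$group <- factor(df$group, levels = unique(df$group))
  df$handedness <- factor(df$handedness, levels = c("R", "L", "M"))
  df
}

#' Export a component's z-scored source map as a NIfTI volume
#'
#' Unflattens one source row through the mask stored in the fusion model
#' and writes it as a 3D NIfTI-1 image (out-of-mask voxels are 0).
#'
#' @param model a [fuse()] result whose feature matrices carried a mask.
#' @param component component index.
#' @param modality modality index.
#' @param path output path.
#' @param z if `TRUE` (default) write the z-scored map.
#' @return the path, invisibly.
#' @export
export_source_map <- function(model, component, modality, path, z = TRUE) {
  mask <- model$masks[[modality]]
  if (is.null(mask)) stop("fusion model carries no mask for this modality")
  src <- model$sources[[modality]][component, ]
  if (z) src <- zscore_threshold(src)$zmap
  vol <- array(0, dim = dim(mask))
  vol[which(as.vector(mask))] <- src
  write_volume(vol, path)
}

#' Save and load a fitted fusion model
#'
#' Serializes the complete model (matrices, configuration, seed,
#' convergence log) to a single RDS archive.
#'
#' @param model a [fuse()] result.
#' @param path file path.
#' @return `save_fusion_model` returns the path invisibly;
#'   `load_fusion_model` returns the model.
#' @export
save_fusion_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_fusion_model
#' @export
load_fusion_model <- function(path) readRDS(path)

#' Write a component-selection report as CSV
#'
#' @param selection a [select_reference_component()] result.
#' @param path CSV path.
#' @return the full component table, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  tab <- selection$table
  tab$selected <- tab$component == selection$component
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
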