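#' Read a multi-b-value signal stack from NIfTI
#'
#' Thin wrapper around RNifti for 4D (x, y, z, b) stacks. RNifti is an
#' optional dependency; array + CSV inputs work without it.
#'
#' @param path Path to a NIfTI file.
#' @return A numeric array.
#' @export
read_stack_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort_invalid("RNifti is required to read NIfTI files")
  as.array(RNifti::readNifti(path))
}

#' Write parameter maps to NIfTI files
#'
#' Writes one file per map (`<name>.nii.gz`) under `dir`; voxels outside a
#' map's fitted mask are written as NA.
#'
#' @param maps List of parameter maps from [fit_parameter_maps()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_maps_nifti <- function(maps, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort_invalid("RNifti is required to write NIfTI files")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(maps, function(m) {
    p <- file.path(dir, paste0(m$name, ".nii.gz"))
    RNifti::writeNifti(m$values, p)
    p
  }, character(1))
  invisible(paths)
}

#' Write parameter maps as voxel-level CSV
#'
#' Desk-scale alternative to NIfTI output: one row per voxel inside any
#' fitted mask, with voxel indices and one column per parameter.
#'
#' @param maps List of parameter maps from [fit_parameter_maps()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_maps_csv <- function(maps, path) {
  any_mask <- Reduce(`|`, lapply(maps, function(m) m$mask))
  idx <- which(as.logical(any_mask))
  coords <- arrayInd(idx, dim(any_mask))
  colnames(coords) <- paste0("i", seq_len(ncol(coords)))
  out <- as.data.frame(coords)
  for (m in maps) out[[m$name]] <- m$values[idx]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
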