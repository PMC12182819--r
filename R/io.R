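# NIfTI, CSV and manifest I/O.

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti keeping data and voxel size together. 3D and
#' 4D volumes round-trip losslessly.
#'
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_volume`: list with `data` (numeric array) and `voxel_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vm <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_mm = as.numeric(vm[seq_len(min(3L, length(vm)))]))
}

#' @rdname read_volume
#' @param data numeric or logical array (3D or 4D).
#' @param voxel_mm voxel size per spatial axis (mm).
#' @export
write_volume <- function(data, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(data * 1)
  pd <- rep(1, length(dim(data)))
  pd[1:3] <- voxel_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# error unless two volumes share a grid
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data)[1:3], dim(b$data)[1:3]) ||
      max(abs(a$voxel_mm - b$voxel_mm)) > 1e-6)
    stop_lungecv("grid mismatch between paired ", what)
  invisible(TRUE)
}

#' Read / write a study manifest
#'
#' The manifest is a YAML (or JSON) document listing subjects, their model,
#' hematocrit, per-phase volume files, time-series files and acquisition
#' metadata. It round-trips losslessly through [write_manifest()] /
#' [read_manifest()].
#'
#' @param path manifest file (`.yaml`/`.yml`/`.json`).
#' @return manifest list.
#' @export
read_manifest <- function(path) {
  man <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = FALSE)
  else yaml::read_yaml(path)
  validate_manifest(man)
  man
}

#' @rdname read_manifest
#' @param manifest manifest list.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  if (grepl("\\.json$", path))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(manifest, path, precision = 15L)
  invisible(path)
}

#' Validate a study manifest
#'
#' Checks the structural contract: subject ids, hematocrit, volume entries
#' with phase/condition labels. When `dir` is given, also checks that every
#' referenced file exists.
#'
#' @param manifest manifest list.
#' @param dir optional root directory for relative paths.
#' @return the manifest, invisibly.
#' @export
validate_manifest <- function(manifest, dir = NULL) {
  if (is.null(manifest$subjects) || length(manifest$subjects) == 0L)
    stop_lungecv("manifest has no subjects")
  for (sub in manifest$subjects) {
    if (is.null(sub$id)) stop_lungecv("subject without id")
    if (is.null(sub$hematocrit))
      stop_lungecv(sprintf("subject %s: missing hematocrit", sub$id))
    if (!(sub$hematocrit > 0 && sub$hematocrit < 1))
      stop_lungecv(sprintf("subject %s: hematocrit outside (0, 1)", sub$id))
    if (is.null(sub$volumes) || length(sub$volumes) == 0L)
      stop_lungecv(sprintf("subject %s: no volumes", sub$id))
    for (v in sub$volumes) {
      if (is.null(v$phase) ||
          !v$phase %in% c("native", "gadolinium", "ferumoxytol"))
        stop_lungecv(sprintf("subject %s: volume with bad phase", sub$id))
      if (is.null(v$condition))
        stop_lungecv(sprintf("subject %s: volume without condition", sub$id))
      if (!is.null(dir) && !is.null(v$series) &&
          !file.exists(file.path(dir, v$series)))
        stop_lungecv(sprintf("subject %s: missing file %s", sub$id, v$series))
    }
  }
  invisible(manifest)
}
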