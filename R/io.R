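#' Write / read a voxel phantom as NIfTI volumes with a JSON sidecar
#'
#' The label grid and each mask are written as separate NIfTI files
#' (\code{<prefix>_labels.nii.gz}, \code{<prefix>_mask_<name>.nii.gz}); the
#' sidecar \code{<prefix>.json} records spacing, origin, the tissue-id legend
#' and the mask names.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  s <- phantom$spacing
  write_vol <- function(arr, path) {
    img <- RNifti::asNifti(arr, pixdim = rep(s, 3))
    RNifti::writeNifti(img, path)
  }
  write_vol(phantom$labels, paste0(prefix, "_labels.nii.gz"))
  for (m in names(phantom$masks)) {
    write_vol(array(as.integer(phantom$masks[[m]]), dim(phantom$labels)),
              paste0(prefix, "_mask_", m, ".nii.gz"))
  }
  sidecar <- list(spacing_mm = s, origin_mm = phantom$origin,
                  legend = as.list(phantom$legend),
                  masks = names(phantom$masks))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  sidecar <- jsonlite::fromJSON(paste0(prefix, ".json"))
  labels <- array(as.integer(RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))),
                  dim = dim(RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))))
  p <- new_phantom(labels, sidecar$spacing_mm,
                   legend = unlist(sidecar$legend), origin = sidecar$origin_mm)
  for (m in sidecar$masks) {
    arr <- RNifti::readNifti(paste0(prefix, "_mask_", m, ".nii.gz"))
    p$masks[[m]] <- array(as.integer(arr) > 0L, dim(labels))
  }
  p
}

#' Write / read a scalar voxel field (SAR or temperature) as NIfTI
#'
#' @param field a [sar_field()], [temperature_field()] or 3D array.
#' @param phantom the phantom defining voxel spacing.
#' @param path output \code{.nii.gz} path.
#' @return the path, invisibly.
#' @export
write_field <- function(field, phantom, path) {
  arr <- if (inherits(field, "sar_field")) field$sar
         else if (inherits(field, "temperature_field")) field$T
         else field
  img <- RNifti::asNifti(arr, pixdim = rep(phantom$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Load a solver/sweep configuration from JSON or YAML
#'
#' @param path a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::fromJSON(path)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format: .", ext)
}
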