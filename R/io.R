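#' Write a tumor volume to NIfTI
#'
#' Writes the intensity volume and its binary mask as compressed NIfTI with
#' the voxel spacing recorded in the header.
#'
#' @param volume a `tumor_volume`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
write_volume_nifti <- function(volume, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- as.character(volume$patient_id %||% "volume")
  paths <- file.path(dir, paste0(id, c("_image.nii.gz", "_mask.nii.gz")))
  img <- RNifti::asNifti(volume$intensities)
  msk <- RNifti::asNifti(array(as.integer(volume$mask), dim(volume$mask)))
  RNifti::pixdim(img) <- volume$spacing
  RNifti::pixdim(msk) <- volume$spacing
  RNifti::writeNifti(img, paths[1])
  RNifti::writeNifti(msk, paths[2])
  invisible(paths)
}

#' Read a tumor volume from NIfTI image/mask files
#'
#' @param image_path,mask_path NIfTI files with matching grids.
#' @param patient_id identifier to attach.
#' @return A `tumor_volume`.
#' @export
read_volume_nifti <- function(image_path, mask_path, patient_id = NULL) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  stopifnot(identical(dim(img), dim(msk)))
  spacing <- RNifti::pixdim(img)[1:3]
  structure(
    list(intensities = array(as.numeric(img), dim(img)),
         mask = array(as.numeric(msk) > 0.5, dim(msk)),
         spacing = as.numeric(spacing),
         patient_id = patient_id %||%
           sub("_image\\.nii(\\.gz)?$", "", basename(image_path))),
    class = "tumor_volume"
  )
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "trait-associated", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}
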