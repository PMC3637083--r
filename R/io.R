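# NIfTI and table I/O helpers.

#' Write a VolumeImage as NIfTI
#'
#' @param vol a \linkS4class{VolumeImage}.
#' @param file output path (.nii or .nii.gz).
#' @return the file path, invisibly.
#' @export
writeVolume <- function(vol, file) {
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@voxelSize
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI file into a VolumeImage
#'
#' @param file path to a NIfTI volume.
#' @param origin mm coordinate of the first voxel center; defaults to the
#'   grid-centering convention of \code{\link{VolumeImage}}.
#' @return A \linkS4class{VolumeImage}.
#' @export
readVolume <- function(file, origin = NULL) {
  img <- RNifti::readNifti(file)
  VolumeImage(array(as.numeric(img), dim = dim(img)),
              voxelSize = RNifti::pixdim(img)[1:3], origin = origin)
}

#' Write a cohort's covariate table
#'
#' Tab-separated with header: id, group, age, gender, depression,
#' months_post_treatment.
#'
#' @param cohort a \linkS4class{PETCohort}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeCovariates <- function(cohort, file) {
  utils::write.table(cohort@covariates, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
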