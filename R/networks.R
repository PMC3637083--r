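# Signed weight-pattern extraction and network mean metabolism.

#' Threshold a weight map into two signed patterns
#'
#' "|w| well above zero" is operationalized as a percentile of |w| over the
#' brain-mask voxels (scale-free under feature rescaling): the threshold is
#' the p-th percentile of |w|; the positive pattern keeps voxels with
#' w >= +threshold, the negative pattern voxels with w <= -threshold.
#' Either side may come back empty.  When the realized threshold is 0
#' (more than p percent of weights exactly zero) the masks are restricted
#' to strictly nonzero weights so they stay disjoint; in the p -> 0 limit
#' the two masks therefore partition the nonzero-weight voxels by sign.
#'
#' @param wm a \linkS4class{WeightMap}.
#' @param percentile p in (0, 100); default 90.
#' @return A \linkS4class{SignedPatterns}.
#' @export
extractSignedPatterns <- function(wm, percentile = 90) {
  stopifnot(percentile > 0, percentile < 100)
  if (all(wm@w == 0)) stop("weight map is all zero: nothing to threshold")
  thr <- stats::quantile(abs(wm@w), percentile / 100, names = FALSE)
  if (thr == 0) {
    pos <- wm@w > 0
    neg <- wm@w < 0
  } else {
    pos <- wm@w >= thr
    neg <- wm@w <= -thr
  }
  toMask <- function(sel) {
    m <- array(FALSE, dim = wm@dim)
    idx <- wm@voxelIndex[sel, , drop = FALSE]
    m[idx[, 1] + wm@dim[1] * (idx[, 2] - 1) +
        wm@dim[1] * wm@dim[2] * (idx[, 3] - 1)] <- TRUE
    m
  }
  new("SignedPatterns", positiveMask = toMask(pos), negativeMask = toMask(neg),
      percentile = percentile, thresholdValue = thr)
}

#' Mean volume value inside a binary mask
#'
#' @param vol a \linkS4class{VolumeImage}.
#' @param mask logical array of matching dimension.
#' @return arithmetic mean over mask voxels.
#' @export
meanInMask <- function(vol, mask) {
  if (!identical(dim(vol@data), dim(mask)))
    stop("mask dimension does not match the volume")
  if (!any(mask)) stop("mask is empty")
  mean(vol@data[mask])
}

#' Per-subject network mean metabolism
#'
#' Extracts, for every subject, the mean metabolism over the positive
#' pattern (reported as \code{pcs_mean}) and over the negative pattern
#' (\code{dan_mean}), aligned with the covariate table by id.  Which sign
#' corresponds to which clinical network is a post-hoc call (see
#' \code{\link{runPipeline}}), not an assumption of this function.
#'
#' @param cohort a \linkS4class{PETCohort}.
#' @param patterns a \linkS4class{SignedPatterns} with both sides non-empty.
#' @return data.frame: id, group, age, pcs_mean, dan_mean.
#' @export
cohortNetworkMeans <- function(cohort, patterns) {
  if (!any(patterns@positiveMask) || !any(patterns@negativeMask))
    stop(paste("a pattern side is empty; re-extract with a lower",
               "percentile to retain voxels on both sides"))
  pcs <- vapply(cohort@volumes, meanInMask, numeric(1),
                mask = patterns@positiveMask)
  dan <- vapply(cohort@volumes, meanInMask, numeric(1),
                mask = patterns@negativeMask)
  data.frame(id = cohort@covariates$id, group = cohort@covariates$group,
             age = cohort@covariates$age,
             pcs_mean = unname(pcs), dan_mean = unname(dan),
             stringsAsFactors = FALSE)
}

#' Dice overlap coefficient between two binary masks
#'
#' 2 |A intersect B| / (|A| + |B|); 0 when both masks are empty.
#'
#' @param a,b logical arrays of identical dimension.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}

#' Write a binary mask as a NIfTI volume
#'
#' @param mask logical 3D array.
#' @param file output path.
#' @param voxelSizeMm voxel size for the header.
#' @return the file path, invisibly.
#' @export
writeMask <- function(mask, file, voxelSizeMm = 2) {
  writeVolume(VolumeImage(array(as.numeric(mask), dim = dim(mask)),
                          voxelSize = voxelSizeMm), file)
  invisible(file)
}
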