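# Reference-region intensity normalization and 3D Gaussian smoothing.

#' Reference region of interest in mm
#'
#' An axis-aligned open box in mm coordinates; a voxel belongs to the ROI
#' when its center falls strictly inside all three open intervals.  The
#' open-inequality convention is documented because voxel counts depend on
#' it: the default pontine-style 16 x 8 x 10 mm box samples 160 voxels on a
#' 2 mm grid.
#'
#' @slot boundsMm numeric(6): x_lo, x_hi, y_lo, y_hi, z_lo, z_hi.
#'
#' @exportClass ReferenceROI
setClass("ReferenceROI", slots = c(boundsMm = "numeric"))

setValidity("ReferenceROI", function(object) {
  b <- object@boundsMm
  if (length(b) != 6L) return("boundsMm must have 6 values")
  if (any(b[c(1, 3, 5)] >= b[c(2, 4, 6)]))
    return("each axis needs lo < hi")
  TRUE
})

#' Construct a ReferenceROI
#'
#' @param boundsMm numeric(6) open bounds (x_lo, x_hi, y_lo, y_hi, z_lo, z_hi)
#'   in mm.  The default is the synthetic pons box used by the simulator.
#' @return A \linkS4class{ReferenceROI}.
#' @export
referenceROI <- function(boundsMm = c(-8, 8, -16, -8, -34, -24)) {
  new("ReferenceROI", boundsMm = as.numeric(boundsMm))
}

setMethod("show", "ReferenceROI", function(object) {
  b <- object@boundsMm
  cat(sprintf("ReferenceROI: %g < x < %g, %g < y < %g, %g < z < %g (mm)\n",
              b[1], b[2], b[3], b[4], b[5], b[6]))
})

.roiVoxelMask <- function(vol, roi) {
  b <- roi@boundsMm
  cx <- voxelCenters(vol, 1); cy <- voxelCenters(vol, 2); cz <- voxelCenters(vol, 3)
  outer(outer(cx > b[1] & cx < b[2], cy > b[3] & cy < b[4], `&`),
        cz > b[5] & cz < b[6], `&`)
}

#' Mean count inside a reference ROI
#'
#' Arithmetic mean over voxels whose centers fall strictly inside the ROI's
#' open mm bounds.
#'
#' @param vol a \linkS4class{VolumeImage}.
#' @param roi a \linkS4class{ReferenceROI}.
#' @return scalar mean count.
#' @export
sampleReferenceMean <- function(vol, roi) {
  m <- .roiVoxelMask(vol, roi)
  if (!any(m)) {
    b <- roi@boundsMm
    stop(sprintf(paste0("reference ROI (%g,%g)x(%g,%g)x(%g,%g) mm contains ",
                        "no voxel centers of this volume"),
                 b[1], b[2], b[3], b[4], b[5], b[6]))
  }
  mean(vol@data[m])
}

#' Normalize a volume to its reference-region mean
#'
#' Divides every voxel by the mean count of the reference ROI, so the
#' output's reference mean is 1.  Idempotent, and invariant to a global
#' positive rescaling of the input.
#'
#' @param vol a \linkS4class{VolumeImage}.
#' @param roi a \linkS4class{ReferenceROI}.
#' @return The normalized \linkS4class{VolumeImage}.
#' @export
normalizeToReference <- function(vol, roi) {
  ref <- sampleReferenceMean(vol, roi)
  if (ref <= 0)
    stop(sprintf("reference mean is %.4g (must be > 0): corrupted input?", ref))
  VolumeImage(vol@data / ref, voxelSize = vol@voxelSize, origin = vol@origin)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm full width at half maximum.
#' @return sigma = fwhm / (2 * sqrt(2 * ln 2)).
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D convolution operator (n x n) for kernel k (odd length), reflect boundary
# (edge-repeating mirror: d c b a | a b c d | d c b a)
.convMatrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- (i - r):(i + r)
    # reflect indices into 1..n (period-2n fold, edge repeated)
    q <- (src - 1L) %% (2L * n)
    src <- ifelse(q < n, q + 1L, 2L * n - q)
    for (o in seq_along(k)) C[i, src[o]] <- C[i, src[o]] + k[o]
  }
  C
}

.convolveAxis <- function(arr, k, axis) {
  d <- dim(arr)
  if (axis != 1L) {
    perm <- switch(axis, NULL, c(2L, 1L, 3L), c(3L, 1L, 2L))
    arr <- aperm(arr, perm)
  }
  dp <- dim(arr)
  C <- .convMatrix(dp[1], k)
  out <- array(C %*% matrix(arr, dp[1]), dim = dp)
  if (axis == 2L) out <- aperm(out, c(2L, 1L, 3L))
  if (axis == 3L) out <- aperm(out, c(2L, 3L, 1L))
  out
}

#' Isotropic 3D Gaussian smoothing
#'
#' Separable Gaussian blur with sigma (mm) = fwhm / (2 sqrt(2 ln 2)) per
#' axis, converted to voxels through the volume's voxel size; reflect
#' boundary handling (avoids edge dimming on small grids).  The discrete
#' kernel is a normalized sampled Gaussian truncated at 4 sigma.  A FWHM of
#' 0 is the identity.
#'
#' @param vol a \linkS4class{VolumeImage}.
#' @param fwhmMm isotropic FWHM in mm (>= 0).
#' @return The smoothed \linkS4class{VolumeImage}.
#' @export
smoothGaussian <- function(vol, fwhmMm) {
  stopifnot(fwhmMm >= 0)
  if (fwhmMm == 0) return(vol)
  out <- vol@data
  for (axis in 1:3) {
    sigmaVox <- fwhmToSigma(fwhmMm) / vol@voxelSize[axis]
    r <- max(1L, ceiling(4 * sigmaVox))
    k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
    k <- k / sum(k)
    out <- .convolveAxis(out, k, axis)
  }
  VolumeImage(out, voxelSize = vol@voxelSize, origin = vol@origin)
}

#' Preprocess a cohort: smooth, then normalize
#'
#' Applies the pipeline's fixed preprocessing order — Gaussian smoothing
#' followed by reference-region normalization — to every subject volume.
#'
#' @param cohort a \linkS4class{PETCohort}.
#' @param roi a \linkS4class{ReferenceROI}.
#' @param fwhmMm smoothing FWHM in mm (default 12).
#' @return The preprocessed \linkS4class{PETCohort}.
#' @export
preprocessCohort <- function(cohort, roi = referenceROI(), fwhmMm = 12) {
  vols <- lapply(cohort@volumes, function(v)
    normalizeToReference(smoothGaussian(v, fwhmMm), roi))
  new("PETCohort", volumes = vols, covariates = cohort@covariates)
}
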