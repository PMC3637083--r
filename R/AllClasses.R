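#' @import methods
NULL

#' 3D scalar brain volume
#'
#' A 3D grid of metabolic counts (arbitrary units) together with its voxel
#' size and the mm coordinate of the first voxel's center.  The mm coordinate
#' of voxel (i, j, k) (1-based) is \code{origin + (c(i, j, k) - 1) * voxelSize}.
#'
#' @slot data 3D numeric array of voxel values; finite values only.
#' @slot voxelSize numeric(3), per-axis voxel edge length in mm (all > 0).
#' @slot origin numeric(3), mm coordinate of the center of voxel (1,1,1).
#'
#' @exportClass VolumeImage
setClass("VolumeImage",
         slots = c(data = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite mm coordinates")
  if (any(!is.finite(object@data)))
    return("volume contains non-finite values")
  TRUE
})

#' Construct a VolumeImage
#'
#' @param data 3D numeric array.
#' @param voxelSize voxel edge length(s) in mm; length 1 (isotropic) or 3.
#' @param origin mm coordinate of the center of voxel (1,1,1).  The default
#'   centers the grid on the mm origin, so coordinates run symmetrically
#'   about 0 on every axis (an MNI-like frame for the synthetic phantom).
#' @return A \linkS4class{VolumeImage}.
#' @export
VolumeImage <- function(data, voxelSize = 2, origin = NULL) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxelSize
  new("VolumeImage", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' @describeIn VolumeImage voxel data array
#' @param x,object a \code{VolumeImage}
#' @export
volumeData <- function(x) x@data

#' @describeIn VolumeImage per-axis voxel size in mm
#' @export
voxelSize <- function(x) x@voxelSize

#' mm coordinates of voxel centers along one axis
#'
#' @param x a \linkS4class{VolumeImage}
#' @param axis 1, 2 or 3
#' @return numeric vector of voxel-center coordinates in mm.
#' @export
voxelCenters <- function(x, axis) {
  x@origin[axis] + (seq_len(dim(x@data)[axis]) - 1) * x@voxelSize[axis]
}

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

#' Simulation specification for a synthetic PET cohort
#'
#' Parameters of the generative model for a two-group (CHT / no-CHT)
#' FDG-PET phantom cohort.  Voxel values follow
#' \code{baseline * g(age) * (1 - chtEffect * [CHT] * [voxel in PCS]) + noise},
#' blurred by a Gaussian point-spread function; the reference region receives
#' neither the age nor the group modulation.
#'
#' @slot gridShape integer(3), voxel counts per axis.
#' @slot voxelSizeMm isotropic voxel size, mm.
#' @slot nPerGroup subjects per group (>= 2).
#' @slot ageRange numeric(2), years.
#' @slot globalAgeSlope fractional change of brain metabolism per year
#'   (negative: decline with age).
#' @slot networkAgeGain multiplier on the age slope inside the two planted
#'   networks (>= 1).  Values above 1 make the networks more age-sensitive
#'   than the rest of the brain, giving them the strong shared
#'   age-driven covariance that real resting-state networks show relative
#'   to background tissue.
#' @slot chtEffect fractional reduction of PCS-network intensity in the
#'   treated group, in [0, 1).
#' @slot noiseSd SD of additive voxel noise as a fraction of baseline, in [0, 1).
#' @slot psfFwhmMm simulated scanner blur, FWHM in mm (>= 0).
#' @slot seed integer RNG seed (required; same seed + spec gives a
#'   bit-identical cohort).
#'
#' @exportClass SimulationSpec
setClass("SimulationSpec",
         slots = c(gridShape = "integer", voxelSizeMm = "numeric",
                   nPerGroup = "integer", ageRange = "numeric",
                   globalAgeSlope = "numeric", networkAgeGain = "numeric",
                   chtEffect = "numeric",
                   noiseSd = "numeric", psfFwhmMm = "numeric",
                   seed = "integer"))

setValidity("SimulationSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be 3 positive voxel counts")
  if (object@voxelSizeMm <= 0) return("voxelSizeMm must be > 0")
  if (object@nPerGroup < 2L) return("nPerGroup must be >= 2")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    return("ageRange must be an increasing pair of years")
  if (object@networkAgeGain < 1) return("networkAgeGain must be >= 1")
  if (object@chtEffect < 0 || object@chtEffect >= 1)
    return("chtEffect must be in [0, 1)")
  if (object@noiseSd < 0 || object@noiseSd >= 1)
    return("noiseSd must be in [0, 1)")
  if (object@psfFwhmMm < 0) return("psfFwhmMm must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is required")
  TRUE
})

#' Construct a SimulationSpec
#'
#' Defaults define the package's reference study conditions: a 48 x 56 x 44
#' grid of 2 mm voxels, 14 subjects per group aged 35-69, a global metabolic
#' decline of 0.8\% per year, a 10\% PCS hypometabolism in the treated group,
#' 5\% voxel noise and a 6 mm FWHM scanner point-spread function.
#'
#' @param gridShape voxel counts per axis.
#' @param voxelSizeMm isotropic voxel size in mm.
#' @param nPerGroup subjects per group.
#' @param ageRange age range in years.
#' @param globalAgeSlope fractional metabolism change per year.
#' @param networkAgeGain age-slope multiplier inside the planted networks.
#' @param chtEffect fractional PCS reduction in the treated group.
#' @param noiseSd additive noise SD as fraction of baseline.
#' @param psfFwhmMm scanner blur FWHM, mm.
#' @param seed integer RNG seed (required).
#' @return A \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(gridShape = c(48L, 56L, 44L), voxelSizeMm = 2,
                           nPerGroup = 14L, ageRange = c(35, 69),
                           globalAgeSlope = -0.008, networkAgeGain = 1.75,
                           chtEffect = 0.10,
                           noiseSd = 0.05, psfFwhmMm = 6, seed) {
  if (missing(seed)) stop("seed is required for a SimulationSpec")
  new("SimulationSpec", gridShape = as.integer(gridShape),
      voxelSizeMm = as.numeric(voxelSizeMm), nPerGroup = as.integer(nPerGroup),
      ageRange = as.numeric(ageRange), globalAgeSlope = as.numeric(globalAgeSlope),
      networkAgeGain = as.numeric(networkAgeGain), chtEffect = as.numeric(chtEffect), noiseSd = as.numeric(noiseSd),
      psfFwhmMm = as.numeric(psfFwhmMm), seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: %d x %d x %d @ %g mm, %d per group, ",
                     "ages %g-%g\n  age slope %g/yr (x%g in networks), CHT effect %g, ",
                     "noise %g, PSF %g mm, seed %d\n"),
              object@gridShape[1], object@gridShape[2], object@gridShape[3],
              object@voxelSizeMm, object@nPerGroup,
              object@ageRange[1], object@ageRange[2],
              object@globalAgeSlope, object@networkAgeGain,
              object@chtEffect, object@noiseSd,
              object@psfFwhmMm, object@seed))
})

#' Planted network masks of the synthetic phantom
#'
#' Binary masks on the simulation grid: the brain envelope, the two planted
#' metabolic networks (PCS: bilateral prefrontal + posterior-inferior
#' cerebellar blobs; DAN: bilateral superior-parietal + dorsal-frontal
#' blobs) and the stable reference region (a small central-inferior box,
#' the synthetic pons).  PCS and DAN are disjoint, both are inside the brain,
#' and the reference region overlaps neither.
#'
#' @slot brain,pcs,dan,reference logical 3D arrays of identical dimension.
#'
#' @exportClass NetworkMasks
setClass("NetworkMasks",
         slots = c(brain = "array", pcs = "array", dan = "array",
                   reference = "array"))

setValidity("NetworkMasks", function(object) {
  dm <- dim(object@brain)
  for (s in c("pcs", "dan", "reference"))
    if (!identical(dim(slot(object, s)), dm))
      return("all masks must share a dimension")
  if (any(object@pcs & object@dan)) return("pcs and dan must be disjoint")
  if (any(object@reference & (object@pcs | object@dan)))
    return("reference region must not overlap pcs or dan")
  if (any((object@pcs | object@dan | object@reference) & !object@brain))
    return("pcs, dan and reference must lie inside the brain mask")
  for (s in c("brain", "pcs", "dan", "reference"))
    if (!any(slot(object, s))) return(sprintf("mask '%s' is empty", s))
  TRUE
})

setMethod("show", "NetworkMasks", function(object) {
  cat(sprintf("NetworkMasks: brain %d, pcs %d, dan %d, reference %d voxels\n",
              sum(object@brain), sum(object@pcs), sum(object@dan),
              sum(object@reference)))
})

#' Synthetic PET cohort
#'
#' An aligned set of subject volumes and a covariate table.  Covariate
#' columns: \code{id}, \code{group} (factor CHT / NOCHT), \code{age},
#' \code{gender} (M / F), \code{depression} (0-21) and
#' \code{months_post_treatment} (CHT subjects only, otherwise NA).
#'
#' @slot volumes list of \linkS4class{VolumeImage}, one per subject, named by id.
#' @slot covariates data.frame, one row per subject, aligned with volumes.
#'
#' @exportClass PETCohort
setClass("PETCohort",
         slots = c(volumes = "list", covariates = "data.frame"))

setValidity("PETCohort", function(object) {
  if (length(object@volumes) != nrow(object@covariates))
    return("volumes and covariates must align")
  need <- c("id", "group", "age", "gender", "depression",
            "months_post_treatment")
  if (!all(need %in% names(object@covariates)))
    return(paste("covariates must contain:", paste(need, collapse = ", ")))
  if (!identical(names(object@volumes), as.character(object@covariates$id)))
    return("volume names must equal covariate ids, in order")
  if (!all(levels(object@covariates$group) == c("CHT", "NOCHT")))
    return("group must be a factor with levels CHT, NOCHT")
  TRUE
})

#' @describeIn PETCohort covariate table
#' @param x a \code{PETCohort}
#' @export
covariates <- function(x) x@covariates

#' @describeIn PETCohort list of subject volumes
#' @export
volumes <- function(x) x@volumes

#' @describeIn PETCohort number of subjects
#' @export
nSubjects <- function(x) nrow(x@covariates)

setMethod("show", "PETCohort", function(object) {
  tb <- table(object@covariates$group)
  cat(sprintf("PETCohort: %d subjects (%s)\n", nSubjects(object),
              paste(sprintf("%s n=%d", names(tb), tb), collapse = ", ")))
})

#' Subject-by-voxel feature matrix
#'
#' Rows are subjects, columns are brain-mask voxels in lexicographic
#' (x, then y, then z) coordinate order; values are (normalized) metabolism.
#' Labels follow the convention +1 = NOCHT, -1 = CHT.
#'
#' @slot values numeric matrix, subjects x voxels.
#' @slot labels numeric vector of +1 / -1, one per row.
#' @slot voxelIndex integer matrix (voxels x 3) mapping columns to 3D voxel
#'   coordinates.
#' @slot dim integer(3), the grid the voxel coordinates refer to.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
         slots = c(values = "matrix", labels = "numeric",
                   voxelIndex = "matrix", dim = "integer"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@labels))
    return("one label per row required")
  if (ncol(object@values) != nrow(object@voxelIndex))
    return("voxelIndex must map every column")
  if (!all(object@labels %in% c(-1, 1)))
    return("labels must be +1 (NOCHT) or -1 (CHT)")
  if (any(!is.finite(object@values)))
    return("feature matrix contains missing values")
  TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d subjects x %d voxels (+1: %d, -1: %d)\n",
              nrow(object@values), ncol(object@values),
              sum(object@labels == 1), sum(object@labels == -1)))
})

#' Linear SVM weight map
#'
#' The separating hyperplane w . v + b = 0 of a linear nu-SVM, with one
#' weight per brain-mask voxel (same column order as the
#' \linkS4class{FeatureMatrix} it was trained on).
#'
#' @slot w numeric weight vector.
#' @slot b offset scalar.
#' @slot voxelIndex integer matrix (voxels x 3) mapping weights to voxels.
#' @slot dim integer(3) grid dimension.
#' @slot nu the nu used for training.
#'
#' @exportClass WeightMap
setClass("WeightMap",
         slots = c(w = "numeric", b = "numeric", voxelIndex = "matrix",
                   dim = "integer", nu = "numeric"))

setValidity("WeightMap", function(object) {
  if (length(object@w) != nrow(object@voxelIndex))
    return("one weight per voxel required")
  if (any(!is.finite(object@w)) || !is.finite(object@b))
    return("weights and offset must be finite")
  TRUE
})

#' @describeIn WeightMap the weight vector
#' @param x,object a \code{WeightMap}
#' @export
weights <- function(x) x@w

#' @describeIn WeightMap the hyperplane offset
#' @export
offset <- function(x) x@b

setMethod("show", "WeightMap", function(object) {
  cat(sprintf("WeightMap: %d voxel weights, b = %.4g, nu = %g, |w| in [%.3g, %.3g]\n",
              length(object@w), object@b, object@nu,
              min(abs(object@w)), max(abs(object@w))))
})

#' Signed weight patterns (networks)
#'
#' The two disjoint binary masks obtained by thresholding a weight map at a
#' percentile of |w| over the brain mask: voxels with w >= +threshold
#' (positive pattern) and w <= -threshold (negative pattern).
#'
#' @slot positiveMask,negativeMask logical 3D arrays.
#' @slot percentile the percentile of |w| used (0 < p < 100).
#' @slot thresholdValue the realized |w| cut.
#'
#' @exportClass SignedPatterns
setClass("SignedPatterns",
         slots = c(positiveMask = "array", negativeMask = "array",
                   percentile = "numeric", thresholdValue = "numeric"))

setValidity("SignedPatterns", function(object) {
  if (!identical(dim(object@positiveMask), dim(object@negativeMask)))
    return("masks must share a dimension")
  if (any(object@positiveMask & object@negativeMask))
    return("signed masks must be disjoint")
  TRUE
})

setMethod("show", "SignedPatterns", function(object) {
  cat(sprintf("SignedPatterns: p%g of |w| -> threshold %.4g; positive %d, negative %d voxels\n",
              object@percentile, object@thresholdValue,
              sum(object@positiveMask), sum(object@negativeMask)))
})

#' Cut-off classification model on network means
#'
#' Either a single-feature threshold (kind "single") or a line
#' PCS = intercept + slope * DAN in (DAN, PCS) space (kind "line"; vertical
#' lines are encoded by \code{vertical = TRUE} with \code{threshold} on DAN).
#' \code{orientation} states which side maps to CHT ("below" or "above" the
#' threshold / line); boundary points always resolve to the no-CHT side.
#'
#' @slot kind "single" or "line".
#' @slot feature "pcs" or "dan" (single kind only).
#' @slot threshold scalar threshold (single kind, or vertical line).
#' @slot slope,intercept line parameters (line kind).
#' @slot vertical logical; TRUE encodes a vertical line in (DAN, PCS) space.
#' @slot orientation "below" or "above": the CHT side.
#' @slot degenerate logical; TRUE when the search saw constant values with
#'   mixed labels.
#'
#' @exportClass CutoffModel
setClass("CutoffModel",
         slots = c(kind = "character", feature = "character",
                   threshold = "numeric", slope = "numeric",
                   intercept = "numeric", vertical = "logical",
                   orientation = "character", degenerate = "logical"),
         prototype = list(feature = NA_character_, threshold = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          vertical = FALSE, degenerate = FALSE))

setValidity("CutoffModel", function(object) {
  if (!object@kind %in% c("single", "line")) return("kind must be single or line")
  if (!object@orientation %in% c("below", "above"))
    return("orientation must be below or above")
  if (object@kind == "single") {
    if (!object@feature %in% c("pcs", "dan")) return("single model needs a feature")
    if (is.na(object@threshold)) return("single model needs a threshold")
  } else if (!object@vertical &&
             (is.na(object@slope) || is.na(object@intercept))) {
    return("line model needs slope and intercept (or vertical + threshold)")
  } else if (object@vertical && is.na(object@threshold)) {
    return("vertical line model needs a threshold")
  }
  TRUE
})

setMethod("show", "CutoffModel", function(object) {
  if (object@kind == "single") {
    cat(sprintf("CutoffModel: %s %s %.4g => CHT\n", object@feature,
                ifelse(object@orientation == "below", "<", ">"),
                object@threshold))
  } else if (object@vertical) {
    cat(sprintf("CutoffModel: vertical line, DAN %s %.4g => CHT\n",
                ifelse(object@orientation == "below", "<", ">"),
                object@threshold))
  } else {
    cat(sprintf("CutoffModel: PCS %s %.4g + %.4g * DAN => CHT\n",
                ifelse(object@orientation == "below", "<", ">"),
                object@intercept, object@slope))
  }
})

#' Cross-validation result
#'
#' @slot folds data.frame with columns fold, id, truth, prediction (one row
#'   per held-out subject prediction).
#' @slot overallAccuracy fraction of correct held-out predictions.
#'
#' @exportClass CVResult
setClass("CVResult",
         slots = c(folds = "data.frame", overallAccuracy = "numeric"))

setValidity("CVResult", function(object) {
  if (object@overallAccuracy < 0 || object@overallAccuracy > 1)
    return("overallAccuracy must be in [0, 1]")
  TRUE
})

#' @describeIn CVResult overall held-out accuracy
#' @param x,object a \code{CVResult}
#' @export
cvAccuracy <- function(x) x@overallAccuracy

#' @describeIn CVResult per-prediction fold table
#' @export
cvFolds <- function(x) x@folds

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d folds, %d held-out predictions, accuracy %.3f\n",
              length(unique(object@folds$fold)), nrow(object@folds),
              object@overallAccuracy))
})

#' Result of a statistical test
#'
#' @slot statistic test statistic.
#' @slot df degrees of freedom (NA where not applicable).
#' @slot p.value two-tailed p value.
#' @slot estimate effect measure (mean difference, r, tau-b, adjusted group
#'   effect) where applicable.
#' @slot r.squared model r-squared (ANCOVA only, else NA).
#' @slot method short description.
#'
#' @exportClass StatResult
setClass("StatResult",
         slots = c(statistic = "numeric", df = "numeric", p.value = "numeric",
                   estimate = "numeric", r.squared = "numeric",
                   method = "character"),
         prototype = list(estimate = NA_real_, r.squared = NA_real_,
                          df = NA_real_))

setValidity("StatResult", function(object) {
  if (is.na(object@p.value) || object@p.value < 0 || object@p.value > 1)
    return("p.value must be in [0, 1]")
  TRUE
})

#' @describeIn StatResult two-tailed p value
#' @param x,object a \code{StatResult}
#' @export
pValue <- function(x) x@p.value

#' @describeIn StatResult test statistic
#' @export
statistic <- function(x) x@statistic

#' @describeIn StatResult effect estimate
#' @export
estimate <- function(x) x@estimate

setMethod("show", "StatResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g", object@method,
              object@statistic,
              ifelse(is.na(object@df), "NA", format(object@df)),
              object@p.value))
  if (!is.na(object@estimate)) cat(sprintf(", estimate = %.4g", object@estimate))
  if (!is.na(object@r.squared)) cat(sprintf(", r2 = %.3f", object@r.squared))
  cat("\n")
})
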