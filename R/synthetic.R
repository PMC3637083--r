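# Synthetic FDG-PET phantom cohorts with planted metabolic networks.
# The two networks share an amplified age sensitivity (networkAgeGain),
# which gives them the strong joint age-driven covariance, relative to
# background tissue, that the downstream pattern analysis exploits.
#
# The phantom brain is an axis-aligned ellipsoid filling 90% of the grid
# extent.  Two disjoint networks are planted as unions of bilateral spheres
# (defined in mm, mirrored across the midsagittal plane) and a small
# central-inferior box serves as the stable reference region (the synthetic
# pons).  All template geometry is fixed in mm so masks are comparable
# across voxel sizes.

.BASELINE <- 100  # metabolic counts, arbitrary units

# template blob centers (mm, relative to grid center) and radii (mm)
.PCS_BLOBS <- list(
  list(center = c(18, 30, 8),    radius = 12),  # prefrontal, right
  list(center = c(-18, 30, 8),   radius = 12),  # prefrontal, left
  list(center = c(14, -28, -20), radius = 10),  # cerebellar, right
  list(center = c(-14, -28, -20), radius = 10)) # cerebellar, left
.DAN_BLOBS <- list(
  list(center = c(16, -14, 26),  radius = 11),  # superior parietal, right
  list(center = c(-16, -14, 26), radius = 11),  # superior parietal, left
  list(center = c(16, 14, 26),   radius = 9),   # dorsal frontal (FEF), right
  list(center = c(-16, 14, 26),  radius = 9))   # dorsal frontal (FEF), left

# reference box: open mm bounds (x_lo, x_hi, y_lo, y_hi, z_lo, z_hi),
# a 16 x 8 x 10 mm central-inferior box
.REFERENCE_BOUNDS <- c(-8, 8, -16, -8, -34, -24)

.gridCenters <- function(spec) {
  d <- spec@gridShape; vs <- spec@voxelSizeMm
  lapply(1:3, function(a) (seq_len(d[a]) - 1 - (d[a] - 1) / 2) * vs)
}

.ellipsoidMask <- function(centers, semi) {
  d <- vapply(centers, length, 1L)
  x2 <- (centers[[1]] / semi[1])^2
  y2 <- (centers[[2]] / semi[2])^2
  z2 <- (centers[[3]] / semi[3])^2
  outer(outer(x2, y2, `+`), z2, `+`) <= 1
}

.sphereMask <- function(centers, center, radius) {
  x2 <- (centers[[1]] - center[1])^2
  y2 <- (centers[[2]] - center[2])^2
  z2 <- (centers[[3]] - center[3])^2
  outer(outer(x2, y2, `+`), z2, `+`) <= radius^2
}

.boxMask <- function(centers, bounds) {
  inx <- centers[[1]] > bounds[1] & centers[[1]] < bounds[2]
  iny <- centers[[2]] > bounds[3] & centers[[2]] < bounds[4]
  inz <- centers[[3]] > bounds[5] & centers[[3]] < bounds[6]
  outer(outer(inx, iny, `&`), inz, `&`)
}

#' Build the planted network masks for a simulation grid
#'
#' Deterministic for a fixed spec.  The brain is an ellipsoid with semi-axes
#' 45\% of the grid extent; PCS and DAN are unions of bilateral spheres
#' (left-right symmetric about the midsagittal plane); the reference region
#' is a 16 x 8 x 10 mm box placed central-inferior, well inside the brain.
#' PCS and DAN are clipped to the brain and the reference region is excluded
#' from both, so all \linkS4class{NetworkMasks} invariants hold by
#' construction.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return A \linkS4class{NetworkMasks}.
#' @export
makeNetworkMasks <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  d <- spec@gridShape; vs <- spec@voxelSizeMm
  extent <- d * vs
  semi <- 0.45 * extent
  centers <- .gridCenters(spec)

  # every template must fit inside the grid extent
  blobs <- c(.PCS_BLOBS, .DAN_BLOBS)
  reach <- vapply(blobs, function(b) max(abs(b$center) + b$radius), numeric(1))
  lim <- rep(extent / 2, length.out = 3)
  fits <- vapply(blobs, function(b)
    all(abs(b$center) + b$radius <= extent / 2), logical(1))
  refFits <- all(abs(.REFERENCE_BOUNDS) <= rep(extent / 2, each = 2))
  if (!all(fits) || !refFits)
    stop(sprintf(paste0("grid too small for network mask templates: extent ",
                        "%g x %g x %g mm cannot contain blobs reaching %g mm ",
                        "from center"), extent[1], extent[2], extent[3],
                 max(reach)))

  brain <- .ellipsoidMask(centers, semi)
  reference <- .boxMask(centers, .REFERENCE_BOUNDS)
  pcs <- Reduce(`|`, lapply(.PCS_BLOBS, function(b)
    .sphereMask(centers, b$center, b$radius)))
  dan <- Reduce(`|`, lapply(.DAN_BLOBS, function(b)
    .sphereMask(centers, b$center, b$radius)))
  pcs <- pcs & brain & !reference
  dan <- dan & brain & !reference & !pcs
  if (!any(reference & brain))
    stop("grid too small: reference region falls outside the brain ellipsoid")
  reference <- reference & brain

  new("NetworkMasks", brain = brain, pcs = pcs, dan = dan,
      reference = reference)
}

#' Simulate one subject volume
#'
#' Voxel values follow the multiplicative model
#' \code{baseline * g(age) * (1 - chtEffect * [CHT] * [voxel in PCS]) + noise}
#' inside the brain, where \code{g(age) = 1 + globalAgeSlope * (age - midpoint)}
#' and the midpoint is the center of the spec's age range.  Inside the two
#' planted networks the age slope is multiplied by \code{networkAgeGain},
#' giving PCS and DAN the strong shared age-driven covariance that real
#' resting-state networks show relative to background tissue.
#' Reference-region
#' voxels receive neither the age nor the group modulation (a stable
#' reference); voxels outside the brain are zero.  Additive Gaussian noise
#' (SD = \code{noiseSd * baseline}) is applied inside the brain, then the
#' whole volume is blurred by the scanner point-spread function
#' (\code{psfFwhmMm}), so the noise is spatially correlated as in
#' reconstructed PET.
#'
#' Randomness is drawn from the current RNG state; \code{\link{simulateCohort}}
#' seeds it from the spec.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param masks matching \linkS4class{NetworkMasks}.
#' @param group "CHT" or "NOCHT".
#' @param age subject age in years (within the spec's range).
#' @return A \linkS4class{VolumeImage}.
#' @export
simulateSubject <- function(spec, masks, group, age) {
  group <- match.arg(group, c("CHT", "NOCHT"))
  if (age < spec@ageRange[1] || age > spec@ageRange[2])
    stop("age outside the spec's age range")
  d <- spec@gridShape
  mid <- mean(spec@ageRange)
  g <- 1 + spec@globalAgeSlope * (age - mid)
  # networks decline faster with age than background tissue
  gNet <- 1 + spec@networkAgeGain * spec@globalAgeSlope * (age - mid)

  vol <- array(0, dim = d)
  modulated <- masks@brain & !masks@reference
  vol[modulated] <- .BASELINE * g
  net <- masks@pcs | masks@dan
  vol[net] <- .BASELINE * gNet
  vol[masks@reference] <- .BASELINE
  if (group == "CHT" && spec@chtEffect > 0)
    vol[masks@pcs] <- vol[masks@pcs] * (1 - spec@chtEffect)
  if (spec@noiseSd > 0) {
    nb <- sum(masks@brain)
    vol[masks@brain] <- vol[masks@brain] +
      stats::rnorm(nb, sd = spec@noiseSd * .BASELINE)
  }
  img <- VolumeImage(vol, voxelSize = spec@voxelSizeMm)
  if (spec@psfFwhmMm > 0) img <- smoothGaussian(img, spec@psfFwhmMm)
  img
}

#' Simulate a full two-group cohort
#'
#' Generates 2 * nPerGroup subjects.  Ages are drawn uniformly over the
#' spec's range for one group and mirrored into the other, so the groups are
#' exactly age-matched; gender is assigned deterministically with the same
#' margin in both groups (12 M / 2 F at the default group size of 14);
#' depression scores (0-21) are shared draws; months since treatment is
#' sampled (gamma, mean 7, SD 9) for treated subjects only.  Rows 1..n are
#' NOCHT, rows n+1..2n are CHT.  Fully reproducible from the spec's seed.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return A list with elements \code{cohort} (\linkS4class{PETCohort}) and
#'   \code{masks} (\linkS4class{NetworkMasks}).
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  masks <- makeNetworkMasks(spec)
  set.seed(spec@seed)
  n <- spec@nPerGroup

  ages <- round(stats::runif(n, spec@ageRange[1], spec@ageRange[2]))
  nM <- round(12 / 14 * n)
  gender <- factor(c(rep("M", nM), rep("F", n - nM)), levels = c("M", "F"))
  depression <- pmin(21L, pmax(0L, round(stats::rnorm(2 * n, 4, 3))))
  monthsCht <- round(stats::rgamma(n, shape = (7 / 9)^2, scale = 9^2 / 7))

  covar <- data.frame(
    id = sprintf("S%02d", seq_len(2 * n)),
    group = factor(rep(c("NOCHT", "CHT"), each = n),
                   levels = c("CHT", "NOCHT")),
    age = c(ages, ages),                       # mirrored: exact age match
    gender = c(gender, gender),
    depression = depression,
    months_post_treatment = c(rep(NA_real_, n), monthsCht),
    stringsAsFactors = FALSE)

  vols <- vector("list", 2 * n)
  for (i in seq_len(2 * n))
    vols[[i]] <- simulateSubject(spec, masks,
                                 as.character(covar$group[i]), covar$age[i])
  names(vols) <- covar$id

  list(cohort = new("PETCohort", volumes = vols, covariates = covar),
       masks = masks)
}
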