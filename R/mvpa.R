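# Whole-brain linear nu-SVM group discrimination.
#
# Training is delegated to libsvm (via e1071); the explicit hyperplane
# w . v + b = 0 is reconstructed from the support-vector expansion
# (w = t(coefs) %*% SV, b = -rho) and re-oriented so that a positive
# decision value means class +1 (NOCHT).

#' Build the subject-by-voxel feature matrix
#'
#' Every brain-mask voxel is one feature.  Columns are ordered
#' lexicographically by voxel coordinate (x, then y, then z), rows follow
#' cohort order; labels are +1 for NOCHT and -1 for CHT.
#'
#' @param cohort a \linkS4class{PETCohort} (all volumes on one grid).
#' @param brainMask logical 3D array.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(cohort, brainMask) {
  if (!any(brainMask)) stop("brain mask is empty")
  d <- dim(brainMask)
  for (id in names(cohort@volumes))
    if (!identical(dim(cohort@volumes[[id]]@data), d))
      stop(sprintf("subject %s: volume grid does not match the brain mask", id))
  coords <- which(brainMask, arr.ind = TRUE)
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  lin <- coords[, 1] + d[1] * (coords[, 2] - 1) + d[1] * d[2] * (coords[, 3] - 1)
  X <- t(vapply(cohort@volumes, function(v) v@data[lin],
                numeric(length(lin))))
  labels <- ifelse(cohort@covariates$group == "NOCHT", 1, -1)
  new("FeatureMatrix", values = unname(X), labels = as.numeric(labels),
      voxelIndex = coords, dim = as.integer(d))
}

.svmFit <- function(X, labels, nu) {
  if (length(unique(labels)) < 2L)
    stop("training data contain a single class; two classes are required")
  y <- factor(labels, levels = c(-1, 1))
  model <- tryCatch(
    e1071::svm(X, y, type = "nu-classification", kernel = "linear",
               nu = nu, scale = FALSE),
    error = function(e) {
      if (grepl("infeasible", conditionMessage(e), ignore.case = TRUE))
        stop(sprintf("nu = %g is infeasible for this class balance", nu),
             call. = FALSE)
      stop(sprintf("nu-SVM training failed numerically: %s",
                   conditionMessage(e)), call. = FALSE)
    })
  w <- unname(drop(t(model$coefs) %*% model$SV))
  b <- -model$rho
  # libsvm's positive decision value corresponds to the class named first in
  # the decision-value column "A/B"; flip so positive means label +1
  dv <- attr(stats::predict(model, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  posClass <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (posClass != "1") { w <- -w; b <- -b }
  list(w = w, b = b)
}

#' Train a linear nu-SVM and recover its weight map
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param nu regularization fraction in (0, 1).
#' @return A \linkS4class{WeightMap} whose decision function
#'   \code{sign(w . x + b)} reproduces the trained machine's predictions on
#'   every training row.
#' @export
trainNuSvm <- function(fm, nu = 0.5) {
  stopifnot(nu > 0, nu < 1)
  fit <- .svmFit(fm@values, fm@labels, nu)
  new("WeightMap", w = fit$w, b = fit$b, voxelIndex = fm@voxelIndex,
      dim = fm@dim, nu = nu)
}

#' Classify a feature vector with a weight map
#'
#' Returns +1 (NOCHT) when w . x + b > 0, -1 (CHT) when < 0; an exact zero
#' resolves to +1 (documented tie rule).
#'
#' @param wm a \linkS4class{WeightMap}.
#' @param x numeric feature vector (or matrix, one row per case).
#' @return numeric vector of +1 / -1 labels.
#' @export
svmClassify <- function(wm, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(wm@w))
    stop(sprintf("feature length %d does not match weight map length %d",
                 ncol(x), length(wm@w)))
  f <- drop(x %*% wm@w) + wm@b
  ifelse(f >= 0, 1, -1)
}

# Exact low-rank factor Z of the linear Gram matrix (Z Z' = X X').  A
# linear-kernel SVM trained on rows of Z has the same dual solution and the
# same decision values on every row as one trained on X, so cross-validated
# predictions are unchanged while each fold trains on an n x n matrix
# instead of n x p.
.gramFactor <- function(X) {
  if (ncol(X) <= nrow(X)) return(X)
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(X))
}

.pairedFolds <- function(labels, nFolds, seed, scheme = c("paired", "random")) {
  scheme <- match.arg(scheme)
  idxP <- which(labels == 1)
  idxN <- which(labels == -1)
  if (length(idxP) < 2L || length(idxN) < 2L)
    stop("need at least 2 subjects per class")
  set.seed(seed)
  if (scheme == "paired") {
    if (length(idxP) != nFolds || length(idxN) != nFolds)
      stop(sprintf(paste0("n_folds = %d incompatible with class sizes ",
                          "%d / %d for the stratified-pair scheme"),
                   nFolds, length(idxP), length(idxN)))
    lapply(seq_len(nFolds), local({
      pP <- sample(idxP); pN <- sample(idxN)
      function(i) c(pP[i], pN[i])
    }))
  } else {
    n <- length(labels)
    lapply(seq_len(nFolds), function(i) sample(n, 2L))
  }
}

#' Leave-pair-out cross-validation of the nu-SVM
#'
#' Each fold holds out one subject per class (a stratified pair), drawn as a
#' seeded random partition, so with 28 subjects and 14 folds every subject
#' is held out exactly once; accuracy is the fraction of correct held-out
#' predictions.  \code{scheme = "random"} instead draws two random subjects
#' per fold (pure resampling, no coverage guarantee).
#'
#' When the feature matrix is wider than it is tall, folds are trained on an
#' exact factor of the linear Gram matrix, which leaves every dual solution
#' and prediction unchanged while avoiding repeated passes over all voxels.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param nu regularization fraction.
#' @param nFolds number of folds (class size for the paired scheme).
#' @param seed RNG seed for the fold draw.
#' @param scheme "paired" (default) or "random".
#' @return A \linkS4class{CVResult}.
#' @export
crossValidate <- function(fm, nu = 0.5, nFolds = length(fm@labels) %/% 2L,
                          seed = 1L, scheme = c("paired", "random")) {
  scheme <- match.arg(scheme)
  folds <- .pairedFolds(fm@labels, nFolds, seed, scheme)
  vals <- .gramFactor(fm@values)
  rows <- lapply(seq_along(folds), function(i) {
    held <- folds[[i]]
    fit <- .svmFit(vals[-held, , drop = FALSE], fm@labels[-held], nu)
    f <- drop(vals[held, , drop = FALSE] %*% fit$w) + fit$b
    data.frame(fold = i, id = held, truth = fm@labels[held],
               prediction = ifelse(f >= 0, 1, -1))
  })
  tab <- do.call(rbind, rows)
  new("CVResult", folds = tab,
      overallAccuracy = mean(tab$prediction == tab$truth))
}

#' Grid search over nu
#'
#' Evaluates each candidate nu by cross-validated accuracy (same seeded
#' folds for every candidate) and returns the maximizer; ties break toward
#' the smaller nu.  Infeasible candidates are skipped (error only when all
#' are infeasible).
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param nuGrid candidate nu values in (0, 1).
#' @param nFolds,seed,scheme as in \code{\link{crossValidate}}.
#' @return list(bestNu, accuracy) plus the per-candidate accuracy table.
#' @export
gridSearchNu <- function(fm, nuGrid = seq(0.1, 0.9, by = 0.1),
                         nFolds = length(fm@labels) %/% 2L, seed = 1L,
                         scheme = c("paired", "random")) {
  if (length(nuGrid) == 0L) stop("nu grid is empty")
  scheme <- match.arg(scheme)
  acc <- vapply(nuGrid, function(nu) {
    tryCatch(cvAccuracy(crossValidate(fm, nu, nFolds, seed, scheme)),
             error = function(e) {
               if (grepl("infeasible", conditionMessage(e))) NA_real_
               else stop(e)
             })
  }, numeric(1))
  if (all(is.na(acc))) stop("every nu in the grid is infeasible")
  ord <- order(-acc, nuGrid, na.last = TRUE)
  best <- ord[1]
  list(bestNu = nuGrid[best], accuracy = acc[best],
       table = data.frame(nu = nuGrid, cv_accuracy = acc))
}

#' Write a weight map as a NIfTI volume
#'
#' Weights are written back through the voxel index; voxels outside the
#' brain mask are zero.
#'
#' @param wm a \linkS4class{WeightMap}.
#' @param file output path (.nii or .nii.gz).
#' @param voxelSizeMm voxel size for the NIfTI header.
#' @return the file path, invisibly.
#' @export
writeWeightMap <- function(wm, file, voxelSizeMm = 2) {
  vol <- array(0, dim = wm@dim)
  lin <- wm@voxelIndex[, 1] + wm@dim[1] * (wm@voxelIndex[, 2] - 1) +
    wm@dim[1] * wm@dim[2] * (wm@voxelIndex[, 3] - 1)
  vol[lin] <- wm@w
  writeVolume(VolumeImage(vol, voxelSize = voxelSizeMm), file)
  invisible(file)
}
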