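# Cut-off classification on network mean metabolism: best single threshold
# per network, and the two-feature "floating cut-off" line in (DAN, PCS)
# space.  Labels follow the package convention +1 = NOCHT, -1 = CHT;
# boundary points always resolve to the no-CHT side.

# Exhaustive 1D threshold search over the n+1 midpoint candidates of the
# sorted values, both orientations.  Ties break toward the widest flanking
# gap, then the lowest threshold, then orientation "below".
.best1D <- function(values, labels) {
  n <- length(values)
  stopifnot(n == length(labels), n >= 1)
  if (length(unique(labels)) == 1L) {
    # degenerate by labels: any extreme threshold classifies perfectly
    ornt <- if (labels[1] == -1) "below" else "above"
    return(list(threshold = max(values) + 1, orientation = ornt,
                accuracy = 1, gap = 0, degenerate = FALSE))
  }
  if (diff(range(values)) == 0) {
    # constant values with mixed labels: no threshold separates anything
    prop <- max(mean(labels == 1), mean(labels == -1))
    # an offset threshold makes the majority call explicit: everything
    # below the threshold is CHT, so place it above (CHT majority) or
    # below (no-CHT majority) the constant value
    chtMajority <- mean(labels == -1) >= mean(labels == 1)
    thr <- if (chtMajority) values[1] + 1 else values[1] - 1
    return(list(threshold = thr, orientation = "below", accuracy = prop,
                gap = 0, degenerate = TRUE))
  }
  s <- sort(values)
  cand <- c(s[1] - 1, (s[-n] + s[-1]) / 2, s[n] + 1)
  gap <- c(0, diff(s), 0)
  best <- NULL
  for (i in seq_along(cand)) {
    t <- cand[i]
    for (ornt in c("below", "above")) {
      pred <- if (ornt == "below") ifelse(values < t, -1, 1)
              else ifelse(values > t, -1, 1)
      acc <- mean(pred == labels)
      key <- c(-acc, -gap[i], t, ornt == "above")
      if (is.null(best) || .lexLess(key, best$key))
        best <- list(threshold = t, orientation = ornt, accuracy = acc,
                     gap = gap[i], degenerate = FALSE, key = key)
    }
  }
  best$key <- NULL
  best
}

.lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Best single-feature cut-off
#'
#' Exhaustive search over the n+1 midpoint thresholds of the sorted values
#' and both orientations, maximizing training accuracy.  Ties break toward
#' the threshold with the widest flanking gap, then the lowest threshold.
#' Constant values with mixed labels return the majority-class accuracy
#' with the model's \code{degenerate} flag set.
#'
#' @param values per-subject scalar (a network mean).
#' @param labels +1 (NOCHT) / -1 (CHT), one per subject.
#' @param feature "pcs" or "dan" (recorded in the model).
#' @return list(model = \linkS4class{CutoffModel}, accuracy).
#' @export
bestSingleCutoff <- function(values, labels, feature = c("pcs", "dan")) {
  feature <- match.arg(feature)
  r <- .best1D(values, labels)
  model <- new("CutoffModel", kind = "single", feature = feature,
               threshold = r$threshold, orientation = r$orientation,
               degenerate = r$degenerate)
  list(model = model, accuracy = r$accuracy)
}

#' Best floating cut-off (line in (DAN, PCS) space)
#'
#' Exhaustive, guaranteed-optimal search over the combinatorially distinct
#' lines in 2D: every candidate slope defined by a pair of subjects (plus
#' the horizontal slope 0 and the vertical direction) is combined with an
#' exact 1D threshold search on the projection pcs - slope * dan.  The
#' family nests all single cut-offs (its axis-aligned members), so the
#' returned training accuracy is >= both single-feature accuracies.  Ties
#' break toward the widest geometric margin, then the smaller |slope|
#' (axis-aligned lines preferred), then the lower threshold.
#'
#' @param dan,pcs per-subject network means.
#' @param labels +1 (NOCHT) / -1 (CHT).
#' @return list(model = \linkS4class{CutoffModel}, accuracy).
#' @export
bestFloatingCutoff <- function(dan, pcs, labels) {
  n <- length(dan)
  stopifnot(n == length(pcs), n == length(labels))
  slopes <- 0
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    dd <- dan[pr[2, ]] - dan[pr[1, ]]
    dp <- pcs[pr[2, ]] - pcs[pr[1, ]]
    ok <- dd != 0
    slopes <- unique(c(0, dp[ok] / dd[ok]))
  }
  best <- NULL
  for (s in slopes) {
    p <- pcs - s * dan
    r <- .best1D(p, labels)
    geomGap <- r$gap / sqrt(1 + s^2)
    key <- c(-r$accuracy, -geomGap, abs(s), r$threshold)
    if (is.null(best) || .lexLess(key, best$key))
      best <- list(kind = "line", slope = s, intercept = r$threshold,
                   vertical = FALSE, orientation = r$orientation,
                   accuracy = r$accuracy, degenerate = r$degenerate, key = key)
  }
  # vertical direction: a cut on DAN alone
  rv <- .best1D(dan, labels)
  keyV <- c(-rv$accuracy, -rv$gap, Inf, rv$threshold)
  if (.lexLess(keyV, best$key))
    best <- list(kind = "line", slope = NA_real_, intercept = NA_real_,
                 vertical = TRUE, threshold = rv$threshold,
                 orientation = rv$orientation, accuracy = rv$accuracy,
                 degenerate = rv$degenerate, key = keyV)
  model <- if (isTRUE(best$vertical)) {
    new("CutoffModel", kind = "line", vertical = TRUE,
        threshold = best$threshold, orientation = best$orientation,
        degenerate = best$degenerate)
  } else {
    new("CutoffModel", kind = "line", slope = best$slope,
        intercept = best$intercept, vertical = FALSE,
        orientation = best$orientation, degenerate = best$degenerate)
  }
  list(model = model, accuracy = best$accuracy)
}

#' Apply a cut-off model
#'
#' Single kind: the named feature is compared to the threshold with the
#' model's orientation.  Line kind: a subject is CHT when its PCS value is
#' on the model's CHT side of intercept + slope * DAN (or its DAN value on
#' the CHT side of a vertical line's threshold).  Boundary points resolve
#' to the no-CHT side.
#'
#' @param model a \linkS4class{CutoffModel}.
#' @param dan,pcs scalar or vector network means.
#' @return numeric labels, +1 (NOCHT) / -1 (CHT).
#' @export
applyCutoff <- function(model, dan, pcs) {
  v <- if (model@kind == "single") {
    if (model@feature == "pcs") pcs else dan
  } else if (model@vertical) {
    dan
  } else {
    pcs - model@slope * dan
  }
  thr <- if (model@kind == "line" && !model@vertical) model@intercept
         else model@threshold
  if (model@orientation == "below") ifelse(v < thr, -1, 1)
  else ifelse(v > thr, -1, 1)
}

#' Leave-pair-out cross-validation of a cut-off model family
#'
#' Same stratified-pair fold scheme as the SVM cross-validation: each fold
#' refits the requested cut-off family on the remaining subjects and
#' predicts the held-out pair.
#'
#' @param dan,pcs per-subject network means.
#' @param labels +1 / -1.
#' @param kind "pcs" or "dan" (single cut-off) or "floating".
#' @param nFolds number of folds (class size).
#' @param seed fold-draw seed.
#' @return A \linkS4class{CVResult}.
#' @export
cutoffCrossValidate <- function(dan, pcs, labels,
                                kind = c("pcs", "dan", "floating"),
                                nFolds = length(labels) %/% 2L, seed = 1L) {
  kind <- match.arg(kind)
  folds <- .pairedFolds(labels, nFolds, seed)
  rows <- lapply(seq_along(folds), function(i) {
    held <- folds[[i]]
    tr <- setdiff(seq_along(labels), held)
    fit <- switch(kind,
      pcs = bestSingleCutoff(pcs[tr], labels[tr], "pcs"),
      dan = bestSingleCutoff(dan[tr], labels[tr], "dan"),
      floating = bestFloatingCutoff(dan[tr], pcs[tr], labels[tr]))
    data.frame(fold = i, id = held, truth = labels[held],
               prediction = applyCutoff(fit$model, dan[held], pcs[held]))
  })
  tab <- do.call(rbind, rows)
  new("CVResult", folds = tab,
      overallAccuracy = mean(tab$prediction == tab$truth))
}

#' Serialize a cut-off model to a JSON-ready list
#'
#' @param model a \linkS4class{CutoffModel}.
#' @param trainingAccuracy,cvAccuracy accuracies to record alongside.
#' @return a named list suitable for \code{jsonlite::write_json}.
#' @export
cutoffModelAsList <- function(model, trainingAccuracy = NA_real_,
                              cvAccuracy = NA_real_) {
  list(kind = model@kind, feature = model@feature,
       threshold = model@threshold, slope = model@slope,
       intercept = model@intercept, vertical = model@vertical,
       orientation = model@orientation, degenerate = model@degenerate,
       training_accuracy = trainingAccuracy, cv_accuracy = cvAccuracy)
}
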