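# Shared fixtures and independent oracles for the test suite.

# compact study conditions for unit tests: same template geometry on a
# coarser 3 mm grid (96 x 114 x 90 mm extent)
smallSpec <- function(seed = 1L, ...) {
  simulationSpec(gridShape = c(32L, 38L, 30L), voxelSizeMm = 3,
                 seed = as.integer(seed), ...)
}

# minimal two-group cohort around explicit volumes
tinyCohort <- function(vols, groups, ages = NULL) {
  n <- length(vols)
  if (is.null(ages)) ages <- rep(50, n)
  ids <- sprintf("T%02d", seq_len(n))
  names(vols) <- ids
  covar <- data.frame(id = ids,
                      group = factor(groups, levels = c("CHT", "NOCHT")),
                      age = ages,
                      gender = factor(rep("M", n), levels = c("M", "F")),
                      depression = rep(4, n),
                      months_post_treatment = ifelse(groups == "CHT", 6, NA),
                      stringsAsFactors = FALSE)
  new("PETCohort", volumes = vols, covariates = covar)
}

# FeatureMatrix around an explicit matrix (for SVM-level tests)
rawFeatureMatrix <- function(X, labels) {
  p <- ncol(X)
  new("FeatureMatrix", values = unname(as.matrix(X)), labels = as.numeric(labels),
      voxelIndex = cbind(seq_len(p), 1L, 1L), dim = c(p, 1L, 1L))
}

# O(n^2) Kendall tau-b oracle: explicit concordant/discordant/tie counts
tauBOracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# exhaustive single-threshold oracle: every candidate, both orientations,
# boundary to no-CHT
singleCutoffOracle <- function(values, labels) {
  s <- sort(values)
  n <- length(s)
  cand <- c(s[1] - 1, (s[-n] + s[-1]) / 2, s[n] + 1)
  best <- 0
  for (t in cand) for (ornt in c("below", "above")) {
    pred <- if (ornt == "below") ifelse(values < t, -1, 1)
            else ifelse(values > t, -1, 1)
    best <- max(best, mean(pred == labels))
  }
  best
}

# dense grid oracle for the floating cut-off: 1000 slopes (uniform in
# angle) x 1000 intercepts spanning each slope's projection range, plus
# vertical cuts on DAN
floatingGridOracle <- function(dan, pcs, labels, nSlope = 1000, nIcpt = 1000) {
  angles <- seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = nSlope)
  best <- 0
  for (s in tan(angles)) {
    p <- pcs - s * dan
    rng <- range(p)
    pad <- max(diff(rng), 1e-8) * 0.01
    thr <- seq(rng[1] - pad, rng[2] + pad, length.out = nIcpt)
    below <- outer(p, thr, `<`)           # n x nIcpt
    accB <- colMeans(ifelse(below, -1, 1) == labels)
    accA <- colMeans(ifelse(!below & outer(p, thr, `>`), -1, 1) == labels)
    best <- max(best, accB, accA)
  }
  rngD <- range(dan)
  padD <- max(diff(rngD), 1e-8) * 0.01
  thrD <- seq(rngD[1] - padD, rngD[2] + padD, length.out = nIcpt)
  belowD <- outer(dan, thrD, `<`)
  best <- max(best,
              colMeans(ifelse(belowD, -1, 1) == labels),
              colMeans(ifelse(outer(dan, thrD, `>`), -1, 1) == labels))
  best
}

# Default-condition cohort analyses used by several property suites; cached
# so the 10-seed loop runs once per test session.
.cohortRunCache <- new.env(parent = emptyenv())

defaultCohortRuns <- function(nSeeds = 10) {
  key <- sprintf("runs_%d", nSeeds)
  if (!is.null(.cohortRunCache[[key]])) return(.cohortRunCache[[key]])
  runs <- lapply(seq_len(nSeeds), function(seed) {
    spec <- simulationSpec(seed = seed)
    sim <- simulateCohort(spec)
    pre <- preprocessCohort(sim$cohort)
    fm <- buildFeatureMatrix(pre, sim$masks@brain)
    wm <- trainNuSvm(fm, 0.5)
    pat <- extractSignedPatterns(wm, 90)
    nm <- cohortNetworkMeans(pre, pat)
    cht <- nm$group == "CHT"
    labels <- ifelse(cht, -1, 1)
    list(
      seed = seed,
      dicePcs = diceCoefficient(pat@positiveMask, sim$masks@pcs),
      diceDan = diceCoefficient(pat@negativeMask, sim$masks@dan),
      pcsP = pValue(twoSampleT(nm$pcs_mean[!cht], nm$pcs_mean[cht])),
      danP = pValue(twoSampleT(nm$dan_mean[!cht], nm$dan_mean[cht])),
      rPcsDan = estimate(pearsonR(nm$pcs_mean, nm$dan_mean)),
      rAgePcs = estimate(pearsonR(nm$age, nm$pcs_mean)),
      rAgeDan = estimate(pearsonR(nm$age, nm$dan_mean)),
      cvSinglePcs = cvAccuracy(cutoffCrossValidate(
        nm$dan_mean, nm$pcs_mean, labels, "pcs", seed = seed + 2000L)),
      cvFloating = cvAccuracy(cutoffCrossValidate(
        nm$dan_mean, nm$pcs_mean, labels, "floating", seed = seed + 2000L)))
  })
  .cohortRunCache[[key]] <- runs
  runs
}
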