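# Feature matrix construction, nu-SVM training, weight-map recovery,
# grid search, leave-pair-out cross-validation.

test_that("feature matrix reads the stated voxels in lexicographic order", {
  dims <- c(3, 3, 3)
  a1 <- array(0, dims); a2 <- array(0, dims)
  # mask voxels (2,1,1), (1,2,1), (1,1,2): lexicographic order on (x,y,z)
  # is (1,1,2), (1,2,1), (2,1,1)
  mask <- array(FALSE, dims)
  mask[2, 1, 1] <- mask[1, 2, 1] <- mask[1, 1, 2] <- TRUE
  a1[2, 1, 1] <- 10; a1[1, 2, 1] <- 20; a1[1, 1, 2] <- 30
  a2[2, 1, 1] <- 40; a2[1, 2, 1] <- 50; a2[1, 1, 2] <- 60
  co <- tinyCohort(list(VolumeImage(a1), VolumeImage(a2)), c("NOCHT", "CHT"))
  fm <- buildFeatureMatrix(co, mask)
  expect_equal(fm@values, rbind(c(30, 20, 10), c(60, 50, 40)))
  expect_equal(fm@labels, c(1, -1))
  expect_equal(fm@voxelIndex[, 1], c(1, 1, 2), ignore_attr = TRUE)
  # determinism
  expect_identical(fm@values, buildFeatureMatrix(co, mask)@values)
})

test_that("feature matrix rejects empty masks and mismatched grids", {
  dims <- c(3, 3, 3)
  co <- tinyCohort(list(VolumeImage(array(1, dims)),
                        VolumeImage(array(1, c(4, 3, 3)))),
                   c("NOCHT", "CHT"))
  expect_error(buildFeatureMatrix(co, array(FALSE, dims)), "empty")
  mask <- array(TRUE, dims)
  expect_error(buildFeatureMatrix(co, mask), "T02")
})

test_that("separable clouds train to accuracy 1 and weights reproduce predict()", {
  set.seed(10)
  X <- rbind(matrix(rnorm(10 * 2, 3), 10), matrix(rnorm(10 * 2, -3), 10))
  fm <- rawFeatureMatrix(X, rep(c(1, -1), each = 10))
  wm <- trainNuSvm(fm, 0.2)
  expect_equal(svmClassify(wm, X), fm@labels)
})

test_that("reconstructed hyperplane reproduces the machine's own decisions", {
  # self-consistency on hard, overlapping data across several nu values
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(24 * 10), 24)
    lab <- rep(c(1, -1), each = 12)
    X[lab == 1, 1] <- X[lab == 1, 1] + 0.5
    fm <- rawFeatureMatrix(X, lab)
    for (nu in c(0.2, 0.5, 0.8)) {
      wm <- trainNuSvm(fm, nu)
      m <- e1071::svm(X, factor(lab, levels = c(-1, 1)),
                      type = "nu-classification", kernel = "linear",
                      nu = nu, scale = FALSE)
      pred <- as.numeric(as.character(predict(m, X)))
      expect_equal(svmClassify(wm, X), pred)
    }
  }
})

test_that("degenerate SVM inputs raise distinguishable errors", {
  X <- matrix(rnorm(20), 10)
  expect_error(trainNuSvm(rawFeatureMatrix(X, rep(1, 10)), 0.5),
               "single class")
  # unbalanced classes make large nu infeasible (nu <= 2 min(n+, n-) / n)
  lab <- c(rep(1, 2), rep(-1, 8))
  expect_error(trainNuSvm(rawFeatureMatrix(X, lab), 0.9), "infeasible")
})

test_that("classification rule: sign of w.x + b with ties to +1", {
  wm <- new("WeightMap", w = c(1, 0), b = 0, voxelIndex = cbind(1:2, 1L, 1L),
            dim = c(2L, 1L, 1L), nu = 0.5)
  expect_equal(svmClassify(wm, c(2, 5)), 1)
  wm@b <- -3
  expect_equal(svmClassify(wm, c(2, 5)), -1)
  wm@b <- -2
  expect_equal(svmClassify(wm, c(2, 5)), 1)  # on the hyperplane -> +1
  expect_error(svmClassify(wm, c(1, 2, 3)), "length")
})

test_that("paired folds hold out every subject exactly once", {
  set.seed(20)
  X <- matrix(rnorm(28 * 12), 28)
  lab <- rep(c(1, -1), 14)
  cv <- crossValidate(rawFeatureMatrix(X, lab), 0.5, seed = 9L)
  expect_equal(nrow(cvFolds(cv)), 28)
  expect_equal(sort(cvFolds(cv)$id), 1:28)
  # each fold holds one subject per class
  byFold <- split(cvFolds(cv)$truth, cvFolds(cv)$fold)
  expect_true(all(vapply(byFold, function(tr) sort(tr), numeric(2))[1, ] == -1))
  # incompatible fold count
  expect_error(crossValidate(rawFeatureMatrix(X, lab), 0.5, nFolds = 10L),
               "incompatible")
})

test_that("cross-validation on the Gram factor equals direct training", {
  set.seed(21)
  X <- matrix(rnorm(16 * 400), 16)  # wide: factor path engages
  lab <- rep(c(1, -1), each = 8)
  X[lab == 1, 1:40] <- X[lab == 1, 1:40] + 0.4
  fm <- rawFeatureMatrix(X, lab)
  cv <- crossValidate(fm, 0.5, seed = 3L)
  folds <- petmvpa:::.pairedFolds(lab, 8L, 3L)
  direct <- unlist(lapply(folds, function(held) {
    fit <- petmvpa:::.svmFit(X[-held, , drop = FALSE], lab[-held], 0.5)
    ifelse(drop(X[held, , drop = FALSE] %*% fit$w) + fit$b >= 0, 1, -1)
  }))
  expect_equal(cvFolds(cv)$prediction, direct)
})

test_that("CV accuracy is invariant to a common positive feature rescaling", {
  set.seed(22)
  X <- matrix(rnorm(20 * 30), 20)
  lab <- rep(c(1, -1), each = 10)
  X[lab == 1, 1:5] <- X[lab == 1, 1:5] + 1
  accs <- vapply(c(0.25, 1, 40), function(cc)
    cvAccuracy(crossValidate(rawFeatureMatrix(X * cc, lab), 0.5, seed = 4L)),
    numeric(1))
  expect_true(all(accs == accs[1]))
})

test_that("permutation-null CV accuracy centers on chance", {
  set.seed(23)
  X <- matrix(rnorm(28 * 30), 28)  # no signal at all
  accs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    lab <- sample(rep(c(1, -1), 14))
    cvAccuracy(crossValidate(rawFeatureMatrix(X, lab), 0.5, seed = s))
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("grid search: singleton grid, determinism, separable optimum", {
  set.seed(24)
  X <- rbind(matrix(rnorm(8 * 3, 2.5), 8), matrix(rnorm(8 * 3, -2.5), 8))
  fm <- rawFeatureMatrix(X, rep(c(1, -1), each = 8))
  g1 <- gridSearchNu(fm, nuGrid = 0.3, seed = 2L)
  expect_equal(g1$bestNu, 0.3)
  g2 <- gridSearchNu(fm, seq(0.1, 0.9, 0.1), seed = 2L)
  g3 <- gridSearchNu(fm, seq(0.1, 0.9, 0.1), seed = 2L)
  expect_identical(g2, g3)
  expect_equal(g2$accuracy, 1)  # some nu separates the toy clouds perfectly
  # ties break toward the smaller nu
  tied <- g2$table$nu[g2$table$cv_accuracy == g2$accuracy]
  expect_equal(g2$bestNu, min(tied))
})

test_that("discriminating cohorts beat the permutation null", {
  # planted effect well above noise: CV accuracy must exceed the null's
  # 95th percentile (the null is computed on the same features with
  # permuted labels)
  sim <- simulateCohort(smallSpec(seed = 31L))
  pre <- preprocessCohort(sim$cohort)
  fm <- buildFeatureMatrix(pre, sim$masks@brain)
  obs <- cvAccuracy(crossValidate(fm, 0.5, seed = 31L))
  nullAcc <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    fmP <- fm
    fmP@labels <- sample(fm@labels)
    cvAccuracy(crossValidate(fmP, 0.5, seed = s))
  }, numeric(1))
  expect_gt(obs, quantile(nullAcc, 0.95))
})
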