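test_that("class weights follow the balanced inverse-frequency rule", {
  expect_equal(unname(classWeights(c(10, 10, 10, 10))), rep(1, 4))
  # printed training composition of an imbalanced 1,462-core set
  counts <- c(242, 526, 314, 380)
  w <- classWeights(counts)
  expect_equal(unname(w), sum(counts) / (4 * counts), tolerance = 1e-12)
  expect_equal(sum(w * counts), sum(counts))          # sum w_c n_c = M
  expect_equal(classWeights(2 * counts), w)           # scale invariance
  expect_error(classWeights(c(0, 5, 5, 5)), "class 0 has zero")
})

test_that("weighted cross-entropy matches hand arithmetic and closed forms", {
  # uniform prediction: log 4
  expect_equal(weightedCrossEntropy(rep(0.25, 4), "2+"), log(4),
               tolerance = 1e-12)
  # two-sample hand example
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  L <- weightedCrossEntropy(probs, c("0", "2+"), weights = c(2, 1, 1, 1))
  expect_equal(L, -(2 * log(0.7) + 1 * log(0.25)) / 2, tolerance = 1e-12)
  # perfect one-hot predictions
  eye <- diag(4)
  expect_equal(weightedCrossEntropy(eye, c("0", "1+", "2+", "3+"),
                                    c(3, 1, 2, 1)), 0)
  # independent oracle on 100 random draws
  set.seed(77)
  for (i in 1:100) {
    m <- sample(1:6, 1)
    p <- randomProbs(m)
    lab <- sample(0:3, m, replace = TRUE)
    w <- stats::runif(4, 0.2, 3)
    ref <- 0
    for (r in 1:m) ref <- ref - w[lab[r] + 1] * log(p[r, lab[r] + 1])
    expect_equal(weightedCrossEntropy(p, lab, w), ref / m,
                 tolerance = 1e-10)
  }
  # unit weights equal the unweighted mean NLL
  p <- randomProbs(5); lab <- c(0, 1, 2, 3, 1)
  expect_equal(weightedCrossEntropy(p, lab),
               -mean(log(p[cbind(1:5, lab + 1)])), tolerance = 1e-12)
})

test_that("degenerate probabilities are clamped with a warning", {
  p <- rbind(c(1, 0, 0, 0))
  expect_warning(L <- weightedCrossEntropy(p, "3+"), "clamped")
  expect_true(is.finite(L))
})

test_that("dihedral transforms form a group and preserve histograms", {
  set.seed(5)
  patch <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  for (k in 0:7) {
    tp <- dihedralTransform(patch, k)
    expect_equal(sort(as.vector(tp)), sort(as.vector(patch)))
    # brute-force inverse exists within the group
    inv <- NA
    for (j in 0:7)
      if (identical(dihedralTransform(tp, j), patch)) { inv <- j; break }
    expect_false(is.na(inv))
  }
  expect_error(dihedralTransform(array(0, c(4, 6, 3)), 1), "square")
})

test_that("augmentation draws are uniform over the 8 transforms", {
  patch <- array(0.5, c(4, 4, 3))
  set.seed(123)
  ks <- replicate(8000, attr(augmentPatch(patch), "transform"))
  tab <- table(factor(ks, levels = 0:7))
  expect_true(all(tab >= 850 & tab <= 1150))
})

test_that("backprop gradients match finite differences", {
  set.seed(31)
  model <- smallConvNet(6, patchSize = 16, channels = c(4, 4, 4, 4),
                        seed = 2)
  X <- array(stats::runif(16 * 16 * 6 * 3), c(16, 16, 6, 3))
  Y <- diag(4)[c(1, 3, 4), ]
  w <- c(1.5, 1, 0.8, 1.2)
  lossOf <- function(m) {
    fw <- pyramidHER2:::.bbForward(m, X, train = TRUE)
    weightedCrossEntropy(fw$probs, Y, w)
  }
  fw <- pyramidHER2:::.bbForward(model, X, train = TRUE)
  wTrue <- as.vector(Y %*% w)
  dZ <- (fw$probs - Y) * wTrue / 3
  grads <- pyramidHER2:::.bbBackward(model, fw$cache, dZ)
  eps <- 1e-5
  for (nm in c("W1", "W3", "g2", "be4", "fcW", "fcb")) {
    th <- model@params[[nm]]
    for (ii in sample(seq_along(th), 3)) {
      mp <- model; mp@params[[nm]][ii] <- th[ii] + eps
      mm <- model; mm@params[[nm]][ii] <- th[ii] - eps
      num <- (lossOf(mp) - lossOf(mm)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-3)
    }
  }
})

test_that("forward pass returns a deterministic probability simplex", {
  core <- tinyCore(seed = 14)
  cfg <- tinyConfig()
  model <- smallConvNet(stackedDepth(cfg), 32, seed = 3)
  x <- stackChannels(samplePss(core, cfg, seed = 5))
  p1 <- predictProbs(model, x)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predictProbs(model, x))
  # shape mismatch names the expected geometry
  bad <- array(0.1, c(32, 32, 15))
  expect_error(predictProbs(model, bad), "does not match the model")
})

test_that("a tiny training run reduces the loss deterministically", {
  ds <- generateDataset(4, coreSpec("0", 128), seed = 19)
  cfg <- tinyConfig()
  tc <- trainConfig(epochs = 5, batchSize = 8, lr = 3e-3)
  fit1 <- trainClassifier(ds$cores, config = cfg, trainCfg = tc,
                          backbone = "small", seed = 9)
  expect_lt(utils::tail(fit1$history$trainLoss, 1),
            fit1$history$trainLoss[1])
  expect_equal(nrow(fit1$history), 5L)
  fit2 <- trainClassifier(ds$cores, config = cfg, trainCfg = tc,
                          backbone = "small", seed = 9)
  expect_identical(fit1$history, fit2$history)
  expect_true(fit1$model@trained)
})

test_that("the backbone is a contract: the gap-linear model drops in", {
  ds <- generateDataset(3, coreSpec("0", 96), seed = 23)
  cfg <- tinyConfig()
  fit <- trainClassifier(ds$cores, config = cfg,
                         trainCfg = trainConfig(epochs = 3, batchSize = 6),
                         backbone = "gap", seed = 2)
  expect_s4_class(fit$model, "GapLinearModel")
  p <- predictProbs(fit$model, samplePss(ds$cores[[1]], cfg, 8))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # downstream protocol runs unchanged on either backbone
  res <- predictCore(fit$model, ds$cores[[2]], cfg, N = 3, k = 2, seed = 5)
  expect_s3_class(res$records, "data.frame")
  expect_equal(nrow(res$records), 3L)
})

test_that("empty splits and bad configs are rejected", {
  ds <- generateDataset(1, coreSpec("0", 96), seed = 2)
  expect_error(trainClassifier(ds$cores, config = tinyConfig(),
                               split = rep("train", 4), seed = 1),
               "non-empty")
  expect_error(trainConfig(batchSize = 0), "batchSize")
  expect_error(trainConfig(lr = -1), "lr")
})

test_that("the DenseNet-201 reference layout is documented as data", {
  sp <- denseNet201Spec(153)
  expect_equal(sp$denseBlocks, c(6L, 12L, 48L, 32L))
  expect_equal(sp$initial$conv, c(7L, 7L, 153L))
  expect_equal(sp$head$classes, 4L)
})
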