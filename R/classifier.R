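## Class-weighted training of a pluggable 4-class backbone on
## channel-stacked PSS inputs.

#' Balanced class weights
#'
#' Weights inversely proportional to class frequency, normalized so that
#' balanced counts give unit weights: \eqn{w_c = M / (C \, n_c)} with
#' \eqn{M = \sum_c n_c} and \eqn{C = 4}.  The identity
#' \eqn{\sum_c w_c n_c = M} holds by construction.
#'
#' @param classCounts integer 4-vector of training-set counts, ordered as
#'   \code{scoreLevels()}.
#' @return Named numeric 4-vector of weights.
#' @examples
#' classWeights(c(10, 10, 10, 10))       # all 1
#' classWeights(c(242, 526, 314, 380))   # imbalanced training set
#' @export
classWeights <- function(classCounts) {
  if (length(classCounts) != 4L)
    stop("classCounts must have length 4")
  if (any(classCounts <= 0)) {
    empty <- .her2Levels[classCounts <= 0][1]
    stop("class ", empty, " has zero (or negative) count; ",
         "weights are undefined for empty classes")
  }
  M <- sum(classCounts)
  stats::setNames(M / (4 * classCounts), .her2Levels)
}

.oneHot <- function(labels, n = 4L) {
  idx <- scoreIndex(labels) + 1L
  Y <- matrix(0, length(idx), n)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Class-weighted cross-entropy loss
#'
#' \deqn{L = -\frac{1}{m} \sum_{i=1}^{m} \sum_{c=1}^{4}
#'   w_c \, y_{i,c} \log p_{i,c}}
#' With unit weights this is the mean negative log-likelihood.  True-class
#' probabilities of 0 are clamped at \code{clampEps} with a warning.
#'
#' @param probs numeric m x 4 matrix (rows sum to 1) or a single 4-vector.
#' @param labels score labels (anything \code{\link{asScoreLabel}} accepts)
#'   or an m x 4 one-hot matrix.
#' @param weights class weight 4-vector (default unit).
#' @param clampEps lower clamp for log arguments.
#' @return Scalar loss.
#' @export
weightedCrossEntropy <- function(probs, labels, weights = rep(1, 4),
                                 clampEps = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != 4L) stop("probs must have 4 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("each probs row must sum to 1")
  Y <- if (is.matrix(labels)) labels else .oneHot(labels)
  if (nrow(Y) != nrow(probs)) stop("labels/probs length mismatch")
  pTrue <- rowSums(probs * Y)
  if (any(pTrue < clampEps)) {
    warning("true-class probability clamped at ", clampEps)
    pTrue <- pmax(pTrue, clampEps)
  }
  wTrue <- as.vector(Y %*% weights)
  -mean(wTrue * log(pTrue))
}

#' Dihedral patch transforms
#'
#' \code{dihedralTransform} applies element \code{k} of the 8-element
#' dihedral group of the square (identity, rotations by 90/180/270 degrees,
#' and the same four after a vertical flip): \code{k \%\% 4} counter-
#' clockwise quarter turns, preceded by a flip when \code{k >= 4}.  All
#' transforms permute pixels, so per-channel histograms are invariant.
#'
#' @param patch square H x H x 3 array.
#' @param k integer 0..7.
#' @return Transformed patch.
#' @export
dihedralTransform <- function(patch, k) {
  .assertRgb(patch, "patch")
  d <- dim(patch)
  if (d[1] != d[2]) stop("patch must be square")
  k <- as.integer(k)
  if (k < 0L || k > 7L) stop("k must be in 0..7")
  if (k >= 4L) patch <- patch[rev(seq_len(d[1])), , , drop = FALSE]
  r <- k %% 4L
  rot1 <- function(p) aperm(p, c(2, 1, 3))[rev(seq_len(d[2])), , ,
                                           drop = FALSE]
  for (i in seq_len(r)) patch <- rot1(patch)
  patch
}

#' @rdname dihedralTransform
#' @details \code{augmentPatch} draws one of the 8 transforms uniformly
#'   from the current RNG stream (the training loop seeds it) and attaches
#'   the chosen index as attribute \code{"transform"}.
#' @export
augmentPatch <- function(patch) {
  k <- sample.int(8L, 1L) - 1L
  out <- dihedralTransform(patch, k)
  attr(out, "transform") <- k
  out
}

#' Training configuration
#'
#' Defaults are the package's desk-scale profile for the small convnet
#' backbone.  The full-scale reference protocol uses the same
#' optimizer family (AdamW, plateau-reduced learning rate, batch size 12)
#' with an initial learning rate of 1e-5 for a DenseNet-201 backbone; see
#' \code{\link{denseNet201Spec}} and the methods vignette.
#'
#' @param epochs maximum epochs.
#' @param batchSize minibatch size (default 12).
#' @param lr initial learning rate.
#' @param weightDecay AdamW decoupled weight decay.
#' @param plateauPatience epochs without validation-loss improvement before
#'   the learning rate is halved.
#' @param lrFactor multiplicative factor on plateau.
#' @param minLr lower bound for the learning rate.
#' @param augment apply dihedral augmentation per patch during training?
#' @param clampEps log clamp in the loss.
#' @return List of class \code{TrainConfig}.
#' @export
trainConfig <- function(epochs = 20L, batchSize = 12L, lr = 1e-3,
                        weightDecay = 1e-4, plateauPatience = 5L,
                        lrFactor = 0.5, minLr = 1e-6, augment = TRUE,
                        clampEps = 1e-12) {
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 weightDecay = weightDecay,
                 plateauPatience = as.integer(plateauPatience),
                 lrFactor = lrFactor, minLr = minLr,
                 augment = isTRUE(augment), clampEps = clampEps),
            class = "TrainConfig")
}

#' Construct an untrained small convnet backbone
#'
#' Four conv(3x3)-BN-ReLU-avgpool(2x2) blocks, global average pooling and a
#' linear softmax head.  The convolutional encoder is shared across the
#' stacked RGB triplets of the PSS input (each patch is encoded with the
#' same weights); the per-patch embeddings are summarized across patches by
#' their mean and their maximum before the head, so a single strongly
#' stained patch can drive the prediction -- the patch-level sensitivity
#' that the inference protocol's confidence selection relies on.
#' \code{patchSize} must be divisible by 16 (four pooling stages) and
#' \code{dIn} by 3 (RGB triplets).
#'
#' @param dIn input channel depth (3 x patch count of the pyramid config).
#' @param patchSize input side length in pixels.
#' @param channels channel widths of the four blocks.
#' @param seed initialization seed (He-normal weights).
#' @return A \linkS4class{ConvNetModel}.
#' @export
smallConvNet <- function(dIn, patchSize = 32L, channels = c(8, 16, 32, 32),
                         seed = 1L) {
  patchSize <- as.integer(patchSize)
  dIn <- as.integer(dIn)
  if (patchSize %% 2L^length(channels) != 0L)
    stop("patchSize must be divisible by ", 2L^length(channels))
  if (dIn %% 3L != 0L)
    stop("dIn must be a multiple of 3 (stacked RGB triplets)")
  withSeed(seed, {
    params <- list()
    cin <- 3L                              # shared per-patch encoder
    running <- list()
    for (b in seq_along(channels)) {
      cout <- as.integer(channels[b])
      params[[paste0("W", b)]] <-
        matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
               9L * cin, cout)
      params[[paste0("g", b)]] <- rep(1, cout)
      params[[paste0("be", b)]] <- rep(0, cout)
      running[[paste0("mu", b)]] <- rep(0, cout)
      running[[paste0("va", b)]] <- rep(1, cout)
      cin <- cout
    }
    params$fcW <- matrix(stats::rnorm(2L * cin * 4L, sd = sqrt(1 / cin)),
                         2L * cin, 4L)
    params$fcb <- rep(0, 4L)
    new("ConvNetModel",
        arch = list(dIn = dIn, patchSize = patchSize,
                    channels = as.integer(channels), nPatch = dIn %/% 3L),
        params = params, running = running)
  })
}

#' Construct an untrained global-average-pool linear backbone
#'
#' @inheritParams smallConvNet
#' @return A \linkS4class{GapLinearModel}.
#' @export
gapLinear <- function(dIn, patchSize = 32L, seed = 1L) {
  withSeed(seed, {
    new("GapLinearModel",
        arch = list(dIn = as.integer(dIn), patchSize = as.integer(patchSize)),
        params = list(W = matrix(stats::rnorm(dIn * 4L, sd = 0.1),
                                 as.integer(dIn), 4L),
                      b = rep(0, 4L)))
  })
}

#' DenseNet-201 reference backbone layout
#'
#' The documented full-scale backbone: an initial 7 x 7 x D_in convolution
#' (batch norm, ReLU, 3 x 3 stride-2 max pool), four dense blocks of
#' 6 / 12 / 48 / 32 densely connected layers with 1 x 1 conv + 2 x 2
#' average-pool transition layers, and a 4-way softmax head.  This function
#' returns the layout as data, for documentation and for export to an
#' external deep-learning runtime; the package's trainable default is
#' \code{\link{smallConvNet}}.
#'
#' @param dIn input channel depth.
#' @return List describing the architecture.
#' @export
denseNet201Spec <- function(dIn = 153L) {
  list(backbone = "DenseNet-201",
       initial = list(conv = c(7L, 7L, as.integer(dIn)),
                      batchNorm = TRUE, activation = "ReLU",
                      maxPool = c(3L, 3L), poolStride = 2L),
       denseBlocks = c(6L, 12L, 48L, 32L),
       transition = list(conv = c(1L, 1L), avgPool = c(2L, 2L)),
       head = list(classes = 4L, activation = "softmax"))
}

.checkInputShape <- function(model, x) {
  a <- model@arch
  d <- dim(x)
  if (length(d) == 3L) d <- c(d, 1L)
  if (d[1] != a$patchSize || d[2] != a$patchSize || d[3] != a$dIn)
    stop(sprintf(
      paste0("input shape %dx%dx%d does not match the model ",
             "(expects %dx%dx%d from pyramid config '%s')"),
      d[1], d[2], d[3], a$patchSize, a$patchSize, a$dIn,
      ifelse(is.na(model@pyramidHash), "<unset>", model@pyramidHash)))
  invisible(TRUE)
}

#' @rdname predictProbs
#' @export
setMethod("predictProbs", signature("HER2Backbone", "array"),
  function(model, x) {
    .checkInputShape(model, x)
    single <- length(dim(x)) == 3L
    if (single) dim(x) <- c(dim(x), 1L)
    probs <- .bbForward(model, x, train = FALSE)$probs
    colnames(probs) <- .her2Levels
    if (single) probs[1, ] else probs
  })

#' @rdname predictProbs
#' @export
setMethod("predictProbs", signature("HER2Backbone", "PyramidSamplingSet"),
  function(model, x) predictProbs(model, stackChannels(x)))

## Assemble a batch array from a list of stacked PSS inputs.
.batchArray <- function(xs) {
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE), c(d, length(xs)))
}

## One fresh (optionally augmented) stacked input for a core.
.stackedInput <- function(core, config, seed, augment = FALSE) {
  pss <- samplePss(core, config, seed)
  pl <- pss@patches
  if (augment)
    pl <- lapply(pl, function(p) dihedralTransform(p, sample.int(8L, 1L) - 1L))
  stackChannels(pl)
}

#' Train a HER2 classifier on pyramid-sampled inputs
#'
#' Trains a backbone with the balanced-class weighted cross-entropy, AdamW,
#' per-patch dihedral augmentation, and a plateau-halved learning rate.  A
#' fresh PSS is sampled for every training core in every epoch (stochastic
#' multi-scale resampling acts as regularization); validation cores use one
#' fixed PSS each so the validation loss is comparable across epochs.  The
#' returned model carries the parameter state of the best validation-loss
#' epoch.
#'
#' @param cores named list of \linkS4class{CoreImage}s, or a manifest
#'   data.frame with columns \code{path} and \code{score} (images are read
#'   from disk).
#' @param labels score labels aligned with \code{cores}; defaults to the
#'   cores' own \code{score} slots.
#' @param config \linkS4class{PyramidConfig} used for sampling.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param backbone \code{"small"} (convnet) or \code{"gap"} (linear).
#' @param split optional character vector of \code{"train"}/\code{"val"}
#'   per core; defaults to a seeded stratified split.
#' @param valFraction validation fraction when \code{split} is NULL.
#' @param seed master seed for initialization, splitting, sampling and
#'   augmentation.
#' @return List with \code{model} (fitted backbone, \code{trained = TRUE})
#'   and \code{history} (data.frame epoch, trainLoss, valLoss, valAcc, lr).
#' @export
trainClassifier <- function(cores, labels = NULL,
                            config = pyramidPreset("default"),
                            trainCfg = trainConfig(),
                            backbone = c("small", "gap"),
                            split = NULL, valFraction = 0.2, seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.data.frame(cores)) {
    man <- cores
    cores <- lapply(seq_len(nrow(man)), function(i)
      readCoreImage(man$path[i], score = man$score[i]))
    names(cores) <- man$core_id %||% vapply(cores, coreId, "")
    if (is.null(labels)) labels <- man$score
    if (is.null(split) && "split" %in% names(man)) split <- man$split
  }
  if (is.null(labels))
    labels <- vapply(cores, function(cc) cc@score, "")
  labels <- asScoreLabel(labels)
  n <- length(cores)
  if (n != length(labels)) stop("cores/labels length mismatch")

  if (is.null(split)) {
    split <- rep("train", n)
    withSeed(deriveSeed(seed, 11L), {
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        nv <- max(1L, round(valFraction * length(idx)))
        split[sample(idx, nv)] <- "val"
      }
    })
  }
  trainIdx <- which(split == "train")
  valIdx <- which(split == "val")
  if (!length(trainIdx) || !length(valIdx))
    stop("both train and val splits must be non-empty")

  counts <- as.integer(table(labels[trainIdx]))
  w <- classWeights(counts)
  dIn <- stackedDepth(config)
  ps <- config@patchSize
  model <- switch(backbone,
                  small = smallConvNet(dIn, ps, seed = deriveSeed(seed, 1L)),
                  gap = gapLinear(dIn, ps, seed = deriveSeed(seed, 1L)))
  model@pyramidHash <- .configHash(config)
  opt <- .adamwInit(model@params)
  lr <- trainCfg$lr

  ## fixed validation inputs (one PSS per val core, reused across epochs)
  valX <- lapply(seq_along(valIdx), function(j)
    .stackedInput(cores[[valIdx[j]]], config, deriveSeed(seed, 424242L, j)))
  valY <- .oneHot(labels[valIdx])

  history <- list()
  best <- list(loss = Inf, params = NULL, running = NULL, epoch = 0L)
  sinceImprove <- 0L

  withSeed(deriveSeed(seed, 555L), {
    for (epoch in seq_len(trainCfg$epochs)) {
      perm <- sample(trainIdx)
      lossSum <- 0; lossN <- 0L
      for (start in seq(1L, length(perm), by = trainCfg$batchSize)) {
        bi <- perm[start:min(start + trainCfg$batchSize - 1L, length(perm))]
        xs <- lapply(bi, function(i)
          .stackedInput(cores[[i]], config, deriveSeed(seed, epoch, i),
                        augment = trainCfg$augment))
        X <- .batchArray(xs)
        Y <- .oneHot(labels[bi])
        fw <- .bbForward(model, X, train = TRUE)
        model <- fw$model
        loss <- weightedCrossEntropy(fw$probs, Y, w, trainCfg$clampEps)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; reduce the learning rate")
        m <- length(bi)
        wTrue <- as.vector(Y %*% w)
        dZ <- (fw$probs - Y) * wTrue / m
        grads <- .bbBackward(model, fw$cache, dZ)
        stepped <- .adamwStep(model@params, grads, opt, lr,
                              trainCfg$weightDecay)
        model@params <- stepped$params
        opt <- stepped$state
        lossSum <- lossSum + loss * m
        lossN <- lossN + m
      }
      trainLoss <- lossSum / lossN

      vp <- .bbForward(model, .batchArray(valX), train = FALSE)$probs
      valLoss <- weightedCrossEntropy(vp, valY, w, trainCfg$clampEps)
      valAcc <- mean(max.col(vp) == max.col(valY))
      history[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                     valLoss = valLoss, valAcc = valAcc,
                                     lr = lr)
      if (valLoss < best$loss - 1e-9) {
        best <- list(loss = valLoss, params = model@params,
                     running = if (is(model, "ConvNetModel")) model@running,
                     epoch = epoch)
        sinceImprove <- 0L
      } else {
        sinceImprove <- sinceImprove + 1L
        if (sinceImprove >= trainCfg$plateauPatience) {
          lr <- max(lr * trainCfg$lrFactor, trainCfg$minLr)
          sinceImprove <- 0L
        }
      }
    }
  })

  if (!is.null(best$params)) {
    model@params <- best$params
    if (is(model, "ConvNetModel")) model@running <- best$running
  }
  model@trained <- TRUE
  list(model = model, history = do.call(rbind, history),
       bestEpoch = best$epoch, classWeights = w)
}
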