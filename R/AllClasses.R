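## Central S4 data containers.

#' CoreImage: one circular tissue core
#'
#' An RGB raster of a single tissue-microarray core plus provenance.  The
#' synthetic generator additionally fills the \code{masks} slot (logical
#' region masks: tissue disk, membrane pixels, heterogeneous sector) and the
#' \code{stainStats} slot (exact per-stain optical density deposited by the
#' renderer), which downstream tests use as ground truth.
#'
#' @slot pixels numeric H x W x 3 array, values in [0, 1] (transmitted
#'   light; 1 = blank background).
#' @slot coreId character identifier.
#' @slot score character HER2 score ("0","1+","2+","3+") or NA when unknown.
#' @slot masks list of logical matrices (possibly empty).
#' @slot stainStats list of renderer bookkeeping values (possibly empty).
#' @exportClass CoreImage
setClass("CoreImage",
  representation(pixels = "array", coreId = "character", score = "character",
                 masks = "list", stainStats = "list"),
  prototype(coreId = "core", score = NA_character_,
            masks = list(), stainStats = list()))

setValidity("CoreImage", function(object) {
  p <- object@pixels
  if (!.isRgbArray(p)) return("pixels must be a numeric H x W x 3 array")
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    return("pixel values must lie in [0, 1]")
  if (length(object@coreId) != 1L) return("coreId must be a single string")
  if (!is.na(object@score) && !(object@score %in% .her2Levels))
    return("score must be one of 0, 1+, 2+, 3+ (or NA)")
  TRUE
})

#' Construct a CoreImage
#'
#' @param pixels numeric H x W x 3 array in [0, 1].
#' @param coreId identifier string.
#' @param score optional HER2 score (anything \code{\link{asScoreLabel}}
#'   accepts).
#' @param masks,stainStats optional generator bookkeeping lists.
#' @return A \linkS4class{CoreImage}.
#' @export
coreImage <- function(pixels, coreId = "core", score = NA, masks = list(),
                      stainStats = list()) {
  sc <- if (length(score) == 1L && is.na(score)) NA_character_
        else as.character(asScoreLabel(score))
  new("CoreImage", pixels = pixels, coreId = as.character(coreId),
      score = sc, masks = masks, stainStats = stainStats)
}

#' PyramidConfig: the multi-scale sampling plan
#'
#' Defines how a Pyramid-Sampling Set is drawn from a core image: the patch
#' side length, an ordered list of resolution levels (integer downsample
#' factor, number of random patches), and whether the whole resized core is
#' appended as a final patch.  The default plan takes 40 patches at full
#' resolution, 10 at 2x downsampling, plus the whole core: 51 patches,
#' stacked channel depth 153.
#'
#' @slot patchSize integer patch side in pixels (default 512).
#' @slot levels data.frame with integer columns \code{factor} (strictly
#'   increasing, >= 1) and \code{nPatches} (>= 0).
#' @slot includeWholeCore logical.
#' @exportClass PyramidConfig
setClass("PyramidConfig",
  representation(patchSize = "integer", levels = "data.frame",
                 includeWholeCore = "logical"))

setValidity("PyramidConfig", function(object) {
  lv <- object@levels
  if (!all(c("factor", "nPatches") %in% names(lv)))
    return("levels needs columns factor and nPatches")
  if (nrow(lv) > 0) {
    if (any(lv$factor < 1L)) return("downsample factors must be >= 1")
    if (any(diff(lv$factor) <= 0))
      return("downsample factors must be strictly increasing")
    if (any(lv$nPatches < 0L)) return("nPatches must be >= 0")
  }
  if (sum(lv$nPatches) + as.integer(object@includeWholeCore) < 1L)
    return("config must yield at least one patch")
  if (object@patchSize < 1L) return("patchSize must be positive")
  TRUE
})

#' Construct a PyramidConfig
#'
#' @param patchSize patch side in pixels.
#' @param levels list of \code{c(factor, nPatches)} pairs, or a data.frame
#'   with those columns.
#' @param includeWholeCore append the whole core resized to
#'   \code{patchSize}?
#' @return A \linkS4class{PyramidConfig}.
#' @examples
#' pyramidConfig()                      # the default 51-patch plan
#' pyramidConfig(256, list(c(1, 4)), FALSE)
#' @export
pyramidConfig <- function(patchSize = 512,
                          levels = list(c(1, 40), c(2, 10)),
                          includeWholeCore = TRUE) {
  if (is.data.frame(levels)) {
    lv <- data.frame(factor = as.integer(levels$factor),
                     nPatches = as.integer(levels$nPatches))
  } else {
    lv <- data.frame(
      factor = vapply(levels, function(x) as.integer(x[1]), 1L),
      nPatches = vapply(levels, function(x) as.integer(x[2]), 1L))
  }
  new("PyramidConfig", patchSize = as.integer(patchSize), levels = lv,
      includeWholeCore = isTRUE(includeWholeCore))
}

#' PyramidSamplingSet: patches drawn from one core
#'
#' The ordered patch collection produced by \code{\link{samplePss}}:
#' level-1 patches in draw order, then deeper levels, then (optionally) the
#' whole resized core last.  Per-patch provenance records the level factor
#' (0 denotes the whole-core patch) and the 0-based top-left corner in the
#' level's coordinate system.
#'
#' @slot coreId character.
#' @slot patches list of patchSize x patchSize x 3 arrays.
#' @slot provenance data.frame(level, row, col), 0-based coordinates.
#' @slot seed integer RNG seed used for the draw.
#' @slot patchSize integer.
#' @exportClass PyramidSamplingSet
setClass("PyramidSamplingSet",
  representation(coreId = "character", patches = "list",
                 provenance = "data.frame", seed = "integer",
                 patchSize = "integer"))

setValidity("PyramidSamplingSet", function(object) {
  if (length(object@patches) != nrow(object@provenance))
    return("provenance rows must match patch count")
  ps <- object@patchSize
  ok <- vapply(object@patches, function(p)
    .isRgbArray(p) && all(dim(p)[1:2] == ps), TRUE)
  if (!all(ok)) return("all patches must be patchSize x patchSize x 3")
  TRUE
})

setClassUnion("OptionalMatrix", c("matrix", "NULL"))

#' Virtual parent of trainable HER2 backbones
#'
#' A backbone maps a channel-stacked PSS array (patchSize x patchSize x
#' D_in) to a softmax probability 4-vector.  Concrete implementations:
#' \linkS4class{ConvNetModel} (the default small convolutional network) and
#' \linkS4class{GapLinearModel} (global-average-pool + multinomial logit,
#' used in interface tests).
#'
#' @exportClass HER2Backbone
setClass("HER2Backbone", representation("VIRTUAL",
  arch = "list", params = "list", classLevels = "character",
  pyramidHash = "character", trained = "logical"),
  prototype(classLevels = c("0", "1+", "2+", "3+"),
            pyramidHash = NA_character_, trained = FALSE))

#' Small convolutional network backbone
#'
#' Four conv(3x3, pad 1) - batch-norm - ReLU - average-pool(2x2) blocks,
#' global average pooling and a linear 4-way softmax head, accepting an
#' arbitrary input channel depth D_in.  Implemented in vectorized base R
#' (im2col + BLAS); \code{running} holds the batch-norm running moments
#' used in eval mode.
#'
#' @exportClass ConvNetModel
setClass("ConvNetModel", contains = "HER2Backbone",
         representation(running = "list"))

#' Global-average-pool linear backbone
#'
#' Per-channel global mean followed by a multinomial logistic (softmax)
#' layer.  Deliberately minimal: it exists to demonstrate that the backbone
#' is a contract, not a fixed architecture.
#'
#' @exportClass GapLinearModel
setClass("GapLinearModel", contains = "HER2Backbone")

#' PredictionPool: cached replicate predictions per core
#'
#' For each core, \code{poolSize} replicate PSS predictions (probability
#' vectors, predicted class, confidence margin) cached so Monte Carlo
#' resampling never re-runs the network.
#'
#' @slot records data.frame with columns coreId, pssSeed, p0..p3, pred,
#'   confidence.
#' @slot labels named character vector: consensus score per coreId.
#' @slot poolSize integer records per core.
#' @exportClass PredictionPool
setClass("PredictionPool",
  representation(records = "data.frame", labels = "character",
                 poolSize = "integer"))

setValidity("PredictionPool", function(object) {
  need <- c("coreId", "pssSeed", "p0", "p1", "p2", "p3", "pred", "confidence")
  if (!all(need %in% names(object@records)))
    return(paste("records needs columns:", paste(need, collapse = ", ")))
  cnt <- table(object@records$coreId)
  if (length(cnt) && any(cnt != object@poolSize))
    return("all cores must share poolSize records")
  if (!all(names(object@labels) %in% unique(object@records$coreId)) ||
      !all(unique(object@records$coreId) %in% names(object@labels)))
    return("labels must cover exactly the pooled cores")
  TRUE
})

#' Construct a PredictionPool from a record table
#'
#' @param records data.frame with columns coreId, pssSeed, p0..p3, pred,
#'   confidence (pred coercible by \code{\link{asScoreLabel}}).
#' @param labels named vector of true scores, names = coreId.
#' @return A \linkS4class{PredictionPool}.
#' @export
predictionPool <- function(records, labels) {
  records$pred <- as.character(asScoreLabel(records$pred))
  labs <- as.character(asScoreLabel(labels))
  names(labs) <- names(labels)
  n <- table(records$coreId)
  new("PredictionPool", records = records, labels = labs,
      poolSize = as.integer(n[[1]]))
}
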