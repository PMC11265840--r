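## Generics and accessors / show methods for the S4 containers.

#' @name accessors
#' @title Accessors for package containers
#' @description Slot accessors: \code{pixels} and \code{coreId} for
#'   \linkS4class{CoreImage} and \linkS4class{PyramidSamplingSet},
#'   \code{nPatches} and \code{stackedDepth} for configs and sampling sets,
#'   \code{patches} and \code{provenance} for sampling sets,
#'   \code{poolRecords}, \code{poolLabels} and \code{poolSize} for
#'   \linkS4class{PredictionPool}.
#' @param x the object.
#' @return The corresponding slot value (or derived count).
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("coreId", function(x) standardGeneric("coreId"))
#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setGeneric("stackedDepth", function(x) standardGeneric("stackedDepth"))
#' @rdname accessors
#' @export
setGeneric("patches", function(x) standardGeneric("patches"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("poolRecords", function(x) standardGeneric("poolRecords"))
#' @rdname accessors
#' @export
setGeneric("poolLabels", function(x) standardGeneric("poolLabels"))
#' @rdname accessors
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))

#' Forward pass of a backbone
#'
#' Computes the softmax class-probability vector(s) for one stacked PSS
#' array (H x W x D_in) or a batch (H x W x D_in x B), in eval mode
#' (deterministic; batch-norm uses running moments).
#'
#' @param model a fitted \linkS4class{HER2Backbone}.
#' @param x stacked input array, or a \linkS4class{PyramidSamplingSet}.
#' @return Probability 4-vector, or B x 4 matrix for a batch.
#' @export
setGeneric("predictProbs", function(model, x) standardGeneric("predictProbs"))

#' @rdname accessors
setMethod("pixels", "CoreImage", function(x) x@pixels)
#' @rdname accessors
setMethod("coreId", "CoreImage", function(x) x@coreId)
#' @rdname accessors
setMethod("coreId", "PyramidSamplingSet", function(x) x@coreId)
#' @rdname accessors
setMethod("nPatches", "PyramidConfig", function(x)
  sum(x@levels$nPatches) + as.integer(x@includeWholeCore))
#' @rdname accessors
setMethod("nPatches", "PyramidSamplingSet", function(x) length(x@patches))
#' @rdname accessors
setMethod("stackedDepth", "PyramidConfig", function(x) 3L * nPatches(x))
#' @rdname accessors
setMethod("stackedDepth", "PyramidSamplingSet", function(x) 3L * nPatches(x))
#' @rdname accessors
setMethod("patches", "PyramidSamplingSet", function(x) x@patches)
#' @rdname accessors
setMethod("provenance", "PyramidSamplingSet", function(x) x@provenance)
#' @rdname accessors
setMethod("poolRecords", "PredictionPool", function(x) x@records)
#' @rdname accessors
setMethod("poolLabels", "PredictionPool", function(x) x@labels)
#' @rdname accessors
setMethod("poolSize", "PredictionPool", function(x) x@poolSize)

setMethod("show", "CoreImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CoreImage '%s': %d x %d px, score %s\n", object@coreId,
              d[1], d[2], ifelse(is.na(object@score), "<NA>", object@score)))
  if (length(object@masks))
    cat("  masks:", paste(names(object@masks), collapse = ", "), "\n")
})

setMethod("show", "PyramidConfig", function(object) {
  lv <- object@levels
  lev <- if (nrow(lv)) paste(sprintf("%dx:%d", lv$factor, lv$nPatches),
                             collapse = " + ") else "none"
  cat(sprintf(
    "PyramidConfig: %d px patches, levels [%s]%s -> %d patches, depth %d\n",
    object@patchSize, lev,
    if (object@includeWholeCore) " + whole core" else "",
    nPatches(object), stackedDepth(object)))
})

setMethod("show", "PyramidSamplingSet", function(object) {
  cat(sprintf("PyramidSamplingSet '%s': %d patches of %d px (seed %d)\n",
              object@coreId, nPatches(object), object@patchSize, object@seed))
})

setMethod("show", "HER2Backbone", function(object) {
  cat(sprintf("%s: D_in = %s, patch %s px, %s\n", class(object),
              object@arch$dIn %||% "?", object@arch$patchSize %||% "?",
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "PredictionPool", function(object) {
  cat(sprintf("PredictionPool: %d cores x %d records\n",
              length(object@labels), object@poolSize))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
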