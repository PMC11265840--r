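## Replicate-PSS inference protocol: confidence margins, k-confident
## selection (KCS) and maximum-score aggregation.

#' Confidence of a prediction
#'
#' The margin between the largest and second-largest class probabilities:
#' 0 for a uniform distribution, approaching 1 for a one-hot prediction.
#' \code{method = "maxprob"} uses the top probability instead (offered for
#' comparison; margin is the default throughout the package).
#'
#' @param probs probability 4-vector, or a matrix with one row per
#'   prediction.
#' @param method \code{"margin"} (default) or \code{"maxprob"}.
#' @return Numeric confidence value(s) in [0, 1].
#' @examples
#' confidenceMargin(c(0.5, 0.3, 0.1, 0.1))   # 0.2
#' @export
confidenceMargin <- function(probs, method = c("margin", "maxprob")) {
  method <- match.arg(method)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probs rows must be probability distributions")
  out <- apply(probs, 1, function(p) {
    s <- sort(p, decreasing = TRUE)
    if (method == "margin") s[1] - s[2] else s[1]
  })
  unname(out)
}

## Normalize a record container (data.frame with p0..p3, pred, confidence,
## pssSeed) coming from predictCore or a PredictionPool subset.
.recordProbs <- function(records)
  as.matrix(records[, c("p0", "p1", "p2", "p3")])

#' Select the k most confident predictions (KCS)
#'
#' Orders records by confidence (descending), breaking ties by lower
#' \code{pssSeed} first for determinism, and keeps the top \code{k}.  When
#' \code{k} exceeds the number of records, all records are returned with a
#' warning.
#'
#' @param records data.frame of prediction records (columns \code{pssSeed},
#'   \code{p0..p3}, \code{pred}, \code{confidence}).
#' @param k number of records to keep (>= 1).
#' @return The selected records, confidences non-increasing.
#' @export
kcsSelect <- function(records, k) {
  if (!nrow(records)) stop("records must be non-empty")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(records)) {
    warning("k = ", k, " exceeds the ", nrow(records),
            " available records; using all of them")
    k <- nrow(records)
  }
  ord <- order(-records$confidence, records$pssSeed)
  records[ord[seq_len(k)], , drop = FALSE]
}

#' Maximum-score aggregation over a KCS
#'
#' The final HER2 score is the maximum predicted class in the selection,
#' under the ordinal order 0 < 1+ < 2+ < 3+.
#'
#' @param kcs records as returned by \code{\link{kcsSelect}} (or any
#'   data.frame with a \code{pred} column), or a vector of score labels.
#' @return A single ordered factor level (the final score).
#' @export
aggregateMax <- function(kcs) {
  preds <- if (is.data.frame(kcs)) kcs$pred else kcs
  lv <- asScoreLabel(preds)
  if (!length(lv)) stop("empty selection")
  asScoreLabel(.her2Levels[max(as.integer(lv))])
}

#' Predict the HER2 score of one core
#'
#' The full inference protocol: \code{N} replicate PSSs are sampled with
#' seeds derived from the master seed, each is classified, the \code{k}
#' most confident predictions form the KCS, and the final score is the
#' maximum score in the KCS.  Defaults N = 20, k = 5.
#'
#' @param model a trained \linkS4class{HER2Backbone}.
#' @param core a \linkS4class{CoreImage} (or RGB array).
#' @param config the \linkS4class{PyramidConfig} the model was trained
#'   with.
#' @param N replicate PSS count.
#' @param k KCS size (k > N is permitted with a warning).
#' @param seed master seed; replicate i uses \code{deriveSeed(seed, i)}.
#' @param method confidence functional, see \code{\link{confidenceMargin}}.
#' @return List: \code{finalScore} (ordered factor), \code{kcs} and
#'   \code{records} (data.frames).
#' @export
predictCore <- function(model, core, config = pyramidPreset("default"),
                        N = 20L, k = 5L, seed = 1L,
                        method = c("margin", "maxprob")) {
  method <- match.arg(method)
  if (N < 1) stop("N must be >= 1")
  seeds <- vapply(seq_len(N), function(i) deriveSeed(seed, i), 1L)
  probs <- t(vapply(seeds, function(s)
    predictProbs(model, samplePss(core, config, s)), numeric(4)))
  records <- data.frame(
    coreId = if (is(core, "CoreImage")) core@coreId else "core",
    pssSeed = seeds,
    p0 = probs[, 1], p1 = probs[, 2], p2 = probs[, 3], p3 = probs[, 4],
    pred = .her2Levels[max.col(probs, ties.method = "first")],
    confidence = confidenceMargin(probs, method),
    stringsAsFactors = FALSE)
  kcs <- kcsSelect(records, k)
  list(finalScore = aggregateMax(kcs), kcs = kcs, records = records)
}
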