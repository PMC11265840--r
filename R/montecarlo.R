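## Monte Carlo analysis of the inference hyperparameters N and k over a
## cached pool of replicate predictions.

#' Build a prediction pool
#'
#' Runs the classifier on \code{poolSize} replicate PSSs for every core and
#' caches the records, so Monte Carlo resampling never re-runs the network.
#' The full-scale protocol uses 300 replicates per test core; the package's
#' desk-scale profile uses 30.
#'
#' @param model trained backbone.
#' @param cores named list of \linkS4class{CoreImage}s.
#' @param labels true scores aligned with \code{cores} (default: the
#'   cores' own score slots).
#' @param poolSize replicate records per core (>= 1).
#' @param config pyramid configuration.
#' @param seed master seed; core j, replicate i uses
#'   \code{deriveSeed(seed, j, i)}.
#' @param method confidence functional.
#' @return A \linkS4class{PredictionPool}.
#' @export
buildPredictionPool <- function(model, cores, labels = NULL, poolSize = 30L,
                                config = pyramidPreset("default"),
                                seed = 1L, method = c("margin", "maxprob")) {
  method <- match.arg(method)
  if (poolSize < 1) stop("poolSize must be >= 1")
  if (is.null(labels))
    labels <- vapply(cores, function(cc) cc@score, "")
  ids <- names(cores) %||% vapply(cores, coreId, "")
  names(labels) <- ids
  recs <- vector("list", length(cores))
  for (j in seq_along(cores)) {
    seeds <- vapply(seq_len(poolSize), function(i) deriveSeed(seed, j, i), 1L)
    probs <- t(vapply(seeds, function(s)
      predictProbs(model, samplePss(cores[[j]], config, s)), numeric(4)))
    recs[[j]] <- data.frame(
      coreId = ids[j], pssSeed = seeds,
      p0 = probs[, 1], p1 = probs[, 2], p2 = probs[, 3], p3 = probs[, 4],
      pred = .her2Levels[max.col(probs, ties.method = "first")],
      confidence = confidenceMargin(probs, method),
      stringsAsFactors = FALSE)
  }
  predictionPool(do.call(rbind, recs), labels)
}

## Internal: per-core list of (confidence-orderable) records for fast
## resampling: predIdx (integer score index 0..3), order key.
.poolByCore <- function(pool) {
  recs <- poolRecords(pool)
  split(data.frame(predIdx = scoreIndex(recs$pred),
                   confidence = recs$confidence,
                   pssSeed = recs$pssSeed),
        recs$coreId)
}

## Final score (integer 0..3) of one drawn subset under kcs + max.
.subsetFinal <- function(df, rows, k) {
  conf <- df$confidence[rows]
  seeds <- df$pssSeed[rows]
  ord <- order(-conf, seeds)
  max(df$predIdx[rows][ord[seq_len(min(k, length(rows)))]])
}

#' Simulate the accuracy distribution at one (N, k)
#'
#' Each replicate draws, for every core independently, \code{N} records
#' uniformly *without replacement* from that core's pool, applies
#' k-confident selection and maximum-score aggregation, and scores overall
#' accuracy against the true labels.
#'
#' @param pool a \linkS4class{PredictionPool}.
#' @param N records drawn per core (<= poolSize).
#' @param k KCS size.
#' @param reps number of Monte Carlo replicates (the full-scale protocol
#'   uses 10,000).
#' @param seed RNG seed.
#' @param returnPreds also return the per-rep predicted classes (used to
#'   materialize confusion matrices)?
#' @return Numeric vector of \code{reps} accuracies; with
#'   \code{returnPreds}, a list(accuracy, preds matrix reps x cores).
#' @export
simulateAccuracy <- function(pool, N, k, reps = 1000L, seed = 1L,
                             returnPreds = FALSE) {
  if (N > poolSize(pool))
    stop("N = ", N, " exceeds poolSize = ", poolSize(pool))
  if (N < 1 || k < 1) stop("N and k must be >= 1")
  if (reps < 1) stop("reps must be >= 1")
  byCore <- .poolByCore(pool)
  ids <- names(byCore)
  truth <- scoreIndex(poolLabels(pool)[ids])
  ps <- poolSize(pool)
  nC <- length(ids)
  withSeed(seed, {
    preds <- matrix(0L, reps, nC)
    for (r in seq_len(reps)) {
      for (j in seq_len(nC)) {
        rows <- if (N == ps) seq_len(ps) else sample.int(ps, N)
        preds[r, j] <- .subsetFinal(byCore[[j]], rows, k)
      }
    }
    acc <- rowMeans(preds == matrix(truth, reps, nC, byrow = TRUE))
    if (returnPreds) list(accuracy = acc, preds = preds, truth = truth,
                          coreIds = ids)
    else acc
  })
}

#' Sweep the (N, k) grid
#'
#' Runs \code{\link{simulateAccuracy}} over a grid and summarizes each cell
#' (min, 25\%, median, 75\%, max).  For the designated cell the replicates
#' achieving the minimum, median and maximum accuracy are re-materialized
#' into 4 x 4 confusion matrices.
#'
#' @param pool a \linkS4class{PredictionPool}.
#' @param NGrid,kGrid integer grids (max(NGrid) <= poolSize).
#' @param reps replicates per cell.
#' @param seed master seed (each cell derives its own stream).
#' @param designated \code{c(N, k)} cell for confusion matrices; default
#'   N = 20, k = 5 clipped to the grid/pool.
#' @return List: \code{summary} (data.frame N, k, min, q25, median, q75,
#'   max), \code{samples} (named list of accuracy vectors), and
#'   \code{confusion} (list min/median/max of 4 x 4 matrices, or NULL when
#'   the designated cell is off-grid).
#' @export
sweepAccuracy <- function(pool, NGrid, kGrid, reps = 1000L, seed = 1L,
                          designated = c(N = 20L, k = 5L)) {
  if (!length(NGrid) || !length(kGrid)) stop("grids must be non-empty")
  if (max(NGrid) > poolSize(pool))
    stop("max(NGrid) exceeds poolSize")
  rows <- list(); samples <- list(); confusion <- NULL
  cell <- 0L
  for (N in NGrid) for (k in kGrid) {
    cell <- cell + 1L
    want <- N == designated[["N"]] && k == designated[["k"]]
    res <- simulateAccuracy(pool, N, k, reps, deriveSeed(seed, N, k),
                            returnPreds = want)
    acc <- if (want) res$accuracy else res
    q <- stats::quantile(acc, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    rows[[cell]] <- data.frame(N = N, k = k, min = q[1], q25 = q[2],
                               median = q[3], q75 = q[4], max = q[5])
    samples[[paste0("N", N, "_k", k)]] <- acc
    if (want) {
      pick <- c(min = which.min(acc),
                median = which.min(abs(acc - stats::median(acc))),
                max = which.max(acc))
      confusion <- lapply(pick, function(r)
        confusionMatrixHer2(.her2Levels[res$truth + 1L],
                            .her2Levels[res$preds[r, ] + 1L]))
    }
  }
  list(summary = do.call(rbind, rows), samples = samples,
       confusion = confusion)
}
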