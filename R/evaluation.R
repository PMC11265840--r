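## Evaluation battery: confusion matrix, overall accuracy, per-class
## specificity, adjacent-pair accuracy, averaged confident probabilities
## and grouped ROC/AUC.

#' 4 x 4 HER2 confusion matrix
#'
#' Rows are true classes, columns predicted classes, both ordered
#' 0, 1+, 2+, 3+.
#'
#' @param true,pred score label vectors of equal length.
#' @return Integer 4 x 4 matrix with dimnames true/predicted.
#' @export
confusionMatrixHer2 <- function(true, pred) {
  true <- asScoreLabel(true); pred <- asScoreLabel(pred)
  if (length(true) != length(pred)) stop("true/pred length mismatch")
  cm <- table(true = true, predicted = pred)
  m <- matrix(as.integer(cm), 4, 4,
              dimnames = list(true = .her2Levels, predicted = .her2Levels))
  m
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm 4 x 4 confusion matrix.
#' @return trace / total.
#' @export
overallAccuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Per-class specificity
#'
#' \eqn{Specificity_i = TN_i / (TN_i + FP_i)} with \eqn{TN_i} the
#' instances correctly identified as not belonging to class \eqn{i} and
#' \eqn{FP_i} those incorrectly assigned to it.  A class whose denominator
#' is zero (every sample truly belongs to it) yields \code{NA} with a
#' warning rather than a silent 0.
#'
#' @param cm 4 x 4 confusion matrix (rows true, cols predicted).
#' @return Named numeric 4-vector.
#' @export
perClassSpecificity <- function(cm) {
  total <- sum(cm)
  out <- numeric(4)
  for (i in 1:4) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    tn <- total - sum(cm[i, ]) - sum(cm[, i]) + tp
    out[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  if (anyNA(out))
    warning("specificity undefined for class(es) with no true negatives: ",
            paste(.her2Levels[is.na(out)], collapse = ", "))
  stats::setNames(out, .her2Levels)
}

#' Accuracy on an adjacent pair of classes
#'
#' Restricted to cores whose true label is in the pair; a prediction is
#' correct iff it equals the true label, so predictions outside the pair
#' count as errors.  An empty subset yields \code{NA} with a warning.
#'
#' @param true,pred score label vectors.
#' @param pair length-2 vector of adjacent classes, e.g. \code{c("0","1+")}.
#' @return Fraction correct on the pair subset.
#' @export
adjacentPairAccuracy <- function(true, pred, pair) {
  true <- asScoreLabel(true); pred <- asScoreLabel(pred)
  pair <- asScoreLabel(pair)
  if (length(pair) != 2L || abs(diff(as.integer(pair))) != 1L)
    stop("pair must be two adjacent classes")
  sel <- true %in% pair
  if (!any(sel)) {
    warning("no cores with true label in pair ",
            paste(as.character(pair), collapse = "/"))
    return(NA_real_)
  }
  mean(pred[sel] == true[sel])
}

#' Average the k most confident probability vectors
#'
#' Reuses \code{\link{kcsSelect}} and returns the arithmetic mean of the
#' selected probability vectors, renormalized to sum to one (a numerical
#' no-op for exact simplex points).  Used as the per-core score for the
#' grouped ROC analyses (full-scale protocol: N = 20, k = 5).
#'
#' @param records prediction records for one core.
#' @param k number of most confident records to average.
#' @return Named probability 4-vector.
#' @export
averagedConfidentProbs <- function(records, k) {
  if (!nrow(records)) stop("records must be non-empty")
  sel <- kcsSelect(records, k)
  p <- colMeans(.recordProbs(sel))
  stats::setNames(p / sum(p), .her2Levels)
}

.rocGroupings <- list(
  "0vRest" = c(FALSE, TRUE, TRUE, TRUE),
  "01v23"  = c(FALSE, FALSE, TRUE, TRUE),
  "012v3"  = c(FALSE, FALSE, FALSE, TRUE))

#' Grouped ROC curve and AUC
#'
#' One of the three binary HER2 groupings: 0 vs {1+,2+,3+}
#' (\code{"0vRest"}), {0,1+} vs {2+,3+} (\code{"01v23"}), or {0,1+,2+} vs
#' 3+ (\code{"012v3"}).  The positive-group score of a core is the sum of
#' its (averaged) class probabilities over the positive classes; the curve
#' is a threshold sweep over the unique scores and the AUC the trapezoidal
#' area, which equals the Mann-Whitney U statistic divided by
#' \eqn{n_+ n_-} (midrank tie handling).
#'
#' @param true score label vector.
#' @param probs matrix of per-core probability 4-vectors (rows), e.g. from
#'   \code{\link{averagedConfidentProbs}}.
#' @param grouping one of \code{"0vRest"}, \code{"01v23"}, \code{"012v3"}.
#' @return List: \code{points} (data.frame fpr, tpr, ordered, endpoints
#'   (0,0) and (1,1)), \code{auc}, \code{grouping}.
#' @export
groupedRocAuc <- function(true, probs, grouping = c("0vRest", "01v23",
                                                    "012v3")) {
  grouping <- match.arg(grouping)
  pos <- .rocGroupings[[grouping]]
  true <- asScoreLabel(true)
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 4)
  if (nrow(probs) != length(true)) stop("true/probs length mismatch")
  y <- pos[as.integer(true)]
  if (!any(y) || all(y)) {
    warning("one-class input: AUC undefined for grouping ", grouping)
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_, grouping = grouping))
  }
  score <- rowSums(probs[, pos, drop = FALSE])
  thr <- sort(unique(score), decreasing = TRUE)
  nP <- sum(y); nN <- sum(!y)
  tpr <- c(0, vapply(thr, function(t) sum(score >= t & y) / nP, 1))
  fpr <- c(0, vapply(thr, function(t) sum(score >= t & !y) / nN, 1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       grouping = grouping)
}

#' Full evaluation summary
#'
#' Convenience wrapper computing the whole battery from predicted and true
#' labels (plus, optionally, per-core records for the probability-based
#' ROC analyses).
#'
#' @param true,pred score label vectors.
#' @param recordsByCore optional named list of per-core prediction record
#'   data.frames (for ROC/AUC via averaged top-k probabilities).
#' @param k KCS size used for probability averaging.
#' @return List: confusion matrix, accuracy, specificity, pair accuracies,
#'   and (when records are given) the three grouped AUCs.
#' @export
evaluationSummary <- function(true, pred, recordsByCore = NULL, k = 5L) {
  cm <- confusionMatrixHer2(true, pred)
  pairs <- list(c("0", "1+"), c("1+", "2+"), c("2+", "3+"))
  pairAcc <- vapply(pairs, function(p)
    adjacentPairAccuracy(true, pred, p), numeric(1))
  names(pairAcc) <- vapply(pairs, paste, "", collapse = "_vs_")
  out <- list(confusion = cm, accuracy = overallAccuracy(cm),
              specificity = perClassSpecificity(cm),
              pairAccuracy = pairAcc)
  if (!is.null(recordsByCore)) {
    probs <- t(vapply(recordsByCore, averagedConfidentProbs, numeric(4),
                      k = k))
    out$auc <- vapply(names(.rocGroupings), function(g)
      groupedRocAuc(true, probs, g)$auc, numeric(1))
  }
  out
}
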