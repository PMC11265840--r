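test_that("confusion matrices match a brute-force tally", {
  t1 <- c("0", "1+", "2+", "3+")
  cm <- confusionMatrixHer2(t1, t1)
  expect_equal(diag(cm), stats::setNames(rep(1L, 4), scoreLevels()))
  expect_equal(overallAccuracy(cm), 1)
  cm2 <- confusionMatrixHer2("2+", "3+")
  expect_equal(cm2["2+", "3+"], 1L)
  expect_equal(overallAccuracy(cm2), 0)
  set.seed(12)
  tr <- sample(scoreLevels(), 200, TRUE)
  pr <- sample(scoreLevels(), 200, TRUE)
  cm3 <- confusionMatrixHer2(tr, pr)
  for (i in 1:4) for (j in 1:4) {
    n <- 0
    for (s in 1:200)
      if (tr[s] == scoreLevels()[i] && pr[s] == scoreLevels()[j]) n <- n + 1
    expect_equal(unname(cm3[i, j]), n)
  }
  expect_error(confusionMatrixHer2(t1, t1[1:2]), "mismatch")
})

test_that("per-class specificity matches one-vs-rest binarization", {
  perfect <- confusionMatrixHer2(rep(scoreLevels(), 5), rep(scoreLevels(), 5))
  expect_equal(unname(perClassSpecificity(perfect)), rep(1, 4))
  # everything predicted class 0 on balanced truth
  allZero <- confusionMatrixHer2(rep(scoreLevels(), each = 3),
                                 rep("0", 12))
  expect_equal(unname(perClassSpecificity(allZero)), c(0, 1, 1, 1))
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    tr <- sample(scoreLevels(), n, TRUE)
    pr <- sample(scoreLevels(), n, TRUE)
    cm <- confusionMatrixHer2(tr, pr)
    sp <- suppressWarnings(perClassSpecificity(cm))
    for (i in 1:4) {
      cls <- scoreLevels()[i]
      tn <- sum(tr != cls & pr != cls)
      fp <- sum(tr != cls & pr == cls)
      # marginals identity
      tp <- sum(tr == cls & pr == cls)
      fn <- sum(tr == cls & pr != cls)
      expect_equal(tn + fp + fn + tp, n)
      if (tn + fp > 0) expect_equal(unname(sp[i]), tn / (tn + fp))
      else expect_true(is.na(sp[i]))
    }
  }
})

test_that("adjacent-pair accuracy counts out-of-pair predictions as errors", {
  tr <- rep(c("0", "1+"), each = 5)
  expect_equal(adjacentPairAccuracy(tr, tr, c("0", "1+")), 1)
  expect_equal(adjacentPairAccuracy(rep("1+", 4), rep("2+", 4),
                                    c("1+", "2+")), 0)
  # mixed subset with one out-of-pair prediction
  tr2 <- c("1+", "1+", "2+", "2+", "2+", "0", "3+", "1+", "2+", "1+")
  pr2 <- c("1+", "2+", "2+", "3+", "2+", "0", "3+", "1+", "2+", "1+")
  sel <- tr2 %in% c("1+", "2+")
  manual <- mean(pr2[sel] == tr2[sel])       # "3+" counts as an error
  expect_equal(adjacentPairAccuracy(tr2, pr2, c("1+", "2+")), manual)
  expect_error(adjacentPairAccuracy(tr2, pr2, c("0", "2+")), "adjacent")
  expect_warning(na <- adjacentPairAccuracy(rep("0", 3), rep("0", 3),
                                            c("2+", "3+")), "no cores")
  expect_true(is.na(na))
  # the three pairs cover every core once or twice
  counts <- rowSums(cbind(tr2 %in% c("0", "1+"), tr2 %in% c("1+", "2+"),
                          tr2 %in% c("2+", "3+")))
  expect_true(all(counts >= 1 & counts <= 2))
})

test_that("averaged confident probabilities reuse the KCS ordering", {
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1),   # conf 0.6
                 c(0.4, 0.3, 0.2, 0.1),   # conf 0.1
                 c(0.1, 0.8, 0.05, 0.05)) # conf 0.7
  recs <- makeRecords(probs, pssSeed = 1:3)
  expect_equal(unname(averagedConfidentProbs(recs, 1)), probs[3, ])
  top2 <- averagedConfidentProbs(recs, 2)
  expect_equal(unname(top2), colMeans(probs[c(3, 1), ]))
  expect_equal(sum(top2), 1, tolerance = 1e-9)
  same <- makeRecords(rbind(probs[1, ], probs[1, ]), pssSeed = 1:2)
  expect_equal(unname(averagedConfidentProbs(same, 2)), probs[1, ])
})

test_that("grouped AUC equals the Mann-Whitney statistic and pROC agrees", {
  # perfectly separated scores
  tr <- c(rep("0", 5), rep("3+", 5))
  probs <- matrix(0, 10, 4)
  probs[1:5, 1] <- 0.9; probs[1:5, 2] <- 0.1
  probs[6:10, 4] <- 0.9; probs[6:10, 3] <- 0.1
  expect_equal(groupedRocAuc(tr, probs, "0vRest")$auc, 1)
  # identical scores: chance
  flat <- matrix(0.25, 10, 4)
  expect_equal(groupedRocAuc(tr, flat, "0vRest")$auc, 0.5)
  # rank-based oracle with midrank ties, 100 random draws
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(10:30, 1)
    tr <- sample(scoreLevels(), n, TRUE)
    if (length(unique(tr)) < 2) next
    # discrete probabilities force score ties
    probs <- randomProbs(n)
    probs <- round(probs * 8) / 8
    probs <- probs / rowSums(probs)
    g <- sample(c("0vRest", "01v23", "012v3"), 1)
    pos <- switch(g, "0vRest" = c(FALSE, TRUE, TRUE, TRUE),
                  "01v23" = c(FALSE, FALSE, TRUE, TRUE),
                  "012v3" = c(FALSE, FALSE, FALSE, TRUE))
    y <- pos[as.integer(asScoreLabel(tr))]
    if (!any(y) || all(y)) next
    score <- rowSums(probs[, pos, drop = FALSE])
    r <- rank(score)                        # midranks
    U <- sum(r[y]) - sum(y) * (sum(y) + 1) / 2
    expect_equal(groupedRocAuc(tr, probs, g)$auc,
                 U / (sum(y) * sum(!y)), tolerance = 1e-12)
  }
  # independent library cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(9)
    tr <- sample(scoreLevels(), 40, TRUE)
    probs <- randomProbs(40)
    ours <- groupedRocAuc(tr, probs, "01v23")$auc
    y <- as.integer(asScoreLabel(tr)) >= 3
    ref <- as.numeric(pROC::auc(pROC::roc(y, rowSums(probs[, 3:4]),
                                          quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone with fixed endpoints; one-class flagged", {
  set.seed(4)
  tr <- sample(c("0", "3+"), 20, TRUE)
  roc <- groupedRocAuc(tr, randomProbs(20), "0vRest")
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(utils::tail(roc$points$fpr, 1), 1)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_warning(und <- groupedRocAuc(rep("0", 5), randomProbs(5), "0vRest"),
                 "one-class")
  expect_true(is.na(und$auc))
})

test_that("the evaluation summary bundles the battery coherently", {
  set.seed(10)
  tr <- sample(scoreLevels(), 30, TRUE)
  pr <- sample(scoreLevels(), 30, TRUE)
  recs <- lapply(1:30, function(i) makeRecords(randomProbs(6)))
  ev <- suppressWarnings(evaluationSummary(tr, pr, recs, k = 3))
  expect_equal(sum(ev$confusion), 30)
  expect_equal(ev$accuracy, mean(tr == pr))
  expect_length(ev$auc, 3L)
  expect_length(ev$pairAccuracy, 3L)
})
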