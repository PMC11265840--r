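# Independent re-implementation of the voting rule, used as the
# enumeration oracle: written naively and separately from the package code.
oracleConsensus <- function(scores, adj = NULL) {
  nd <- scores == "ND"
  if (sum(nd) > length(scores) / 2) return("EX:nondiagnostic")
  rated <- scores[!nd]
  if (!length(rated)) return("EX:nondiagnostic")
  counts <- sapply(c("0", "1+", "2+", "3+"), function(s) sum(rated == s))
  mx <- max(counts)
  winners <- names(counts)[counts == mx]
  if (mx >= 2 && length(winners) == 1) return(winners)
  cand <- if (mx >= 2) winners else unique(rated)
  if (!is.null(adj) && adj %in% cand) return(adj)
  "EX:discordant"
}

resultOf <- function(res) {
  if (res$excluded) paste0("EX:", res$reason) else as.character(res$label)
}

test_that("worked examples of the voting protocol", {
  expect_equal(resultOf(consensusScore(c("3+", "3+", "3+", "2+", "3+"))),
               "3+")
  expect_equal(resultOf(consensusScore(c("1+", "2+", "1+", "2+", "0"), "2+")),
               "2+")
  expect_equal(resultOf(consensusScore(c("0", "1+", "2+", "3+", "ND"))),
               "EX:discordant")
  expect_equal(resultOf(consensusScore(c("ND", "ND", "ND", "2+", "2+"))),
               "EX:nondiagnostic")
  # single nondiagnostic flag does not veto a consensus
  expect_equal(resultOf(consensusScore(c("ND", "2+", "2+", "1+", "2+"))),
               "2+")
  # an adjudicator introducing a brand-new score cannot create agreement
  expect_equal(resultOf(consensusScore(c("0", "0", "1+", "1+", "ND"), "3+")),
               "EX:discordant")
  expect_error(consensusScore(c("5+", "2+")), "unknown HER2 score")
})

test_that("consensus agrees with exhaustive enumeration over all 4^5
           vectors and nondiagnostic variants", {
  levelsAll <- c("0", "1+", "2+", "3+")
  grid <- expand.grid(rep(list(levelsAll), 5), stringsAsFactors = FALSE)
  adjOptions <- list(NULL, "0", "2+", "3+")
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ], use.names = FALSE)
    adj <- adjOptions[[(i %% 4) + 1]]
    expect_equal(resultOf(consensusScore(v, adj)), oracleConsensus(v, adj),
                 info = paste(c(v, "|", adj %||% "-"), collapse = " "))
  }
  # nondiagnostic variants: all 5-rater vectors over {0, 3+, ND}
  gridNd <- expand.grid(rep(list(c("0", "3+", "ND")), 5),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gridNd))) {
    v <- unlist(gridNd[i, ], use.names = FALSE)
    adj <- adjOptions[[(i %% 4) + 1]]
    expect_equal(resultOf(consensusScore(v, adj)), oracleConsensus(v, adj),
                 info = paste(c(v, "|", adj %||% "-"), collapse = " "))
  }
})

test_that("consensus is invariant to rater order and to agreeing additions", {
  set.seed(6)
  for (rep in 1:50) {
    v <- sample(c("0", "1+", "2+", "3+", "ND"), 5, TRUE)
    adj <- sample(list(NULL, "1+", "3+"), 1)[[1]]
    base <- resultOf(consensusScore(v, adj))
    expect_equal(resultOf(consensusScore(sample(v), adj)), base)
    # monotone agreement: appending a rater that matches the current
    # consensus never changes it
    if (!startsWith(base, "EX:")) {
      expect_equal(resultOf(consensusScore(c(v, base), adj)), base)
    }
  }
})

test_that("consensusTable resolves a ratings file", {
  ratings <- data.frame(
    core_id = rep(c("c1", "c2"), each = 3),
    rater_id = rep(1:3, 2),
    score = c("2+", "2+", "1+", "0", "1+", "3+"))
  adj <- data.frame(core_id = "c2", score = "1+")
  out <- consensusTable(ratings, adj)
  expect_equal(out$consensus[out$core_id == "c1"], "2+")
  expect_equal(out$consensus[out$core_id == "c2"], "1+")
  expect_error(consensusTable(ratings[c(1, 1), ]), "duplicate")
})

test_that("labels are applied with patient-disjoint splits", {
  man <- data.frame(core_id = sprintf("c%02d", 1:10),
                    patient_id = rep(sprintf("p%d", 1:5), each = 2))
  cons <- data.frame(core_id = man$core_id,
                     consensus = rep(c("1+", "2+"), 5),
                     excluded = c(TRUE, TRUE, rep(FALSE, 8)),
                     reason = "consensus")
  out <- applyLabels(man, cons, c(train = 0.6, val = 0.2, test = 0.2),
                     seed = 4)
  expect_equal(nrow(out), 8L)
  bySplit <- split(out$patient_id, out$split)
  for (a in seq_along(bySplit)) for (b in seq_along(bySplit))
    if (a < b) expect_length(intersect(bySplit[[a]], bySplit[[b]]), 0L)
  expect_error(applyLabels(man[1:2, ], cons[3:4, ]), "no consensus")
  # everything excluded: empty result with a warning
  consAll <- transform(cons, excluded = TRUE)
  expect_warning(empty <- applyLabels(man, consAll), "all cores excluded")
  expect_equal(nrow(empty), 0L)
})

test_that("split fractions are honored up to rounding", {
  man <- data.frame(core_id = sprintf("c%03d", 1:100),
                    patient_id = sprintf("p%03d", 1:100))
  cons <- data.frame(core_id = man$core_id, consensus = "1+",
                     excluded = FALSE, reason = "consensus")
  out <- applyLabels(man, cons, c(train = 0.7, val = 0.1, test = 0.2),
                     seed = 2)
  tab <- table(out$split)
  expect_equal(as.vector(tab[c("train", "val", "test")]),
               c(70L, 10L, 20L), tolerance = 1)
})
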