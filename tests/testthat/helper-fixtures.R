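# Shared fixtures: everything is generated in code at test time.

# Small core for fast unit tests (128 px, default staining).
tinyCore <- function(score = "2+", seed = 1L, diameter = 128L,
                     heterogeneity = 0) {
  generateCore(coreSpec(score, diameter, heterogeneity, seed = seed))
}

# Compact pyramid plan used by most unit tests: 2 full-resolution patches,
# 1 half-resolution patch, plus the whole core (4 patches, depth 12).
tinyConfig <- function(patchSize = 32)
  pyramidConfig(patchSize, list(c(1, 2), c(2, 1)), TRUE)

# Desk-scale study profile shared by the acceptance experiments: a scaled
# analog of the default 51-patch plan (same 4:1 level-1 : level-2 ratio).
studyConfig <- function() pyramidConfig(32, list(c(1, 6), c(2, 2)), TRUE)

# Hand-built prediction records table.
makeRecords <- function(probs, pssSeed = seq_len(nrow(probs)),
                        coreId = "c1") {
  data.frame(coreId = coreId, pssSeed = pssSeed,
             p0 = probs[, 1], p1 = probs[, 2],
             p2 = probs[, 3], p3 = probs[, 4],
             pred = scoreLevels()[max.col(probs, ties.method = "first")],
             confidence = confidenceMargin(probs),
             stringsAsFactors = FALSE)
}

# Random probability 4-vectors (rows on the simplex).
randomProbs <- function(n, alpha = 1) {
  g <- matrix(stats::rgamma(4 * n, alpha), n, 4)
  g / rowSums(g)
}
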