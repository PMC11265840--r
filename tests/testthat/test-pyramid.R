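test_that("preset patch counts and stacked depths are conserved", {
  expect_equal(nPatches(pyramidPreset("default")), 51L)
  expect_equal(stackedDepth(pyramidPreset("default")), 153L)
  expect_equal(nPatches(pyramidPreset("a")), 1L)
  expect_equal(nPatches(pyramidPreset("b")), 27L)
  expect_equal(nPatches(pyramidPreset("c")), 29L)
  # count/depth identity for arbitrary configs
  for (cfg in list(tinyConfig(), pyramidConfig(64, list(c(1, 3)), FALSE),
                   pyramidConfig(32, list(c(1, 0), c(3, 5)), TRUE))) {
    core <- tinyCore(seed = 2)
    pss <- samplePss(core, cfg, seed = 4)
    expect_equal(nPatches(pss),
                 sum(cfg@levels$nPatches) + cfg@includeWholeCore)
    expect_equal(dim(stackChannels(pss))[3], 3L * nPatches(pss))
  }
})

test_that("invalid pyramid configs are rejected", {
  expect_error(pyramidConfig(64, list(c(2, 4), c(2, 1))), "increasing")
  expect_error(pyramidConfig(64, list(c(1, 0)), FALSE), "at least one")
})

test_that("a core exactly one patch wide yields identical level-1 patches", {
  core <- generateCore(coreSpec("2+", 64, seed = 3))
  cfg <- pyramidConfig(64, list(c(1, 3)), FALSE)
  pss <- samplePss(core, cfg, seed = 5)
  expect_true(all(provenance(pss)$row == 0 & provenance(pss)$col == 0))
  expect_identical(patches(pss)[[1]], patches(pss)[[2]])
  expect_equal(patches(pss)[[1]], pixels(core), tolerance = 1e-12)
})

test_that("sampling is deterministic in the seed", {
  core <- tinyCore(seed = 6)
  a <- samplePss(core, tinyConfig(), seed = 10)
  b <- samplePss(core, tinyConfig(), seed = 10)
  expect_identical(provenance(a), provenance(b))
  expect_identical(patches(a), patches(b))
  d <- samplePss(core, tinyConfig(), seed = 11)
  expect_false(identical(provenance(a), provenance(d)))
})

test_that("stack/unstack is an exact round trip and ordering is patch-major", {
  core <- tinyCore(seed = 8)
  pss <- samplePss(core, tinyConfig(), seed = 2)
  x <- stackChannels(pss)
  back <- unstackChannels(x)
  for (i in seq_along(back))
    expect_identical(back[[i]][, , ], patches(pss)[[i]][, , ])
  # single patch: stacking is the identity up to axis layout
  one <- samplePss(core, pyramidConfig(32, list(c(1, 1)), FALSE), seed = 2)
  expect_identical(stackChannels(one)[, , 1:3], patches(one)[[1]][, , 1:3])
})

test_that("every patch rectangle lies inside its (padded) level image", {
  set.seed(41)
  core <- tinyCore(seed = 12, diameter = 96)
  for (rep in 1:20) {
    cfg <- pyramidConfig(32,
                         list(c(1, sample(0:4, 1)), c(2, sample(1:3, 1))),
                         sample(c(TRUE, FALSE), 1))
    if (sum(cfg@levels$nPatches) + cfg@includeWholeCore < 1) next
    pss <- samplePss(core, cfg, seed = rep)
    pr <- provenance(pss)
    for (j in seq_len(nrow(pr))) {
      if (pr$level[j] == 0) next               # whole-core pseudo level
      d <- dim(pixels(core))[1:2] %/% pr$level[j]
      lim <- pmax(d, 32)                       # padded to patch size
      expect_gte(pr$row[j], 0)
      expect_gte(pr$col[j], 0)
      expect_lte(pr$row[j] + 32, lim[1])
      expect_lte(pr$col[j] + 32, lim[2])
    }
  }
})

test_that("level-1 sector hit rate converges to its uniform-sampling
           expectation", {
  core <- generateCore(coreSpec("3+", 192, heterogeneity = 0.25, seed = 21))
  sector <- core@masks$sector
  ps <- 32L
  # prefix sums for O(1) any-sector-pixel-in-rectangle queries
  cs <- apply(apply(sector, 2, cumsum), 1, cumsum)  # transposed prefix
  rectHasSector <- function(r, c) {                 # 0-based top-left
    r2 <- r + ps; c2 <- c + ps
    tot <- cs[c2, r2] - (if (r > 0) cs[c2, r] else 0) -
      (if (c > 0) cs[c, r2] else 0) +
      (if (r > 0 && c > 0) cs[c, r] else 0)
    tot > 0
  }
  nPos <- 192L - ps + 1L
  # analytic expectation under uniform draws, by exhaustive position scan
  hits <- outer(0:(nPos - 1), 0:(nPos - 1), Vectorize(rectHasSector))
  pTrue <- mean(hits)
  # Monte Carlo oracle (1e5 uniform draws)
  set.seed(9)
  mc <- mean(hits[cbind(sample.int(nPos, 1e5, TRUE),
                        sample.int(nPos, 1e5, TRUE))])
  expect_lt(abs(mc - pTrue), 0.01)
  # the sampler's empirical hit rate over many seeds
  cfg <- pyramidConfig(ps, list(c(1, 8)), FALSE)
  emp <- mean(vapply(1:150, function(s) {
    pr <- provenance(samplePss(core, cfg, seed = s))
    mean(mapply(rectHasSector, pr$row, pr$col))
  }, numeric(1)))
  expect_lt(abs(emp - pTrue), 3 * sqrt(pTrue * (1 - pTrue) / 1200))
})
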