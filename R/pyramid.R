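## Pyramid-Sampling Set construction: multi-scale random patch extraction
## and channel stacking.

#' Named pyramid sampling presets
#'
#' The default plan plus the three reduced configurations used for
#' ablation comparisons: (a) a single full-resolution patch; (b) 20
#' full-resolution + 6 half-resolution patches + the whole core; (c) as (b)
#' plus 2 quarter-resolution patches.
#'
#' @param name one of \code{"default"}, \code{"a"}, \code{"b"}, \code{"c"}.
#' @param patchSize patch side in pixels.
#' @return A \linkS4class{PyramidConfig}.
#' @examples
#' nPatches(pyramidPreset("b"))   # 27
#' @export
pyramidPreset <- function(name = c("default", "a", "b", "c"),
                          patchSize = 512) {
  name <- match.arg(name)
  switch(name,
    default = pyramidConfig(patchSize, list(c(1, 40), c(2, 10)), TRUE),
    a = pyramidConfig(patchSize, list(c(1, 1)), FALSE),
    b = pyramidConfig(patchSize, list(c(1, 20), c(2, 6)), TRUE),
    c = pyramidConfig(patchSize, list(c(1, 20), c(2, 6), c(4, 2)), TRUE))
}

#' All ablation presets
#'
#' @param patchSize patch side in pixels.
#' @return Named list of \linkS4class{PyramidConfig}s
#'   (\code{a}, \code{b}, \code{c}, \code{default}).
#' @export
ablationConfigs <- function(patchSize = 512) {
  stats::setNames(lapply(c("a", "b", "c", "default"), pyramidPreset,
                         patchSize = patchSize),
                  c("a", "b", "c", "default"))
}

## Canonical string identifying a config; embedded in trained models so a
## D_in mismatch can be reported against the config that built the model.
.configHash <- function(config) {
  lv <- config@levels
  paste0("ps", config@patchSize, ";",
         paste(sprintf("%d:%d", lv$factor, lv$nPatches), collapse = ","),
         ";whole=", as.integer(config@includeWholeCore))
}

#' Sample a Pyramid-Sampling Set from a core image
#'
#' For each configured level the core is downsampled by the level's integer
#' factor (block averaging); \code{nPatches} top-left positions are then
#' drawn uniformly at random *with replacement* over all valid positions
#' and square patches extracted.  If requested, the whole core resized
#' (area interpolation) to \code{patchSize} is appended last.  Images
#' smaller than \code{patchSize} at some level are centered and
#' white-padded, never an error.
#'
#' @param core a \linkS4class{CoreImage} or RGB array.
#' @param config a \linkS4class{PyramidConfig}.
#' @param seed integer; the draw is fully determined by (core, config,
#'   seed).
#' @return A \linkS4class{PyramidSamplingSet}.
#' @export
samplePss <- function(core, config = pyramidPreset("default"), seed = 1L) {
  id <- if (is(core, "CoreImage")) core@coreId else "core"
  img <- if (is(core, "CoreImage")) core@pixels else core
  .assertRgb(img, "core")
  ps <- config@patchSize
  patches <- list()
  prov <- list()
  withSeed(seed, {
    for (li in seq_len(nrow(config@levels))) {
      f <- config@levels$factor[li]
      n <- config@levels$nPatches[li]
      if (n == 0L) next
      lvl <- blockDownsample(img, f)
      d <- dim(lvl)
      if (d[1] < ps || d[2] < ps) lvl <- padToSquare(lvl, ps)
      d <- dim(lvl)
      maxR <- d[1] - ps; maxC <- d[2] - ps          # 0-based inclusive max
      r <- sample.int(maxR + 1L, n, replace = TRUE) - 1L
      cc <- sample.int(maxC + 1L, n, replace = TRUE) - 1L
      for (i in seq_len(n)) {
        patches[[length(patches) + 1L]] <-
          lvl[r[i] + seq_len(ps), cc[i] + seq_len(ps), , drop = FALSE]
        prov[[length(prov) + 1L]] <-
          data.frame(level = f, row = r[i], col = cc[i])
      }
    }
    if (config@includeWholeCore) {
      d <- dim(img)
      whole <- if (d[1] < ps && d[2] < ps) padToSquare(img, ps)
               else areaResize(img, ps, ps)
      patches[[length(patches) + 1L]] <- whole
      prov[[length(prov) + 1L]] <- data.frame(level = 0L, row = 0L, col = 0L)
    }
  })
  new("PyramidSamplingSet", coreId = id, patches = patches,
      provenance = do.call(rbind, prov), seed = as.integer(seed),
      patchSize = ps)
}

#' Stack PSS patches along the channel dimension
#'
#' Concatenates the RGB channels of all patches in patch order (RGB
#' triplets contiguous), producing the classifier input of depth
#' \code{3 * nPatches}.  Exactly invertible via
#' \code{\link{unstackChannels}}.
#'
#' @param pss a \linkS4class{PyramidSamplingSet} or list of equal-size RGB
#'   patches.
#' @return Array patchSize x patchSize x (3 * nPatches).
#' @export
stackChannels <- function(pss) {
  pl <- if (is(pss, "PyramidSamplingSet")) pss@patches else pss
  if (!length(pl)) stop("no patches to stack")
  d <- dim(pl[[1]])
  ok <- vapply(pl, function(p) identical(dim(p), d), TRUE)
  if (!all(ok)) stop("internal error: heterogeneous patch sizes")
  array(unlist(pl, use.names = FALSE), c(d[1], d[2], 3L * length(pl)))
}

#' @rdname stackChannels
#' @param x stacked array from \code{stackChannels}.
#' @return \code{unstackChannels}: list of RGB patches, bit-identical to
#'   the originals.
#' @export
unstackChannels <- function(x) {
  d <- dim(x)
  if (d[3] %% 3L != 0L) stop("channel depth is not a multiple of 3")
  lapply(seq_len(d[3] %/% 3L), function(i)
    x[, , 3L * (i - 1L) + 1:3, drop = FALSE])
}
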