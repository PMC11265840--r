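## Shared internal helpers: score labels, seeded evaluation, image resizing.

.her2Levels <- c("0", "1+", "2+", "3+")

#' HER2 score levels
#'
#' The four ordinal HER2 categories used throughout the package, in
#' increasing clinical order \code{0 < 1+ < 2+ < 3+}.
#'
#' @return Character vector \code{c("0","1+","2+","3+")}.
#' @export
scoreLevels <- function() .her2Levels

#' Coerce to an ordered HER2 score factor
#'
#' Accepts characters (\code{"0"}, \code{"1+"}, ..., also bare \code{"1"},
#' \code{"2"}, \code{"3"}), integers 0--3, or factors, and returns an
#' ordered factor on the standard levels.
#'
#' @param x vector of score codes.
#' @return Ordered factor with levels \code{scoreLevels()}.
#' @export
asScoreLabel <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 3 | x != floor(x))))
      stop("numeric HER2 scores must be integers in 0..3")
    x <- ifelse(is.na(x), NA_character_, .her2Levels[x + 1])
  }
  x <- as.character(x)
  bare <- x %in% c("1", "2", "3")
  x[bare] <- paste0(x[bare], "+")
  bad <- !is.na(x) & !(x %in% .her2Levels)
  if (any(bad))
    stop("unknown HER2 score symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = .her2Levels, ordered = TRUE)
}

#' Integer index of a HER2 score
#'
#' @param x anything \code{\link{asScoreLabel}} accepts.
#' @return Integer vector in 0..3.
#' @export
scoreIndex <- function(x) as.integer(asScoreLabel(x)) - 1L

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed with one or more integer stream
#' identifiers, used everywhere the package needs many independent RNG
#' streams (per-core image seeds, per-epoch patch-sampling seeds, replicate
#' PSS seeds).  The result is always in \code{[1, 2^31 - 2]}.
#'
#' @param seed master integer seed.
#' @param ... integer stream identifiers.
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  ids <- as.double(unlist(list(...)))
  x <- as.double(seed) %% 2147483647
  for (i in ids) {
    x <- (x * 69069 + (i + 1) * 104729) %% 2147483647
    x <- (x * 48271) %% 2147483647
  }
  as.integer(x) + 1L
}

## Evaluate expr under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

.isRgbArray <- function(x)
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)

.assertRgb <- function(x, what = "image") {
  if (!.isRgbArray(x))
    stop(what, " must be a numeric H x W x 3 array")
  invisible(x)
}

## Block-average downsampling by an integer factor; short edges are padded
## with `fill` up to the next multiple of the factor before averaging.
blockDownsample <- function(img, factor, fill = 1) {
  .assertRgb(img)
  factor <- as.integer(factor)
  if (factor < 1L) stop("downsample factor must be >= 1")
  if (factor == 1L) return(img)
  d <- dim(img)
  H2 <- ceiling(d[1] / factor); W2 <- ceiling(d[2] / factor)
  if (H2 * factor != d[1] || W2 * factor != d[2]) {
    padded <- array(fill, c(H2 * factor, W2 * factor, 3L))
    padded[seq_len(d[1]), seq_len(d[2]), ] <- img
    img <- padded
  }
  a <- img
  dim(a) <- c(factor, H2, factor * W2 * 3L)
  b <- colMeans(a)                       # (H2, factor, W2, 3) flattened
  dim(b) <- c(H2, factor, W2 * 3L)
  b <- aperm(b, c(2L, 1L, 3L))
  out <- colMeans(b)
  dim(out) <- c(H2, W2, 3L)
  out
}

## 1-D area (box) averaging matrix mapping `n` input cells to `m` output
## cells; rows sum to 1.  Used separably for arbitrary-size area resizing.
.areaWeights <- function(n, m) {
  W <- matrix(0, m, n)
  step <- n / m
  for (i in seq_len(m)) {
    lo <- (i - 1) * step; hi <- i * step
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov / step
    }
  }
  W
}

## Area-interpolated resize of an RGB array to outH x outW.
areaResize <- function(img, outH, outW = outH) {
  .assertRgb(img)
  d <- dim(img)
  if (d[1] == outH && d[2] == outW) return(img)
  L <- .areaWeights(d[1], outH)
  R <- t(.areaWeights(d[2], outW))
  out <- array(0, c(outH, outW, 3L))
  for (ch in 1:3) out[, , ch] <- L %*% img[, , ch] %*% R
  out
}

## Center an image on a square canvas of side `size`, filled with `fill`.
padToSquare <- function(img, size, fill = 1) {
  .assertRgb(img)
  d <- dim(img)
  if (d[1] > size || d[2] > size) stop("image larger than target canvas")
  if (d[1] == size && d[2] == size) return(img)
  out <- array(fill, c(size, size, 3L))
  r0 <- (size - d[1]) %/% 2L
  c0 <- (size - d[2]) %/% 2L
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- img
  out
}

.luminance <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}
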