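## Tissue-core detection in TMA slide mosaics: downsampled circular Hough
## transform with non-maximum suppression, followed by full-resolution
## mask-centroid refinement, and square core cropping.

## Boundary of a logical mask: mask pixels with at least one unset
## 4-neighbor.  Used as the edge map for Hough voting, which makes the
## detector insensitive to stain texture inside the tissue.
.maskBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  mask & !inner
}

## Luminance below this is treated as tissue (blank glass sits near 0.95).
.tissueThreshold <- 0.90

## Integer offsets on a circle of radius r (deduplicated Bresenham-like
## sampling at ~1 px arc steps).
.circleOffsets <- function(r) {
  n <- max(8L, ceiling(2 * pi * r))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  o <- unique(cbind(round(r * sin(th)), round(r * cos(th))))
  o
}

#' Detect circular tissue cores in a slide image
#'
#' Circular Hough transform on a downsampled, edge-detected copy of the
#' slide: every edge pixel votes for candidate centers at each radius in
#' the search range; per-pixel best-radius accumulator peaks are kept by
#' non-maximum suppression, then each detection is refined at full
#' resolution by the centroid and area of the local dark (tissue) mask.
#' The empty or blank image yields an empty result, not an error.
#'
#' @param slide RGB array (or \linkS4class{CoreImage}).
#' @param radiusRange \code{c(min, max)} core radius in full-resolution
#'   pixels (min < max).
#' @param minSeparationPx minimum distance between returned centers.
#' @param downsample integer detection-scale factor, or \code{"auto"}
#'   (largest factor keeping the smallest search radius >= 8 px).
#' @param minScore minimum supported fraction of the circle circumference
#'   for a detection to be kept.
#' @param refine refine center/radius at full resolution?
#' @return data.frame(center_row, center_col, radius, detection_score),
#'   0-based pixel coordinates, sorted by detection_score descending.
#' @export
detectTissueCores <- function(slide, radiusRange, minSeparationPx,
                              downsample = "auto", minScore = 0.25,
                              refine = TRUE) {
  if (is(slide, "CoreImage")) slide <- slide@pixels
  .assertRgb(slide, "slide")
  if (length(radiusRange) != 2L || radiusRange[1] >= radiusRange[2])
    stop("radiusRange must be c(min, max) with min < max")
  empty <- data.frame(center_row = numeric(0), center_col = numeric(0),
                      radius = numeric(0), detection_score = numeric(0))
  f <- if (identical(downsample, "auto"))
    max(1L, min(8L, floor(radiusRange[1] / 8))) else as.integer(downsample)
  small <- blockDownsample(slide, f)
  g <- .luminance(small)
  mask <- g < .tissueThreshold
  if (!any(mask)) return(empty)               # blank glass
  edges <- which(.maskBoundary(mask), arr.ind = TRUE)
  if (!nrow(edges)) return(empty)

  H <- nrow(g); W <- ncol(g)
  radii <- seq(max(3L, floor(radiusRange[1] / f)),
               max(4L, ceiling(radiusRange[2] / f)))
  bestScore <- matrix(0, H, W)
  bestR <- matrix(0L, H, W)
  for (r in radii) {
    off <- .circleOffsets(r)
    acc <- matrix(0L, H, W)
    for (i in seq_len(nrow(off))) {
      rr <- edges[, 1] + off[i, 1]
      cc <- edges[, 2] + off[i, 2]
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      idx <- rr[ok] + (cc[ok] - 1L) * H
      tab <- tabulate(idx, nbins = H * W)
      acc <- acc + tab
    }
    sc <- acc / nrow(off)                    # supported circumference frac.
    upd <- sc > bestScore
    bestScore[upd] <- sc[upd]
    bestR[upd] <- r
  }

  ## greedy non-maximum suppression by minSeparation (at detection scale)
  minSep <- minSeparationPx / f
  ord <- order(bestScore, decreasing = TRUE)
  keep <- list()
  taken <- matrix(FALSE, H, W)
  for (ii in ord) {
    s <- bestScore[ii]
    if (s < minScore) break
    r0 <- (ii - 1L) %% H + 1L
    c0 <- (ii - 1L) %/% H + 1L
    clash <- FALSE
    for (kk in keep)
      if ((kk$r - r0)^2 + (kk$c - c0)^2 < minSep^2) { clash <- TRUE; break }
    if (!clash) keep[[length(keep) + 1L]] <-
        list(r = r0, c = c0, rad = bestR[ii], score = s)
  }
  if (!length(keep)) return(empty)

  out <- do.call(rbind, lapply(keep, function(kk) {
    ## map detection-scale block center back to full resolution (0-based)
    cr <- (kk$r - 0.5) * f - 0.5
    cc <- (kk$c - 0.5) * f - 0.5
    rad <- kk$rad * f
    if (refine) {
      ref <- .refineCircle(slide, cr, cc, rad)
      cr <- ref$row; cc <- ref$col; rad <- ref$radius
    }
    data.frame(center_row = cr, center_col = cc, radius = rad,
               detection_score = kk$score)
  }))
  out[order(-out$detection_score), , drop = FALSE]
}

## Full-resolution refinement: centroid and equivalent-area radius of the
## dark (tissue) mask inside a disk slightly larger than the coarse guess.
.refineCircle <- function(slide, cr, cc, rad) {
  H <- dim(slide)[1]; W <- dim(slide)[2]
  win <- ceiling(rad * 1.15)
  r0 <- max(1L, floor(cr + 1 - win)); r1 <- min(H, ceiling(cr + 1 + win))
  c0 <- max(1L, floor(cc + 1 - win)); c1 <- min(W, ceiling(cc + 1 + win))
  sub <- .luminance(slide[r0:r1, c0:c1, , drop = FALSE])
  dy <- (r0:r1) - (cr + 1); dx <- (c0:c1) - (cc + 1)
  inWin <- outer(dy^2, dx^2, "+") <= win^2
  dark <- sub < .tissueThreshold & inWin
  n <- sum(dark)
  if (n < 10) return(list(row = cr, col = cc, radius = rad))
  rows <- matrix(r0:r1, nrow(sub), ncol(sub))
  cols <- matrix(c0:c1, nrow(sub), ncol(sub), byrow = TRUE)
  list(row = mean(rows[dark]) - 1, col = mean(cols[dark]) - 1,
       radius = sqrt(n / pi))
}

#' Crop a square core image around a detected circle
#'
#' Square crop of side \code{2 * radius * (1 + marginFraction)} centered on
#' the circle; regions falling outside the slide are filled with
#' background white rather than reflected.
#'
#' @param slide RGB array or \linkS4class{CoreImage}.
#' @param circle one row of \code{\link{detectTissueCores}} output (or any
#'   list with center_row, center_col, radius; 0-based).
#' @param marginFraction margin added around the circle.
#' @param fill fill value for out-of-bounds pixels.
#' @param coreId identifier for the returned core.
#' @return A \linkS4class{CoreImage}.
#' @export
cropCore <- function(slide, circle, marginFraction = 0.1, fill = 0.96,
                     coreId = "crop") {
  if (is(slide, "CoreImage")) slide <- slide@pixels
  .assertRgb(slide, "slide")
  side <- as.integer(round(2 * circle$radius * (1 + marginFraction)))
  H <- dim(slide)[1]; W <- dim(slide)[2]
  out <- array(fill, c(side, side, 3L))
  ## 0-based half-open source range centered on the circle
  r0 <- as.integer(round(circle$center_row + 0.5 - side / 2))
  c0 <- as.integer(round(circle$center_col + 0.5 - side / 2))
  srcR <- intersect(seq(r0, r0 + side - 1L), 0:(H - 1L))
  srcC <- intersect(seq(c0, c0 + side - 1L), 0:(W - 1L))
  if (length(srcR) && length(srcC))
    out[srcR - r0 + 1L, srcC - c0 + 1L, ] <-
      slide[srcR + 1L, srcC + 1L, , drop = FALSE]
  coreImage(pmin(pmax(out, 0), 1), coreId = coreId)
}

#' Detect and crop all cores of a slide
#'
#' @inheritParams detectTissueCores
#' @inheritParams cropCore
#' @return List with \code{circles} (detection table with core_id) and
#'   \code{cores} (list of \linkS4class{CoreImage}).
#' @export
extractCores <- function(slide, radiusRange, minSeparationPx,
                         marginFraction = 0.1, ...) {
  circles <- detectTissueCores(slide, radiusRange, minSeparationPx, ...)
  if (!nrow(circles)) return(list(circles = circles, cores = list()))
  circles$core_id <- sprintf("core%02d", seq_len(nrow(circles)))
  cores <- lapply(seq_len(nrow(circles)), function(i)
    cropCore(slide, circles[i, ], marginFraction,
             coreId = circles$core_id[i]))
  names(cores) <- circles$core_id
  list(circles = circles, cores = cores)
}
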