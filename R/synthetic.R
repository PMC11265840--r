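## Synthetic IHC-like core and TMA-slide generator.
##
## Images are composed additively in optical-density (OD) space using the
## standard Ruifrok-Johnston stain vectors and converted to transmitted
## light by Beer-Lambert (pixel = background * exp(-OD)).  Because OD is
## additive, stain unmixing is exact and the mean DAB density of a
## generated core has a closed form, which the test suite exploits.

.stainVectors <- function() {
  m <- cbind(hem = c(0.650, 0.704, 0.286),
             eos = c(0.072, 0.990, 0.105),
             dab = c(0.268, 0.570, 0.776))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Default class-conditional stain parameters
#'
#' Membrane staining follows the ASCO/CAP reading of HER2 scores: both the
#' DAB (brown) optical density of the membrane ring and the fraction of the
#' ring that is stained ("completeness") increase with class, so mean
#' membrane density is strictly monotone in score.  Nuclei are hematoxylin
#' disks; all tissue gets a light eosin/hematoxylin base so cores are
#' visible against the slide background.
#'
#' @return Named list: \code{membraneOD} and \code{completeness} (per-class,
#'   names \code{scoreLevels()}), \code{nucleusOD}, \code{cellRadius} (px),
#'   \code{tissueEosin}, \code{tissueHem}, \code{background} (RGB of blank
#'   slide glass).
#' @export
defaultStainParams <- function() {
  list(
    membraneOD   = stats::setNames(c(0.02, 0.35, 0.65, 1.00), .her2Levels),
    completeness = stats::setNames(c(0.15, 0.40, 0.75, 1.00), .her2Levels),
    nucleusOD    = 0.55,
    cellRadius   = 8,
    tissueEosin  = 0.18,
    tissueHem    = 0.05,
    background   = c(0.96, 0.95, 0.94))
}

#' Specification of one synthetic core
#'
#' @param score HER2 score of the core (majority expression level).
#' @param diameterPx core diameter in pixels (>= 64; default 2048, a
#'   desk-scale stand-in for full-resolution cores of roughly 10,000 px).
#' @param heterogeneity fraction in [0, 1] of the core area rendered with
#'   the staining parameters of the class one level below \code{score}
#'   (clamped at 0).  Realized as one contiguous angular sector, so random
#'   patch sampling can plausibly miss the minority region.
#' @param cellDensity cells per 10^4 px^2.
#' @param stainParams see \code{\link{defaultStainParams}}.
#' @param seed integer; (spec, seed) fully determines the image bytes.
#' @return A list of class \code{CoreSpec}.
#' @export
coreSpec <- function(score, diameterPx = 2048, heterogeneity = 0,
                     cellDensity = 12, stainParams = defaultStainParams(),
                     seed = 1L) {
  score <- as.character(asScoreLabel(score))
  if (length(score) != 1L || is.na(score))
    stop("score must be a single valid HER2 class")
  diameterPx <- as.integer(diameterPx)
  if (is.na(diameterPx) || diameterPx < 64L)
    stop("diameterPx must be an integer >= 64")
  if (heterogeneity < 0 || heterogeneity > 1)
    stop("heterogeneity must lie in [0, 1]")
  structure(list(score = score, diameterPx = diameterPx,
                 heterogeneity = heterogeneity, cellDensity = cellDensity,
                 stainParams = stainParams, seed = as.integer(seed)),
            class = "CoreSpec")
}

## Paint a disk or ring arc into an OD coefficient matrix (in place value
## semantics: returns the modified matrix).  All geometry is computed on a
## local window for speed.
.paintCell <- function(dabMat, hemMat, cy, cx, cellR, nucleusOD,
                       membraneOD, completeness, arcStart) {
  D <- nrow(dabMat)
  r0 <- max(1L, floor(cy - cellR)); r1 <- min(D, ceiling(cy + cellR))
  c0 <- max(1L, floor(cx - cellR)); c1 <- min(D, ceiling(cx + cellR))
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - cy; dx <- cc - cx
  dist <- sqrt(outer(dy^2, dx^2, "+"))
  nuc <- dist <= 0.45 * cellR
  if (any(nuc)) hemMat[rr, cc][nuc] <- hemMat[rr, cc][nuc] + nucleusOD
  if (membraneOD > 0 && completeness > 0) {
    ring <- dist >= 0.72 * cellR & dist <= cellR
    if (completeness < 1) {
      ang <- (atan2(outer(dy, rep(1, length(dx))),
                    outer(rep(1, length(dy)), dx)) - arcStart) %%
        (2 * pi)
      ring <- ring & ang <= completeness * 2 * pi
    }
    if (any(ring))
      dabMat[rr, cc][ring] <- dabMat[rr, cc][ring] + membraneOD
  }
  list(dab = dabMat, hem = hemMat)
}

#' Generate one synthetic IHC core image
#'
#' Renders a circular tissue region containing cell-like objects (disk
#' nuclei, ring membranes) on a light background.  A \code{heterogeneity}
#' area fraction -- one contiguous sector -- is rendered with the staining
#' parameters of class \code{max(score - 1, 0)}.  Identical (spec, seed)
#' yields a bit-identical image.
#'
#' @param spec a \code{\link{coreSpec}}.
#' @param coreId identifier stored in the result.
#' @return A \linkS4class{CoreImage} whose \code{score} slot is the spec
#'   score, with masks (\code{tissue}, \code{membrane}, \code{sector}) and
#'   \code{stainStats} bookkeeping (exact deposited DAB density,
#'   closed-form expected mean DAB, cell count, sector area fraction).
#' @export
generateCore <- function(spec, coreId = sprintf("core_s%d", spec$seed)) {
  stopifnot(inherits(spec, "CoreSpec"))
  sp <- spec$stainParams
  D <- spec$diameterPx
  R <- D / 2
  cellR <- sp$cellRadius
  withSeed(spec$seed, {
    ctr <- (D + 1) / 2
    dy <- seq_len(D) - ctr
    dist2 <- outer(dy^2, dy^2, "+")
    tissue <- dist2 <= R^2
    nPix <- D * D

    hemM <- matrix(0, D, D); eosM <- matrix(0, D, D); dabM <- matrix(0, D, D)
    ## light tissue base with mild multiplicative texture
    tex <- matrix(stats::runif(nPix, 0.85, 1.15), D, D)
    eosM[tissue] <- sp$tissueEosin * tex[tissue]
    hemM[tissue] <- sp$tissueHem * tex[tissue]

    ## heterogeneous sector: contiguous wedge of angle 2*pi*h
    h <- spec$heterogeneity
    theta0 <- stats::runif(1, 0, 2 * pi)
    ang <- (atan2(outer(dy, rep(1, D)), outer(rep(1, D), dy)) - theta0) %%
      (2 * pi)
    sector <- tissue & (ang < h * 2 * pi)

    lowScore <- .her2Levels[max(scoreIndex(spec$score), 1L)]  # max(score-1,0)+1
    hiOD <- sp$membraneOD[[spec$score]]; hiC <- sp$completeness[[spec$score]]
    loOD <- sp$membraneOD[[lowScore]];   loC <- sp$completeness[[lowScore]]

    nCells <- max(1L, round(spec$cellDensity * pi * R^2 / 1e4))
    rad <- (R - cellR - 1) * sqrt(stats::runif(nCells))
    phi <- stats::runif(nCells, 0, 2 * pi)
    cy <- ctr + rad * sin(phi); cx <- ctr + rad * cos(phi)
    arcStart <- stats::runif(nCells, 0, 2 * pi)
    inSector <- ((phi - theta0) %% (2 * pi)) < h * 2 * pi

    for (i in seq_len(nCells)) {
      od <- if (inSector[i]) loOD else hiOD
      cm <- if (inSector[i]) loC else hiC
      res <- .paintCell(dabM, hemM, cy[i], cx[i], cellR, sp$nucleusOD,
                        od, cm, arcStart[i])
      dabM <- res$dab; hemM <- res$hem
    }

    M <- .stainVectors()
    bg <- sp$background
    px <- array(0, c(D, D, 3L))
    for (ch in 1:3)
      px[, , ch] <- bg[ch] *
        exp(-(M[ch, 1] * hemM + M[ch, 2] * eosM + M[ch, 3] * dabM))

    stats <- list(
      dabDeposited = sum(dabM),
      meanDab = sum(dabM) / nPix,
      tissueArea = sum(tissue),
      sectorFraction = if (sum(tissue)) sum(sector) / sum(tissue) else 0,
      nCells = nCells,
      membraneArea = sum(dabM > 0),
      cellRadius = cellR,
      classMembraneOD = hiOD, classCompleteness = hiC,
      background = bg)
    coreImage(px, coreId = coreId, score = spec$score,
              masks = list(tissue = tissue, membrane = dabM > 0,
                           sector = sector),
              stainStats = stats)
  })
}

#' Exact stain unmixing of a generated image
#'
#' Inverts the renderer's Beer-Lambert model: per-pixel optical densities
#' are projected onto the hematoxylin / eosin / DAB vectors (the 3x3 stain
#' matrix is invertible, so for generator output the recovery is exact up
#' to pixel quantization).
#'
#' @param img a \linkS4class{CoreImage} or an RGB array in [0, 1].
#' @param background RGB of blank glass (default the generator's).
#' @return List of matrices \code{hem}, \code{eos}, \code{dab} (OD
#'   coefficients per pixel).
#' @export
stainUnmix <- function(img, background = defaultStainParams()$background) {
  if (is(img, "CoreImage")) img <- img@pixels
  .assertRgb(img)
  d <- dim(img)
  od <- sapply(1:3, function(ch)
    -log(pmax(img[, , ch], 1e-8) / background[ch]))
  a <- od %*% t(solve(.stainVectors()))
  list(hem = matrix(a[, 1], d[1], d[2]),
       eos = matrix(a[, 2], d[1], d[2]),
       dab = matrix(a[, 3], d[1], d[2]))
}

#' Mean membrane (DAB) optical density of a core image
#'
#' Mean of the unmixed DAB coefficient over all pixels; for generator
#' output this equals total deposited membrane density / pixel count,
#' which is strictly monotone in HER2 class under the default parameters.
#'
#' @inheritParams stainUnmix
#' @return A single number.
#' @export
meanMembraneOD <- function(img, background = defaultStainParams()$background) {
  mean(stainUnmix(img, background)$dab)
}

#' Generate a labeled synthetic core dataset
#'
#' \code{nPerClass} cores for each of the four HER2 classes, with per-core
#' seeds derived deterministically from the master seed.  When \code{dir}
#' is given, images are written as PNG and a manifest CSV
#' (\code{core_id, path, score, heterogeneity, seed}) is written alongside.
#'
#' @param nPerClass cores per class (>= 1).
#' @param template a \code{\link{coreSpec}} supplying everything but score
#'   and seed.
#' @param seed master seed.
#' @param dir optional output directory.
#' @return List with \code{cores} (list of \linkS4class{CoreImage}) and
#'   \code{manifest} (data.frame).
#' @export
generateDataset <- function(nPerClass, template = coreSpec("0", 256),
                            seed = 1L, dir = NULL) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  rows <- list(); cores <- list()
  for (ci in seq_along(.her2Levels)) {
    for (i in seq_len(nPerClass)) {
      s <- deriveSeed(seed, ci, i)
      sp <- template
      sp$score <- .her2Levels[ci]
      sp$seed <- s
      id <- sprintf("c%d_%03d", ci - 1L, i)
      core <- generateCore(coreSpec(sp$score, sp$diameterPx,
                                    sp$heterogeneity, sp$cellDensity,
                                    sp$stainParams, s), coreId = id)
      path <- if (is.null(dir)) NA_character_
              else file.path(dir, paste0(id, ".png"))
      if (!is.null(dir)) writeCoreImage(core, path)
      cores[[id]] <- core
      rows[[length(rows) + 1L]] <- data.frame(
        core_id = id, path = path, score = sp$score,
        heterogeneity = sp$heterogeneity, seed = s,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(cores = cores, manifest = manifest)
}

#' Specification of a synthetic TMA slide mosaic
#'
#' @param gridRows,gridCols grid dimensions.
#' @param coreRadiusPx core radius in pixels.
#' @param spacingPx center-to-center spacing; must exceed
#'   \code{2 * coreRadiusPx} or the cores would touch (parameter error).
#' @param coreSpecs optional list of \code{\link{coreSpec}}s, one per grid
#'   cell (row-major); defaults to cycling the four classes.
#' @param drop integer indices (row-major) of grid positions left empty.
#' @param backgroundLevel gray level of blank slide glass.
#' @param seed integer master seed.
#' @return A list of class \code{SlideSpec}.
#' @export
slideSpec <- function(gridRows, gridCols, coreRadiusPx, spacingPx,
                      coreSpecs = NULL, drop = integer(0),
                      backgroundLevel = 0.96, seed = 1L) {
  if (spacingPx <= 2 * coreRadiusPx)
    stop("spacingPx must be > 2 * coreRadiusPx: cores would overlap")
  n <- gridRows * gridCols
  if (is.null(coreSpecs)) {
    coreSpecs <- lapply(seq_len(n), function(i)
      coreSpec(.her2Levels[(i - 1L) %% 4L + 1L],
               diameterPx = 2L * as.integer(coreRadiusPx),
               seed = deriveSeed(seed, 7L, i)))
  }
  if (length(coreSpecs) != n)
    stop("need one coreSpec per grid cell (", n, ")")
  structure(list(gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols),
                 coreRadiusPx = as.integer(coreRadiusPx),
                 spacingPx = as.integer(spacingPx),
                 coreSpecs = coreSpecs, drop = as.integer(drop),
                 backgroundLevel = backgroundLevel,
                 seed = as.integer(seed)),
            class = "SlideSpec")
}

#' Generate a synthetic TMA slide mosaic
#'
#' Renders a grid of synthetic cores on a blank-glass background and
#' returns the image together with the ground-truth circle list in 0-based
#' pixel coordinates.
#'
#' @param spec a \code{\link{slideSpec}}.
#' @return List with \code{image} (H x W x 3 array) and \code{circles}
#'   (data.frame core_id, center_row, center_col, radius, score; 0-based).
#' @export
generateTmaSlide <- function(spec) {
  stopifnot(inherits(spec, "SlideSpec"))
  rad <- spec$coreRadiusPx; sp <- spec$spacingPx
  margin <- as.integer(ceiling(sp / 2))
  H <- 2L * (margin + rad) + (spec$gridRows - 1L) * sp
  W <- 2L * (margin + rad) + (spec$gridCols - 1L) * sp
  img <- withSeed(deriveSeed(spec$seed, 99L), {
    array(spec$backgroundLevel + stats::runif(H * W * 3L, -0.01, 0.01),
          c(H, W, 3L))
  })
  rows <- list()
  idx <- 0L
  for (gr in seq_len(spec$gridRows)) for (gc in seq_len(spec$gridCols)) {
    idx <- idx + 1L
    if (idx %in% spec$drop) next
    cs <- spec$coreSpecs[[idx]]
    cs$diameterPx <- 2L * rad
    core <- generateCore(coreSpec(cs$score, 2L * rad, cs$heterogeneity,
                                  cs$cellDensity, cs$stainParams, cs$seed))
    cy <- margin + rad + (gr - 1L) * sp   # 1-based center ~ cy + 0.5
    cx <- margin + rad + (gc - 1L) * sp
    tis <- core@masks$tissue
    sub <- img[cy - rad + seq_len(2L * rad), cx - rad + seq_len(2L * rad), ,
               drop = FALSE]
    for (ch in 1:3) {
      s <- sub[, , ch]; p <- core@pixels[, , ch]
      s[tis] <- p[tis]
      sub[, , ch] <- s
    }
    img[cy - rad + seq_len(2L * rad), cx - rad + seq_len(2L * rad), ] <- sub
    rows[[length(rows) + 1L]] <- data.frame(
      core_id = sprintf("r%dc%d", gr, gc),
      center_row = cy + 0.5 - 1, center_col = cx + 0.5 - 1,
      radius = rad, score = cs$score, stringsAsFactors = FALSE)
  }
  list(image = img, circles = do.call(rbind, rows))
}
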