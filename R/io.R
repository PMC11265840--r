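## Reading and writing images and manifest tables.

#' Write a core or slide image to disk
#'
#' PNG (8-bit) via the png package; \code{.tif/.tiff} paths use the tiff
#' package when installed.
#'
#' @param img a \linkS4class{CoreImage} or RGB array in [0, 1].
#' @param path output file path; the directory is created if needed.
#' @return \code{path}, invisibly.
#' @export
writeCoreImage <- function(img, path) {
  if (is(img, "CoreImage")) img <- img@pixels
  .assertRgb(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the tiff package")
    tiff::writeTIFF(img, path)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read an image from disk
#'
#' @param path PNG or TIFF file.
#' @param coreId,score stored in the returned object.
#' @return A \linkS4class{CoreImage}.
#' @export
readCoreImage <- function(path, coreId = tools::file_path_sans_ext(basename(path)),
                          score = NA) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  coreImage(img, coreId = coreId, score = score)
}

#' Read / write a manifest table
#'
#' Plain CSV round trip for the manifest tables used across the package
#' (core_id, path, score, ... columns).
#'
#' @param manifest data.frame to write.
#' @param path CSV file.
#' @return \code{readManifest} returns a data.frame.
#' @export
writeManifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)
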