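# Image and table readers/writers. Tabular outputs are CSV with a one-line
# header comment carrying version, seed and config hash; images are TIFF
# (exact 8-bit round trip) or PNG.

#' Read a worm image from TIFF or PNG
#'
#' Pixel values are returned on the container's native integer scale (8-bit
#' images give 0-255). The pixel size always comes from the caller, never
#' from file metadata. 16-bit input is kept on its 0-65535 scale unless
#' \code{rescale_to_8bit} is set, in which case values are divided by 257
#' (mapping 65535 to 255).
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_um microns per pixel.
#' @param mask optional logical body mask; defaults to all-TRUE.
#' @param rescale_to_8bit rescale 16-bit data into 0-255 (default FALSE).
#' @return A \code{\linkS4class{WormImage}}.
#' @export
readWormImage <- function(path, pixel_size_um, mask = NULL,
                          rescale_to_8bit = FALSE) {
  if (!file.exists(path)) stop("readWormImage: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) stop("readWormImage: corrupt or ",
                                             "unreadable TIFF: ", path))
    bps <- attr(img, "bits.per.sample")
    if (is.null(bps)) bps <- 8L
    # multi-channel data comes back normalized to [0, 1] regardless of
    # as.is; restore the native integer scale from the sample depth
    if (max(img) <= 1 && any(img != round(img)))
      img <- round(img * (2^bps - 1))
    img <- array(as.numeric(img), dim = dim(img))
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("readWormImage: corrupt or ",
                                             "unreadable PNG: ", path))
    img <- round(img * 255)
  } else stop("readWormImage: unsupported format '.", ext,
              "' (TIFF or PNG required)")
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3]                      # drop alpha
  if (max(img) > 255 && rescale_to_8bit) img <- img / 257
  if (is.null(mask)) mask <- matrix(TRUE, dim(img)[1L], dim(img)[2L])
  WormImage(img, mask, pixel_size_um)
}

#' Write a worm image (or plain array) to TIFF or PNG
#'
#' 8-bit-scale values are written so that \code{\link{readWormImage}}
#' recovers them exactly (TIFF) or to the nearest 8-bit level (PNG).
#'
#' @param image \code{\linkS4class{WormImage}}, matrix or array on the
#'   \code{[0, 255]} scale.
#' @param path output path (.tif/.tiff/.png).
#' @return The path, invisibly.
#' @export
writeWormImage <- function(image, path) {
  if (is(image, "WormImage")) image <- intensityData(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- clip8(round(image)) / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else stop("writeWormImage: unsupported format '.", ext, "'")
  invisible(path)
}

#' Read a body mask from a PNG/TIFF
#'
#' Nonzero pixels are foreground.
#'
#' @param path file path.
#' @return Logical matrix.
#' @export
readMask <- function(path) {
  img <- intensityData(readWormImage(path, pixel_size_um = 1))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0
}

# One-line header comment for CSV artifacts.
csvHeaderComment <- function(seed, config_hash) {
  sprintf("# plangrad %s seed=%s config=%s",
          as.character(packageVersion("plangrad")),
          as.character(seed), config_hash)
}

#' Write a pipeline CSV with a provenance header comment
#'
#' @param x data.frame.
#' @param path output path.
#' @param seed,config_hash recorded in the header comment.
#' @return The path, invisibly.
#' @export
writePipelineCsv <- function(x, path, seed = NA, config_hash = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csvHeaderComment(seed, config_hash), con)
  write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, skipping provenance comments
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readPipelineCsv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialization; changes iff any parameter
#' changes.
#'
#' @param config configuration list.
#' @return Character hash.
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)
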