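#' Render a synthetic two-channel fluorescence image pair
#'
#' Maps two nonnegative density fields to channel intensities through an
#' affine map, adds symmetric cross-channel bleed-through and Gaussian
#' noise, and clips to `[0, 1]` (the representable range of the 16-bit
#' image the pair is written as). The ground-truth challenger fraction
#' (channel 1) is recorded so that image-based quantification can be
#' validated.
#'
#' @param field1,field2 nonnegative numeric matrices of identical shape
#'   (challenger and partner density fields).
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   dynamic range.
#' @param bleed cross-channel bleed-through fraction in `[0, 1)`.
#' @param seed integer seed for the noise.
#' @param gain peak intensity (fraction of dynamic range) that the maximum
#'   field value is mapped to.
#' @param offset constant background offset added to both channels.
#' @return list of class `synthetic_image_pair`: `$challenger`, `$partner`
#'   (matrices in `[0, 1]`), `$truth$percent_challenger`.
#' @export
render_fluorescence_image <- function(field1, field2, noise_sd = 0,
                                      bleed = 0, seed = 1L, gain = 0.8,
                                      offset = 0.05) {
  if (!all(dim(field1) == dim(field2))) {
    stop("field1 and field2 must have the same shape", call. = FALSE)
  }
  if (min(field1) < 0 || min(field2) < 0) {
    stop("fields must be nonnegative", call. = FALSE)
  }
  if (bleed < 0 || bleed >= 1) stop("bleed must be in [0, 1)", call. = FALSE)
  tot <- sum(field1) + sum(field2)
  if (tot <= 0) stop("both fields are identically zero", call. = FALSE)
  scale <- gain / max(max(field1), max(field2), .Machine$double.eps)
  ch1 <- scale * (field1 + bleed * field2) + offset
  ch2 <- scale * (field2 + bleed * field1) + offset
  if (noise_sd > 0) {
    with_seed(seed, {
      ch1 <- ch1 + matrix(stats::rnorm(length(ch1), sd = noise_sd), nrow(ch1))
      ch2 <- ch2 + matrix(stats::rnorm(length(ch2), sd = noise_sd), nrow(ch2))
    })
  }
  ch1 <- pmin(pmax(ch1, 0), 1)
  ch2 <- pmin(pmax(ch2, 0), 1)
  structure(list(
    challenger = ch1, partner = ch2,
    truth = list(percent_challenger = 100 * sum(field1) / tot),
    noise_sd = noise_sd, bleed = bleed),
    class = "synthetic_image_pair")
}

#' Write an image pair as 16-bit TIFFs
#'
#' @param pair a `synthetic_image_pair` (or list with `$challenger`,
#'   `$partner` matrices in `[0, 1]`).
#' @param dir output directory.
#' @param basename file stem.
#' @return invisibly, paths to the two TIFFs.
#' @export
write_image_pair <- function(pair, dir, basename = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(basename, "_challenger.tiff"))
  p2 <- file.path(dir, paste0(basename, "_partner.tiff"))
  tiff::writeTIFF(pair$challenger, p1, bits.per.sample = 16L)
  tiff::writeTIFF(pair$partner, p2, bits.per.sample = 16L)
  invisible(c(challenger = p1, partner = p2))
}

#' Read a single-channel raster image (TIFF or PNG)
#'
#' @param path image path.
#' @return numeric matrix of intensities in `[0, 1]` (multi-channel images
#'   are reduced to their first channel).
#' @export
read_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
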