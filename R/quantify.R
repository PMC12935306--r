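#' Relative strain densities from two density fields
#'
#' @param B1,B2 nonnegative numeric matrices (or vectors) of strain
#'   densities.
#' @return numeric vector `c(f1, f2)` with `f_i = sum(B_i) / sum(B1 + B2)`.
#' @export
relative_density_from_fields <- function(B1, B2) {
  if (min(B1) < 0 || min(B2) < 0) {
    stop("density fields must be nonnegative", call. = FALSE)
  }
  s1 <- sum(B1); s2 <- sum(B2)
  if (s1 + s2 <= 0) stop("empty biofilm", call. = FALSE)
  c(f1 = s1 / (s1 + s2), f2 = s2 / (s1 + s2))
}

# Rolling-ball-style background estimate: morphological opening with a disc
# structuring element; subtracting it is the white top-hat transform.
subtract_background <- function(ch, radius) {
  if (is.null(radius) || radius <= 0) return(ch)
  side <- 2L * as.integer(radius) + 1L
  if (side >= min(dim(ch))) return(ch - min(ch))
  kern <- EBImage::makeBrush(side, shape = "disc")
  as.matrix(EBImage::whiteTopHat(EBImage::Image(ch), kern))
}

# Otsu threshold computed on the channel's own range, so the selected pixel
# set is invariant under positive rescaling of the intensities.
auto_threshold <- function(ch, method = "otsu") {
  if (is.numeric(method)) return(method)
  rng <- range(ch)
  if (diff(rng) <= .Machine$double.eps) return(rng[1] - 1e-9)
  switch(method,
         otsu = EBImage::otsu(EBImage::Image(ch), range = rng),
         none = 0,
         stop("unknown threshold method: ", method, call. = FALSE))
}

#' Percent challenger remaining from a two-channel fluorescence image
#'
#' Each channel is automatically thresholded (Otsu on its own intensity
#' range); the union of the two above-threshold masks defines the colony
#' footprint. The default background estimate is the per-channel median of
#' the off-colony pixels (`background = "median"`); subtracting it from the
#' colony pixels and integrating gives each strain's signal, so dim
#' minority-strain signal inside the colony still counts towards its
#' channel. A rolling-ball-style alternative (`background = "tophat"`:
#' morphological opening with a disc of `background_radius` pixels,
#' subtracted before thresholding) is available for images with strong
#' illumination gradients. Integrated intensity (not pixel count) is the
#' default signal because relative strain density weights brighter, denser
#' regions; `mode = "pixels"` counts per-channel above-threshold pixels
#' instead.
#'
#' @param challenger,partner intensity matrices (challenger = channel 1),
#'   or file paths readable by [read_channel()].
#' @param background `"median"`, `"tophat"` or `"none"`.
#' @param background_radius disc radius (px) for the `"tophat"` estimate;
#'   it must exceed the colony radius or real signal is subtracted too.
#' @param threshold_method `"otsu"`, `"none"`, or a numeric absolute
#'   threshold applied to both channels.
#' @param mode `"intensity"` or `"pixels"`.
#' @return list of class `density_quant`: `percent_challenger` in
#'   `[0, 100]`, `threshold1`, `threshold2`.
#' @export
quantify_relative_density <- function(challenger, partner,
                                      background = c("median", "tophat",
                                                     "none"),
                                      background_radius = 50,
                                      threshold_method = "otsu",
                                      mode = c("intensity", "pixels")) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  if (is.character(challenger)) challenger <- read_channel(challenger)
  if (is.character(partner)) partner <- read_channel(partner)
  if (!all(dim(challenger) == dim(partner))) {
    stop("channels must have the same shape", call. = FALSE)
  }
  ch1 <- challenger; ch2 <- partner
  if (background == "tophat") {
    ch1 <- subtract_background(ch1, background_radius)
    ch2 <- subtract_background(ch2, background_radius)
  }
  t1 <- auto_threshold(ch1, threshold_method)
  t2 <- auto_threshold(ch2, threshold_method)
  a1 <- ch1 > t1; a2 <- ch2 > t2
  if (!any(a1) && !any(a2)) stop("empty biofilm", call. = FALSE)
  if (mode == "pixels") {
    s1 <- sum(a1); s2 <- sum(a2)
  } else {
    mask <- a1 | a2
    b1 <- b2 <- 0
    if (background == "median" && !all(mask)) {
      b1 <- stats::median(ch1[!mask])
      b2 <- stats::median(ch2[!mask])
    }
    s1 <- sum(pmax(ch1[mask] - b1, 0))
    s2 <- sum(pmax(ch2[mask] - b2, 0))
  }
  if (s1 + s2 <= 0) stop("empty biofilm", call. = FALSE)
  structure(list(percent_challenger = 100 * s1 / (s1 + s2),
                 threshold1 = t1, threshold2 = t2),
            class = "density_quant")
}

#' Biofilm footprint area from a single-channel image
#'
#' Thresholds the image, labels connected components, and returns the area
#' of the largest component (satellite colonies are ignored).
#'
#' @param image intensity matrix or a file path.
#' @param threshold_method `"otsu"` or a numeric absolute threshold.
#' @param pixel_size physical length per pixel (area is
#'   `pixels * pixel_size^2`).
#' @return numeric area; `0` (with a warning) for a blank image.
#' @export
biofilm_footprint <- function(image, threshold_method = "otsu",
                              pixel_size = 1) {
  if (is.character(image)) image <- read_channel(image)
  rng <- range(image)
  if (diff(rng) <= .Machine$double.eps) {
    if (rng[1] <= 0) {
      warning("blank image: footprint area is 0")
      return(0)
    }
    return(length(image) * pixel_size^2)  # uniformly saturated frame
  }
  thr <- auto_threshold(image, threshold_method)
  bw <- EBImage::Image(image > thr)
  if (sum(bw) == 0) {
    warning("no pixel above threshold: footprint area is 0")
    return(0)
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  max(sizes) * pixel_size^2
}
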