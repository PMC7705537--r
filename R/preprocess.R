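#' Extract the static background from sampled frames
#'
#' Whiskers appear dark against the backlight, so the background of a video
#' with a static camera is recovered as the per-pixel maximum (brightest
#' value) over frames sampled from across the video: anything that moves
#' (whiskers, most fur) is replaced by the backlight it occasionally reveals.
#'
#' @param frames list of intensity matrices, identical dimensions, values in
#'   `[0, 1]`; at least 2 frames spread across the video
#' @param sample_indices optional frame indices the samples came from (kept
#'   for provenance)
#' @return object of class `background_model` with fields `pixels` and
#'   `sample_indices`
#' @export
extract_background <- function(frames, sample_indices = seq_along(frames)) {
  if (length(frames) < 2)
    stop("background extraction needs at least 2 sampled frames")
  dm <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), dm)) stop("sampled frames differ in shape")
  structure(list(pixels = Reduce(pmax, frames),
                 sample_indices = as.integer(sample_indices)),
            class = "background_model")
}

#' Subtract the background, inverting polarity
#'
#' `clamp(background - frame, 0, 1)`: whiskers (dark on bright) become bright
#' structures on a near-zero background.
#'
#' @param frame intensity matrix
#' @param bg a `background_model` or an intensity matrix
#' @return intensity matrix, same shape
#' @export
subtract_background <- function(frame, bg) {
  bgp <- if (inherits(bg, "background_model")) bg$pixels else bg
  if (!identical(dim(frame), dim(bgp)))
    stop("frame and background differ in shape")
  pmin(pmax(bgp - frame, 0), 1)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
}

#' Extract the snout/fur silhouette mask
#'
#' On the background-subtracted image, bright content is either whisker shaft
#' (thin) or snout/fur residue (blobby). The image is binarized (Otsu by
#' default) and a morphological opening deletes structures thinner than
#' `open_radius`, leaving the blob; a dilation then pads it so fur at the
#' snout edge is covered.
#'
#' @param image background-subtracted intensity matrix
#' @param threshold binarization threshold in `[0, 1]`; `NULL` = Otsu
#' @param open_radius disc radius (px) of the opening that removes thin
#'   structures (whiskers)
#' @param dilate_radius disc radius (px) of the padding dilation
#' @param max_fraction warn when the mask covers more than this fraction of
#'   the image (suggests a bad threshold)
#' @return logical matrix (`TRUE` = remove); attribute `"threshold"` records
#'   the threshold used
#' @export
extract_silhouette <- function(image, threshold = NULL, open_radius = 2,
                               dilate_radius = 3, max_fraction = 0.5) {
  rng <- range(image)
  if (diff(rng) < 1e-12) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    attr(m, "threshold") <- NA_real_
    return(m)
  }
  if (is.null(threshold))
    threshold <- EBImage::otsu(image, range = c(0, 1))
  bin <- (image > threshold) * 1
  opened <- EBImage::opening(bin, disc_brush(open_radius))
  mask <- EBImage::dilate(opened, disc_brush(dilate_radius)) > 0.5
  if (mean(mask) > max_fraction)
    warning(sprintf("silhouette mask covers %.0f%% of the image; threshold %.3g may be off",
                    100 * mean(mask), threshold))
  mask <- matrix(as.logical(mask), nrow(image), ncol(image))
  attr(mask, "threshold") <- threshold
  mask
}

#' Zero out masked pixels
#'
#' @param image intensity matrix
#' @param mask logical matrix of the same shape (`TRUE` = remove)
#' @return intensity matrix
#' @export
remove_silhouette <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask differ in shape")
  image[mask] <- 0
  image
}

#' Full per-frame preprocessing
#'
#' Background subtraction followed by silhouette removal: turns a raw frame
#' into an image where whiskers are bright curvilinear ridges on a dark,
#' empty background.
#'
#' @param frame raw intensity matrix (whiskers dark on bright backlight; set
#'   `invert = TRUE` for the opposite polarity)
#' @param bg a `background_model`
#' @param mask optional precomputed silhouette mask; `NULL` recomputes per
#'   frame
#' @param invert logical; invert the input polarity first
#' @param ... passed to [extract_silhouette()]
#' @return cleaned intensity matrix
#' @export
preprocess_frame <- function(frame, bg, mask = NULL, invert = FALSE, ...) {
  if (invert) frame <- 1 - frame
  sub <- subtract_background(frame, bg)
  if (is.null(mask)) mask <- extract_silhouette(sub, ...)
  remove_silhouette(sub, mask)
}
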