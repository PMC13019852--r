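#' Frozen per-channel thresholding macro
#'
#' Mirrors the practice of tuning mask sensitivity on one representative image
#' and then applying the saved settings uniformly to every image of the
#' dataset. The threshold for a channel is `threshold_fraction` times a
#' dataset-wide calibration reference intensity (never a per-image maximum,
#' which would silently equalise group differences). `tolerance_px` is the
#' merge radius used when counting nearby supra-threshold objects as one;
#' `min_object_px` rejects speckle below that pixel count.
#'
#' @param threshold_fraction named numeric in (0,1), per channel.
#' @param tolerance_px named integer merge radius, per channel.
#' @param min_object_px named integer speckle-rejection size, per channel.
#' @param calib_ref named numeric calibration reference intensity per channel;
#'   usually filled in by [calibrate_macro()].
#' @return object of class `threshold_macro` (immutable by convention: the
#'   quantification functions never modify it).
#' @export
threshold_macro <- function(threshold_fraction = c(DAPI = 0.5, OXTR = 0.5, CHAT = 0.5),
                            tolerance_px = c(DAPI = 1L, OXTR = 1L, CHAT = 1L),
                            min_object_px = c(DAPI = 1L, OXTR = 1L, CHAT = 1L),
                            calib_ref = NULL) {
  stopifnot(all(threshold_fraction > 0), all(threshold_fraction < 1),
            all(min_object_px >= 1))
  structure(list(threshold_fraction = threshold_fraction,
                 tolerance_px = tolerance_px,
                 min_object_px = min_object_px,
                 calib_ref = calib_ref),
            class = "threshold_macro")
}

#' Calibrate a macro's reference intensities on a calibration image set
#'
#' The per-channel reference is the maximum intensity observed over the whole
#' calibration set, so one frozen threshold applies to all images.
#'
#' @param images list of `fish_image` objects (the calibration set).
#' @param macro a [threshold_macro()] whose `calib_ref` is to be filled.
#' @return a new frozen `threshold_macro` with `calib_ref` set.
#' @export
calibrate_macro <- function(images, macro = threshold_macro()) {
  stopifnot(length(images) >= 1L)
  chans <- names(images[[1]]$channels)
  ref <- vapply(chans, function(ch) {
    max(vapply(images, function(im) max(im$channels[[ch]]), numeric(1)))
  }, numeric(1))
  threshold_macro(macro$threshold_fraction, macro$tolerance_px,
                  macro$min_object_px, calib_ref = ref)
}

#' Binary mask with physical area
#'
#' @param pixels logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param source_channel channel label.
#' @return object of class `binary_mask` with `area_um2` = true-pixel count
#'   times `pixel_size^2`.
#' @export
binary_mask <- function(pixels, pixel_size, source_channel = NA_character_) {
  stopifnot(is.logical(pixels), is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels,
                 pixel_size = pixel_size,
                 area_um2 = sum(pixels) * pixel_size^2,
                 source_channel = source_channel),
            class = "binary_mask")
}

#' Threshold one channel under a frozen macro
#'
#' Pixels at or above `threshold_fraction * calib_ref` are kept; connected
#' components smaller than `min_object_px` are removed. Mean brightness is the
#' mean intensity over the retained mask (0 and flagged when the mask is
#' empty).
#'
#' @param image a `fish_image`.
#' @param channel one of "DAPI", "OXTR", "CHAT".
#' @param macro a calibrated [threshold_macro()].
#' @return list: `mask` (a `binary_mask`), `mean_brightness`, `empty` flag.
#' @export
apply_channel_threshold <- function(image, channel, macro) {
  if (!channel %in% names(image$channels))
    stop("channel '", channel, "' not present in image ", image$image_id)
  if (is.null(macro$calib_ref))
    stop("macro is not calibrated; run calibrate_macro() first")
  plane <- image$channels[[channel]]
  thr <- macro$threshold_fraction[[channel]] * macro$calib_ref[[channel]]
  keep <- plane >= thr
  min_px <- macro$min_object_px[[channel]]
  if (min_px > 1L && any(keep)) {
    lab <- EBImage::bwlabel(EBImage::Image(keep * 1))
    sizes <- tabulate(as.integer(lab))
    small <- which(sizes < min_px)
    if (length(small)) keep[as.integer(lab) %in% small] <- FALSE
  }
  empty <- !any(keep)
  list(mask = binary_mask(keep, image$pixel_size, channel),
       mean_brightness = if (empty) 0 else mean(plane[keep]),
       empty = empty)
}
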