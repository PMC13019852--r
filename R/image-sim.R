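#' Recipe for a synthetic duplex fISH image
#'
#' Describes a single-plane three-channel (DAPI / OXTR / ChAT) field of view.
#' NBM recipes contain magnocellular ChAT+ blobs with deliberate 1-2 px cracks
#' (so the crack-filling stage has work to do); VP recipes contain no ChAT
#' blobs, mirroring the absence of condensed cholinergic signal there.
#'
#' @param image_shape integer (height, width) in pixels.
#' @param pixel_size pixel size in micrometres.
#' @param n_neurons number of magnocellular ChAT+ blobs (forced to 0 for VP).
#' @param neuron_radius mean and sd of blob radius, micrometres.
#' @param crack_width width in pixels of the artificial gap cut through each
#'   blob.
#' @param oxtr_density_inside,oxtr_density_outside expected OXTR puncta per
#'   1000 square micrometres inside / outside the blobs, at latent level 1.
#' @param puncta_radius puncta radius, micrometres.
#' @param background_level,signal_level intensity units (12-bit range).
#' @param psf_sigma Gaussian point-spread sigma, micrometres (0 = no blur).
#' @param noise logical; add Poisson-Gaussian noise.
#' @param read_noise_sd Gaussian read-noise sd, intensity units.
#' @param dapi_n_nuclei,dapi_radius DAPI nuclei count and radius (um).
#' @param region "NBM" or "VP".
#' @return object of class `image_recipe`.
#' @export
image_recipe <- function(image_shape = c(160L, 160L),
                         pixel_size = 0.75,
                         n_neurons = 6L,
                         neuron_radius = c(15, 3),
                         crack_width = 2L,
                         oxtr_density_inside = 30,
                         oxtr_density_outside = 3,
                         puncta_radius = 0.9,
                         background_level = 80,
                         signal_level = 2000,
                         psf_sigma = 0.6,
                         noise = TRUE,
                         read_noise_sd = 15,
                         dapi_n_nuclei = 60L,
                         dapi_radius = 3,
                         region = c("NBM", "VP")) {
  region <- match.arg(region)
  if (region == "VP") n_neurons <- 0L
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            pixel_size > 0, oxtr_density_inside >= 0,
            oxtr_density_outside >= 0, crack_width >= 0,
            background_level >= 0, signal_level > 0,
            background_level + signal_level <= 4095)
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_neurons = as.integer(n_neurons), neuron_radius = neuron_radius,
    crack_width = as.integer(crack_width),
    oxtr_density_inside = oxtr_density_inside,
    oxtr_density_outside = oxtr_density_outside,
    puncta_radius = puncta_radius, background_level = background_level,
    signal_level = signal_level, psf_sigma = psf_sigma, noise = noise,
    read_noise_sd = read_noise_sd, dapi_n_nuclei = as.integer(dapi_n_nuclei),
    dapi_radius = dapi_radius, region = region
  ), class = "image_recipe")
}

#' Declared acquisition settings shared by every image of a dataset
#'
#' Exposure descriptors recorded in image metadata; the QC stage rejects
#' images whose recorded exposures differ from these declared values.
#' @return named list, one exposure string per channel.
#' @export
declared_exposure <- function() {
  list(DAPI = "1/5s", OXTR = "1/4s", CHAT = "3s")
}

#' Construct an image stack container
#'
#' @param channels named list of numeric matrices (DAPI, OXTR, CHAT), equal
#'   dimensions, nonnegative intensities.
#' @param pixel_size micrometres per pixel.
#' @param specimen_id,region,batch_id,image_id metadata.
#' @param exposure named list of per-channel exposure descriptors.
#' @return object of class `fish_image`.
#' @export
fish_image <- function(channels, pixel_size, specimen_id = NA_character_,
                       region = NA_character_, batch_id = NA_character_,
                       image_id = NA_character_,
                       exposure = declared_exposure()) {
  stopifnot(is.list(channels), all(c("DAPI", "OXTR", "CHAT") %in% names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channel planes must share the same shape")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("intensities must be nonnegative")
  structure(list(channels = channels, pixel_size = pixel_size,
                 specimen_id = specimen_id, region = region,
                 batch_id = batch_id, image_id = image_id,
                 exposure = exposure),
            class = "fish_image")
}

# cut a straight crack of given pixel width through a blob, angle in radians
cut_crack <- function(mask, cy, cx, angle, width) {
  if (width <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  # signed distance of each pixel centre to the line through (cy,cx)
  d <- (rows - cy) * cos(angle) - (cols - cx) * sin(angle)
  mask & !(abs(d) <= width / 2)
}

#' Simulate one three-channel fISH image with ground truth
#'
#' Renders ChAT+ blobs (with cracks), OXTR puncta at densities scaled by the
#' specimen's latent mRNA level, and DAPI nuclei; applies Gaussian blur and
#' Poisson-Gaussian noise per the recipe. Ground-truth masks and puncta counts
#' are returned alongside so downstream measurements can be checked against
#' what was actually drawn.
#'
#' @param recipe an [image_recipe()].
#' @param latent_mrna multiplicative latent mRNA level (1 = recipe densities).
#' @param seed integer seed.
#' @param specimen_id,batch_id,image_id metadata for the stack.
#' @return list with `image` (a `fish_image`), and `truth`: `chat_blobs`
#'   (uncracked blob mask), `chat_signal` (cracked, as rendered), `oxtr_puncta`
#'   (puncta mask), `n_puncta_in`, `n_puncta_out`, `puncta_in_mask`,
#'   `puncta_out_mask`.
#' @export
simulate_image <- function(recipe, latent_mrna = 1, seed = 1L,
                           specimen_id = "S1", batch_id = "B1",
                           image_id = "I1") {
  stopifnot(inherits(recipe, "image_recipe"), latent_mrna >= 0)
  set.seed(seed)
  h <- recipe$image_shape[1]; w <- recipe$image_shape[2]
  px <- recipe$pixel_size
  r_px <- recipe$puncta_radius / px
  if (recipe$puncta_radius < px)
    warning("puncta radius below pixel size; puncta rendered as single pixels")

  blob <- matrix(FALSE, h, w)       # uncracked ground truth
  blob_signal <- matrix(FALSE, h, w) # with cracks, as rendered
  if (recipe$n_neurons > 0) {
    for (i in seq_len(recipe$n_neurons)) {
      rad <- max(2, stats::rnorm(1, recipe$neuron_radius[1],
                                 recipe$neuron_radius[2])) / px
      rad <- min(rad, (min(h, w) - 3) / 2)  # blob must fit the field of view
      cy <- stats::runif(1, rad + 1, h - rad)
      cx <- stats::runif(1, rad + 1, w - rad)
      d <- disk_mask(h, w, cy, cx, rad)
      blob <- blob | d
      d_cracked <- cut_crack(d, cy, cx, stats::runif(1, 0, pi),
                             sample(seq_len(max(1L, recipe$crack_width)), 1L))
      blob_signal <- blob_signal | d_cracked
    }
  }

  # OXTR puncta: Poisson counts at per-1000-um^2 densities scaled by latent level
  area_in <- sum(blob) * px^2
  area_out <- (h * w - sum(blob)) * px^2
  n_in <- stats::rpois(1, recipe$oxtr_density_inside * latent_mrna * area_in / 1000)
  n_out <- stats::rpois(1, recipe$oxtr_density_outside * latent_mrna * area_out / 1000)
  place_puncta <- function(where, n) {
    m <- matrix(FALSE, h, w)
    idx <- which(where)
    if (n == 0L || length(idx) == 0L) return(m)
    centres <- idx[sample.int(length(idx), n, replace = TRUE)]
    for (ci in centres) {
      cy <- (ci - 1L) %% h + 1L
      cx <- (ci - 1L) %/% h + 1L
      m <- m | disk_mask(h, w, cy, cx, r_px)
    }
    m
  }
  puncta_in <- place_puncta(blob, n_in)
  puncta_out <- place_puncta(!blob, n_out)
  oxtr_mask <- puncta_in | puncta_out

  dapi_mask <- matrix(FALSE, h, w)
  for (i in seq_len(recipe$dapi_n_nuclei)) {
    rad <- recipe$dapi_radius / px
    dapi_mask <- dapi_mask | disk_mask(h, w, stats::runif(1, 1, h),
                                       stats::runif(1, 1, w), rad)
  }

  render <- function(mask) {
    plane <- recipe$background_level + recipe$signal_level * mask
    if (recipe$psf_sigma > 0) {
      sig_px <- recipe$psf_sigma / px
      plane <- as.matrix(EBImage::gblur(EBImage::Image(plane), sigma = sig_px))
    }
    if (recipe$noise) {
      plane <- stats::rpois(length(plane), pmax(plane, 0)) +
        stats::rnorm(length(plane), 0, recipe$read_noise_sd)
      plane <- matrix(plane, h, w)
    }
    pmin(pmax(plane, 0), 4095)
  }
  channels <- list(DAPI = render(dapi_mask),
                   OXTR = render(oxtr_mask),
                   CHAT = render(blob_signal))
  list(
    image = fish_image(channels, px, specimen_id = specimen_id,
                       region = recipe$region, batch_id = batch_id,
                       image_id = image_id),
    truth = list(chat_blobs = blob, chat_signal = blob_signal,
                 oxtr_puncta = oxtr_mask,
                 puncta_in_mask = puncta_in, puncta_out_mask = puncta_out,
                 n_puncta_in = n_in, n_puncta_out = n_out)
  )
}
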