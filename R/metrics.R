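#' Quantify one image: signal areas, brightness, and the OXTR partition
#'
#' Runs the frozen macro on each channel, builds the condensed cholinergic
#' region from the ChAT mask, partitions OXTR signal inside/outside it, and
#' normalises the two partition areas by the cholinergic region area (the
#' extraction target), accounting for differences in the number and size of
#' cholinergic neurons across images. ChAT-normalised metrics are missing
#' (not zero) when the image has no cholinergic region: a 0/0 ratio is
#' undefined.
#'
#' @param image a `fish_image`.
#' @param macro a calibrated [threshold_macro()].
#' @param close_radius_px closing radius for [build_condensed_region()].
#' @param declared named list of declared exposure settings (QC metadata
#'   check); `NULL` skips the comparison.
#' @return one-row data.frame of image metrics.
#' @export
compute_image_metrics <- function(image, macro, close_radius_px = 2,
                                  declared = declared_exposure()) {
  th <- lapply(c(DAPI = "DAPI", OXTR = "OXTR", CHAT = "CHAT"),
               function(ch) apply_channel_threshold(image, ch, macro))
  chat_region <- build_condensed_region(th$CHAT$mask, close_radius_px)
  part <- partition_oxtr(th$OXTR$mask, chat_region)
  npix <- prod(dim(image$channels$OXTR))
  chat_area <- chat_region$area_um2
  exposure_ok <- is.null(declared) ||
    identical(image$exposure[names(declared)], declared)
  data.frame(
    specimen_id = image$specimen_id, region = image$region,
    batch_id = image$batch_id, image_id = image$image_id,
    pixel_size = image$pixel_size,
    dapi_area_um2 = th$DAPI$mask$area_um2,
    oxtr_area_um2 = th$OXTR$mask$area_um2,
    chat_area_um2 = th$CHAT$mask$area_um2,
    dapi_brightness = th$DAPI$mean_brightness,
    oxtr_brightness = th$OXTR$mean_brightness,
    chat_brightness = th$CHAT$mean_brightness,
    chat_region_area_um2 = chat_area,
    chat_area_fraction = sum(chat_region$pixels) / npix,
    oxtr_in_chat_area_um2 = part$in_area_um2,
    oxtr_out_chat_area_um2 = part$out_area_um2,
    oxtr_total_area_um2 = part$in_area_um2 + part$out_area_um2,
    chat_norm_oxtr_in = if (chat_area > 0) part$in_area_um2 / chat_area else NA_real_,
    chat_norm_oxtr_out = if (chat_area > 0) part$out_area_um2 / chat_area else NA_real_,
    oxtr_empty = th$OXTR$empty, chat_empty = th$CHAT$empty,
    exposure_ok = exposure_ok,
    stringsAsFactors = FALSE
  )
}

#' QC rules for image inclusion
#'
#' NBM images require condensed cholinergic signal (magnocellular neurons);
#' VP images require OXTR signal and the absence of significant ChAT signal;
#' every image's recorded exposure must match the dataset-wide declared
#' settings.
#'
#' @param tau_chat_nbm minimum ChAT region area fraction for NBM inclusion.
#' @param tau_chat_vp maximum ChAT region area fraction for VP inclusion.
#' @return list of thresholds.
#' @export
qc_rules <- function(tau_chat_nbm = 0.01, tau_chat_vp = 0.005) {
  list(tau_chat_nbm = tau_chat_nbm, tau_chat_vp = tau_chat_vp)
}

#' Apply QC inclusion rules to a table of image metrics
#'
#' @param metrics data.frame from [compute_image_metrics()] (row-bound).
#' @param rules a [qc_rules()] list.
#' @return list: `included` (data.frame), `excluded` (data.frame with a
#'   machine-readable `reason` per exclusion).
#' @export
qc_filter_images <- function(metrics, rules = qc_rules()) {
  reason <- rep(NA_character_, nrow(metrics))
  bad_exposure <- !metrics$exposure_ok
  reason[bad_exposure] <- "imaging_parameters"
  nbm <- metrics$region == "NBM"
  vp <- metrics$region == "VP"
  no_chat <- nbm & metrics$chat_area_fraction < rules$tau_chat_nbm
  reason[is.na(reason) & no_chat] <- "no_magnocellular_signal"
  chat_in_vp <- vp & metrics$chat_area_fraction > rules$tau_chat_vp
  reason[is.na(reason) & chat_in_vp] <- "chat_in_vp"
  no_oxtr <- vp & metrics$oxtr_total_area_um2 <= 0
  reason[is.na(reason) & no_oxtr] <- "no_oxtr_signal"
  keep <- is.na(reason)
  excluded <- metrics[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(included = metrics[keep, , drop = FALSE], excluded = excluded)
}

#' Aggregate included image metrics to specimen level
#'
#' Area and brightness metrics are means over a specimen's included images in
#' a region. Percent colocalization is NOT the mean of per-image ratios: the
#' OXTR-in and OXTR-total areas are summed across a specimen's images first
#' and the ratio of the sums is taken (sample-wise summation), which weights
#' images by their total signal.
#'
#' @param metrics data.frame of included image metrics.
#' @return data.frame, one row per specimen x region: the four mRNA metrics
#'   (`nbm_oxtr_area`, `chatplus_oxtr_area`, `chatminus_oxtr_area`,
#'   `vp_oxtr_area`), brightness analogues, `percent_colocalization`, and
#'   `n_images_used`.
#' @export
aggregate_specimen <- function(metrics) {
  if (nrow(metrics) == 0L) stop("no included images to aggregate")
  key <- interaction(metrics$specimen_id, metrics$region, drop = TRUE)
  rows <- lapply(split(metrics, key), function(g) {
    region <- g$region[1]
    sum_total <- sum(g$oxtr_total_area_um2)
    pct <- if (region == "NBM" && sum_total > 0)
      100 * sum(g$oxtr_in_chat_area_um2) / sum_total else NA_real_
    data.frame(
      specimen_id = g$specimen_id[1], region = region,
      batch_id = g$batch_id[1],
      nbm_oxtr_area = if (region == "NBM") mean(g$oxtr_total_area_um2) else NA_real_,
      chatplus_oxtr_area = if (region == "NBM") mean(g$chat_norm_oxtr_in, na.rm = TRUE) else NA_real_,
      chatminus_oxtr_area = if (region == "NBM") mean(g$chat_norm_oxtr_out, na.rm = TRUE) else NA_real_,
      vp_oxtr_area = if (region == "VP") mean(g$oxtr_total_area_um2) else NA_real_,
      nbm_oxtr_brightness = if (region == "NBM") mean(g$oxtr_brightness) else NA_real_,
      vp_oxtr_brightness = if (region == "VP") mean(g$oxtr_brightness) else NA_real_,
      chat_brightness = mean(g$chat_brightness),
      percent_colocalization = pct,
      percent_coloc_flagged = region == "NBM" && sum_total <= 0,
      n_images_used = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise percent colocalization overall and by neurotype
#'
#' @param specimens data.frame from [aggregate_specimen()] (NBM rows carry
#'   `percent_colocalization`).
#' @param cohort data.frame with `specimen_id` and `neurotype` (ASD/AST).
#' @return list: `overall` (mean, sem, n) and `by_group` data.frame with a
#'   Welch two-sample p-value attached as attribute `p_welch` and in the
#'   `p_welch` column.
#' @export
percent_colocalization_summary <- function(specimens, cohort) {
  nbm <- specimens[specimens$region == "NBM" &
                     !is.na(specimens$percent_colocalization), , drop = FALSE]
  m <- merge(nbm, cohort[, c("specimen_id", "neurotype")], by = "specimen_id")
  overall <- list(mean = mean(m$percent_colocalization),
                  sem = sem(m$percent_colocalization),
                  n = nrow(m))
  groups <- split(m$percent_colocalization, m$neurotype)
  by_group <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(neurotype = g, mean = mean(groups[[g]]),
               sem = sem(groups[[g]]), n = length(groups[[g]]),
               stringsAsFactors = FALSE)
  }))
  p <- if (length(groups) == 2L && all(lengths(groups) >= 2L))
    tryCatch(stats::t.test(groups[[1]], groups[[2]])$p.value,
             error = function(e) NA_real_)  # constant data -> undefined
  else NA_real_
  by_group$p_welch <- p
  list(overall = overall, by_group = by_group)
}

#' One-way ANOVA of channel brightness across assay batches
#'
#' Checks that fluorescence brightness does not differ across assay batches.
#' Batches with fewer than two images are excluded (flagged); a degenerate
#' design (zero variance everywhere) reports F = 0, p = 1 with a flag rather
#' than erroring.
#'
#' @param metrics image-metrics data.frame with `batch_id` and per-channel
#'   brightness columns.
#' @param channels channels to test.
#' @return data.frame: channel, F, p, df1, df2, degenerate flag, and the
#'   batches excluded for n < 2.
#' @export
batch_brightness_check <- function(metrics,
                                   channels = c("DAPI", "OXTR", "CHAT")) {
  cols <- c(DAPI = "dapi_brightness", OXTR = "oxtr_brightness",
            CHAT = "chat_brightness")
  out <- lapply(channels, function(ch) {
    y <- metrics[[cols[[ch]]]]
    b <- metrics$batch_id
    counts <- table(b)
    small <- names(counts)[counts < 2L]
    keep <- !(b %in% small)
    y <- y[keep]; b <- factor(b[keep])
    if (nlevels(b) < 2L)
      return(data.frame(channel = ch, F = NA_real_, p = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, degenerate = TRUE,
                        excluded_batches = paste(small, collapse = ";")))
    if (stats::var(y) == 0)
      return(data.frame(channel = ch, F = 0, p = 1,
                        df1 = nlevels(b) - 1, df2 = length(y) - nlevels(b),
                        degenerate = TRUE,
                        excluded_batches = paste(small, collapse = ";")))
    fit <- stats::aov(y ~ b)
    s <- summary(fit)[[1]]
    data.frame(channel = ch, F = s$`F value`[1], p = s$`Pr(>F)`[1],
               df1 = s$Df[1], df2 = s$Df[2], degenerate = FALSE,
               excluded_batches = paste(small, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
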