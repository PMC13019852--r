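make_image <- function(planes, pixel_size = 1, region = "NBM", ...) {
  fish_image(planes, pixel_size, specimen_id = "S1", region = region,
             batch_id = "B1", image_id = "I1", ...)
}
flat <- function(v, h = 32, w = 32) matrix(v, h, w)

test_that("thresholding handles empty, block, and generator-truth cases", {
  # constant-zero plane -> empty mask, flagged brightness
  img <- make_image(list(DAPI = flat(0), OXTR = flat(0), CHAT = flat(0)))
  mac <- threshold_macro(calib_ref = c(DAPI = 100, OXTR = 100, CHAT = 100))
  th <- apply_channel_threshold(img, "OXTR", mac)
  expect_true(th$empty)
  expect_identical(th$mask$area_um2, 0)
  expect_identical(th$mean_brightness, 0)

  # 10x10 block at full intensity, pixel 1 um, fraction 0.5 -> 100 um^2
  plane <- flat(0)
  plane[11:20, 6:15] <- 100
  img <- make_image(list(DAPI = flat(0), OXTR = plane, CHAT = flat(0)))
  th <- apply_channel_threshold(img, "OXTR", mac)
  expect_identical(th$mask$area_um2, 100)
  expect_identical(th$mean_brightness, 100)

  # missing channel errors
  expect_error(apply_channel_threshold(img, "GFP", mac), "not present")

  # clean generator image: mask identical to ground-truth puncta (>= 99%)
  rec <- image_recipe(oxtr_density_inside = 20, oxtr_density_outside = 0,
                      image_shape = c(128L, 128L), noise = FALSE, psf_sigma = 0)
  sim <- simulate_image(rec, seed = 11L)
  thg <- apply_channel_threshold(sim$image, "OXTR", calibrate_macro(list(sim$image)))
  agree <- mean(thg$mask$pixels == sim$truth$oxtr_puncta)
  expect_gte(agree, 0.99)
})

test_that("speckle rejection removes components below min_object_px", {
  plane <- flat(0)
  plane[5, 5] <- 100            # single pixel
  plane[20:22, 20:22] <- 100    # 9-px block
  img <- make_image(list(DAPI = flat(0), OXTR = plane, CHAT = flat(0)))
  mac <- threshold_macro(min_object_px = c(DAPI = 1L, OXTR = 4L, CHAT = 1L),
                         calib_ref = c(DAPI = 100, OXTR = 100, CHAT = 100))
  th <- apply_channel_threshold(img, "OXTR", mac)
  expect_identical(sum(th$mask$pixels), 9L)
})

test_that("crack filling bridges gaps, matches a brute-force oracle, and is safe on edge cases", {
  # two half-disks separated by a 1-px vertical crack
  m <- disk_mask_for_tests <- matrix(FALSE, 41, 41)
  full <- fishcoloc:::disk_mask(41, 41, 21, 21, 12)
  m <- full; m[, 21] <- FALSE
  closed <- build_condensed_region(binary_mask(m, 1), close_radius_px = 2,
                                   fill_holes = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(closed$pixels * 1))
  expect_equal(max(lab), 1)

  # oracle agreement on the same raster (modulo the extensivity union)
  oracle <- brute_close(m, 2) | m
  expect_gte(mean(closed$pixels == oracle), 0.99)

  # empty input -> empty output
  e <- build_condensed_region(binary_mask(matrix(FALSE, 10, 10), 1))
  expect_false(any(e$pixels))

  # interior hole is filled
  holed <- full
  holed[20:22, 20:22] <- FALSE
  filled <- build_condensed_region(binary_mask(holed, 1), close_radius_px = 0,
                                   fill_holes = TRUE)
  expect_true(all(filled$pixels[full]))

  expect_error(build_condensed_region(binary_mask(m, 1), close_radius_px = -1),
               "nonnegative")
})

test_that("closing is non-shrinking and idempotent on random masks", {
  set.seed(100)
  for (i in 1:25) {
    m <- binary_mask(random_mask(32, 32, runif(1, 0.1, 0.5)), 1)
    once <- build_condensed_region(m, close_radius_px = 2)
    expect_true(all(m$pixels <= once$pixels))  # never shrinks
    twice <- build_condensed_region(once, close_radius_px = 2)
    expect_identical(once$pixels, twice$pixels)
  }
})

test_that("partition is exact and matches the per-pixel oracle", {
  # oxtr inside chat -> out = 0; disjoint -> in = 0
  chat <- binary_mask(fishcoloc:::disk_mask(20, 20, 10, 10, 6), 0.5)
  inner <- binary_mask(fishcoloc:::disk_mask(20, 20, 10, 10, 3), 0.5)
  expect_identical(partition_oxtr(inner, chat)$out_area_um2, 0)
  corner <- matrix(FALSE, 20, 20); corner[1:2, 1:2] <- TRUE
  expect_identical(partition_oxtr(binary_mask(corner, 0.5), chat)$in_area_um2, 0)
  expect_error(partition_oxtr(binary_mask(corner, 0.5),
                              binary_mask(matrix(FALSE, 5, 5), 0.5)),
               "shape mismatch")

  set.seed(7)
  for (i in 1:20) {
    px <- runif(1, 0.2, 2)
    a <- binary_mask(random_mask(64, 64), px)
    b <- binary_mask(random_mask(64, 64), px)
    got <- partition_oxtr(a, b)
    want <- brute_partition(a$pixels, b$pixels, px)
    expect_identical(got$in_px, want$in_px)
    expect_identical(got$out_px, want$out_px)
    expect_identical(got$in_px + got$out_px, sum(a$pixels))
    expect_equal(got$in_area_um2 + got$out_area_um2, sum(a$pixels) * px^2)
  }
})

test_that("image metrics compose the stages and flag missing ChAT regions", {
  # VP-style image: no ChAT -> normalised metric missing, total = out
  oxtr <- flat(0); oxtr[4:6, 4:6] <- 100
  img <- make_image(list(DAPI = flat(0), OXTR = oxtr, CHAT = flat(0)),
                    region = "VP")
  mac <- threshold_macro(calib_ref = c(DAPI = 100, OXTR = 100, CHAT = 100))
  m <- compute_image_metrics(img, mac)
  expect_true(is.na(m$chat_norm_oxtr_in))
  expect_identical(m$oxtr_total_area_um2, m$oxtr_out_chat_area_um2)

  # constructed arithmetic: chat region area known, oxtr fully inside
  chat <- flat(0); chat[1:20, 1:20] <- 100     # closes to >= 400 px
  oxtr2 <- flat(0); oxtr2[1:10, 1:10] <- 100   # 100 px inside
  img2 <- make_image(list(DAPI = flat(0), OXTR = oxtr2, CHAT = chat))
  m2 <- compute_image_metrics(img2, mac, close_radius_px = 0)
  expect_equal(m2$chat_norm_oxtr_in, 100 / 400)
  expect_identical(m2$oxtr_in_chat_area_um2 + m2$oxtr_out_chat_area_um2,
                   m2$oxtr_total_area_um2)

  # generator truth: in/out areas within 5% of truth puncta areas (clean)
  rec <- image_recipe(image_shape = c(128L, 128L), noise = FALSE,
                      psf_sigma = 0, crack_width = 0L)
  sim <- simulate_image(rec, seed = 13L)
  mg <- compute_image_metrics(sim$image, calibrate_macro(list(sim$image)))
  px2 <- sim$image$pixel_size^2
  truth_in <- sum(sim$truth$oxtr_puncta & sim$truth$chat_blobs) * px2
  truth_out <- sum(sim$truth$oxtr_puncta & !sim$truth$chat_blobs) * px2
  expect_lt(abs(mg$oxtr_in_chat_area_um2 - truth_in) / truth_in, 0.05)
  expect_lt(abs(mg$oxtr_out_chat_area_um2 - truth_out) / max(truth_out, 1), 0.25)
})

test_that("QC filter applies region rules and the metadata check", {
  base <- data.frame(
    specimen_id = "S", region = c("VP", "NBM", "NBM"),
    image_id = c("vp_chatty", "nbm_empty", "nbm_badexp"),
    chat_area_fraction = c(0.4, 0, 0.3),
    oxtr_total_area_um2 = c(10, 10, 10),
    exposure_ok = c(TRUE, TRUE, FALSE))
  qc <- qc_filter_images(base)
  expect_identical(nrow(qc$included), 0L)
  expect_identical(qc$excluded$reason[qc$excluded$image_id == "vp_chatty"],
                   "chat_in_vp")
  expect_identical(qc$excluded$reason[qc$excluded$image_id == "nbm_empty"],
                   "no_magnocellular_signal")
  expect_identical(qc$excluded$reason[qc$excluded$image_id == "nbm_badexp"],
                   "imaging_parameters")
})

test_that("specimen aggregation uses sample-wise summation for percent colocalization", {
  m <- data.frame(
    specimen_id = "S1", region = "NBM", batch_id = "B1",
    image_id = c("a", "b"),
    oxtr_total_area_um2 = c(40, 10),
    oxtr_in_chat_area_um2 = c(30, 10),
    oxtr_out_chat_area_um2 = c(10, 0),
    chat_norm_oxtr_in = c(0.3, 0.1), chat_norm_oxtr_out = c(0.1, 0),
    oxtr_brightness = c(50, 60), chat_brightness = c(40, 40))
  agg <- aggregate_specimen(m)
  expect_equal(agg$percent_colocalization, 100 * 40 / 50)  # 80, not 87.5
  expect_false(isTRUE(all.equal(agg$percent_colocalization,
                                mean(100 * c(30 / 40, 10 / 10)))))

  # single image -> per-image ratio; identical images -> same as single
  one <- aggregate_specimen(m[1, ])
  expect_equal(one$percent_colocalization, 75)
  dup <- m; dup$oxtr_total_area_um2 <- 40; dup$oxtr_in_chat_area_um2 <- 30
  dup$oxtr_out_chat_area_um2 <- 10; dup$chat_norm_oxtr_in <- 0.3
  expect_equal(aggregate_specimen(dup)$percent_colocalization, 75)
  expect_equal(aggregate_specimen(dup)$nbm_oxtr_area, 40)
})

test_that("percent colocalization summary gives mean, SEM and group comparison", {
  specs <- data.frame(specimen_id = c("A", "B", "C", "D"), region = "NBM",
                      percent_colocalization = c(60, 80, 100, 100))
  cohort <- data.frame(specimen_id = c("A", "B", "C", "D"),
                       neurotype = c("ASD", "ASD", "AST", "AST"))
  s <- percent_colocalization_summary(specs, cohort)
  expect_equal(s$overall$mean, 85)
  expect_equal(s$by_group$mean[s$by_group$neurotype == "ASD"], 70)
  expect_equal(s$by_group$sem[s$by_group$neurotype == "ASD"], 10)
  expect_equal(s$by_group$sem[s$by_group$neurotype == "AST"], 0)
  all100 <- specs; all100$percent_colocalization <- 100
  s2 <- percent_colocalization_summary(all100, cohort)
  expect_equal(s2$overall$mean, 100)
  expect_equal(s2$overall$sem, 0)
})

test_that("batch brightness ANOVA is calibrated and detects shifted batches", {
  mk <- function(vals, batches) data.frame(
    batch_id = batches, dapi_brightness = vals, oxtr_brightness = vals,
    chat_brightness = vals)
  # degenerate: identical values -> F = 0, p = 1, flagged
  d <- batch_brightness_check(mk(rep(5, 12), rep(c("B1", "B2", "B3"), 4)))
  expect_true(all(d$degenerate))
  expect_true(all(d$p == 1))
  expect_true(all(d$F == 0))

  # one batch shifted by 5 SD -> p < 0.001
  set.seed(8)
  vals <- c(rnorm(10, 0, 1), rnorm(10, 5, 1), rnorm(10, 0, 1))
  d2 <- batch_brightness_check(mk(vals, rep(c("B1", "B2", "B3"), each = 10)))
  expect_true(all(d2$p < 0.001))

  # null calibration: same distribution across batches
  set.seed(9)
  rej <- vapply(1:200, function(i) {
    v <- rnorm(30)
    batch_brightness_check(mk(v, rep(c("B1", "B2", "B3"), 10)))$p[1] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.04)

  # a batch with < 2 images is excluded and logged
  d3 <- batch_brightness_check(mk(c(rnorm(8), 3), c(rep(c("B1", "B2"), 4), "B3")))
  expect_identical(unique(d3$excluded_batches), "B3")
})

test_that("tiling an image does not change specimen percent colocalization", {
  set.seed(21)
  for (i in 1:10) {
    oxtr <- random_mask(32, 32, 0.2); chat <- random_mask(32, 32, 0.3)
    whole <- brute_partition(oxtr, chat, 1)
    tiles <- list(1:16, 17:32)
    parts <- lapply(tiles, function(rows)
      partition_oxtr(binary_mask(oxtr[rows, ], 1), binary_mask(chat[rows, ], 1)))
    in_sum <- sum(vapply(parts, `[[`, numeric(1), "in_area_um2"))
    tot_sum <- sum(vapply(parts, function(p) p$in_area_um2 + p$out_area_um2,
                          numeric(1)))
    expect_identical(in_sum, whole$in_area)
    expect_identical(tot_sum, whole$in_area + whole$out_area)
  }
})
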