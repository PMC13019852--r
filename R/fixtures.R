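#' Write a complete synthetic fixture set to disk
#'
#' Simulates a cohort, genotypes, and per-specimen images (2-5 per specimen
#' per available region), and writes: multi-page TIFF stacks (one page per
#' channel, order DAPI, OXTR, CHAT, recorded in the manifest), `cohort.csv`,
#' `binding.csv`, `genotypes.vcf` (VCF v4.2, three biallelic records), and
#' `manifest.json` with all seeds and ground truth. Reruns with the same
#' seeds are byte-identical.
#'
#' @param spec a [cohort_spec()].
#' @param ld an [ld_spec()].
#' @param recipe_nbm,recipe_vp [image_recipe()]s for the two regions.
#' @param outdir output directory (created).
#' @param images_per_specimen integer range images are drawn from
#'   (default 2:5).
#' @return invisibly, the manifest list.
#' @export
write_fixture_set <- function(spec, ld = ld_spec(),
                              recipe_nbm = image_recipe(region = "NBM"),
                              recipe_vp = image_recipe(region = "VP"),
                              outdir,
                              images_per_specimen = 2:5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(outdir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  cohort <- simulate_cohort(spec)
  gsim <- simulate_genotypes(ld, n = nrow(cohort),
                             seed = stage_seed(spec$seed, "genotypes"))
  geno <- gsim$genotypes
  rownames(geno) <- cohort$specimen_id

  # latent level driving puncta density: relative to the AST baseline of the
  # metric each region's images report
  rel_chat <- cohort$latent_chatplus / 18.7
  rel_vp <- cohort$latent_vp / 2292

  set.seed(stage_seed(spec$seed, "image_plan"))
  images <- list()
  for (i in seq_len(nrow(cohort))) {
    for (reg in c("NBM", "VP")) {
      if (reg == "NBM" && !cohort$has_nbm[i]) next
      if (reg == "VP" && !cohort$has_vp[i]) next
      n_img <- sample(images_per_specimen, 1L)
      for (j in seq_len(n_img)) {
        iid <- sprintf("%s_%s_%02d", cohort$specimen_id[i], reg, j)
        iseed <- stage_seed(spec$seed, paste0("img_", iid))
        recipe <- if (reg == "NBM") recipe_nbm else recipe_vp
        latent <- if (reg == "NBM") rel_chat[i] else rel_vp[i]
        sim <- simulate_image(recipe, latent_mrna = latent, seed = iseed,
                              specimen_id = cohort$specimen_id[i],
                              batch_id = cohort$batch_id[i], image_id = iid)
        path <- file.path(img_dir, paste0(iid, ".tif"))
        write_image_stack(sim$image, path)
        images[[length(images) + 1L]] <- list(
          image_id = iid, specimen_id = cohort$specimen_id[i], region = reg,
          batch_id = cohort$batch_id[i], seed = iseed, path = basename(path),
          n_puncta_in = sim$truth$n_puncta_in,
          n_puncta_out = sim$truth$n_puncta_out)
      }
    }
  }

  utils::write.csv(cohort[, c("specimen_id", "neurotype", "age", "batch_id",
                              "has_nbm", "has_vp")],
                   file.path(outdir, "cohort.csv"), row.names = FALSE)
  binding <- rbind(
    data.frame(specimen_id = cohort$specimen_id, region = "NBM",
               binding_density = cohort$binding_nbm),
    data.frame(specimen_id = cohort$specimen_id, region = "VP",
               binding_density = cohort$binding_vp))
  binding <- binding[!is.na(binding$binding_density), ]
  utils::write.csv(binding, file.path(outdir, "binding.csv"), row.names = FALSE)
  write_genotypes_vcf(geno, file.path(outdir, "genotypes.vcf"))

  manifest <- list(
    seed = spec$seed,
    channel_order = c("DAPI", "OXTR", "CHAT"),
    pixel_size = recipe_nbm$pixel_size,
    declared_exposure = declared_exposure(),
    n_specimens = nrow(cohort),
    images = images,
    ld = list(maf = ld$maf, dprime_targets = ld$dprime_targets,
              loci = ld$loci),
    ground_truth = list(
      latent = cohort[, c("specimen_id", "latent_nbm", "latent_chatplus",
                          "latent_chatminus", "latent_vp")])
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a three-channel image stack as multi-page TIFF
#'
#' One 16-bit page per channel in the order DAPI, OXTR, CHAT; intensities are
#' stored as `value / 4095` of the 12-bit range.
#'
#' @param image a `fish_image`.
#' @param path output .tif path.
#' @export
write_image_stack <- function(image, path) {
  pages <- lapply(image$channels[c("DAPI", "OXTR", "CHAT")],
                  function(m) pmin(pmax(m / 4095, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a `fish_image`
#'
#' @param path .tif path.
#' @param pixel_size micrometres per pixel.
#' @param specimen_id,region,batch_id,image_id metadata (usually from the
#'   manifest).
#' @param channel_order page-to-channel mapping.
#' @param exposure per-channel exposure metadata.
#' @return a `fish_image` (intensities rescaled back to the 12-bit range).
#' @export
read_image_stack <- function(path, pixel_size, specimen_id = NA, region = NA,
                             batch_id = NA, image_id = NA,
                             channel_order = c("DAPI", "OXTR", "CHAT"),
                             exposure = declared_exposure()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < length(channel_order))
    stop("missing channel: ", path, " has ", length(pages), " pages, ",
         length(channel_order), " expected")
  channels <- stats::setNames(lapply(seq_along(channel_order),
                                     function(i) pages[[i]] * 4095),
                              channel_order)
  fish_image(channels, pixel_size, specimen_id = specimen_id, region = region,
             batch_id = batch_id, image_id = image_id, exposure = exposure)
}

#' Write a three-record VCF v4.2 for the SNP panel
#'
#' @param genotypes n x 3 matrix of 0/1/2 ALT-dosage codes with specimen ids
#'   as rownames and locus ids as colnames.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(!is.null(rownames(genotypes)), ncol(genotypes) == 3L)
  ids <- rownames(genotypes)
  gt_of <- function(g) {
    ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
  }
  # OXTR is on 3p25.3; positions are placeholders in ascending order
  meta <- c("##fileformat=VCFv4.2",
            "##source=fishcoloc",
            "##contig=<ID=3>",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", ids), collapse = "\t")
  pos <- c(8792000, 8797000, 8802000)
  recs <- vapply(seq_len(3L), function(j) {
    paste(c("3", pos[j], colnames(genotypes)[j], "C", "T", ".", "PASS", ".",
            "GT", gt_of(genotypes[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, recs), path)
  invisible(path)
}

#' Read a SNP panel from VCF or 0/1/2 CSV
#'
#' VCF is parsed with vcfR; a CSV must have a `specimen_id` column and one
#' 0/1/2-coded column per locus.
#'
#' @param path .vcf or .csv path.
#' @return matrix of ALT-dosage codes, rownames = specimen ids.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(x) {
      out <- rep(NA_integer_, length(x))
      out[x %in% c("0/0", "0|0")] <- 0L
      out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
      out[x %in% c("1/1", "1|1")] <- 2L
      out
    }
    m <- apply(gt, 1, code)          # transposes to sample x locus
    rownames(m) <- colnames(gt)
    m
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    m <- as.matrix(d[, setdiff(names(d), "specimen_id"), drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- d$specimen_id
    if (any(!is.na(m) & !(m %in% 0:2))) stop("genotype codes must be 0/1/2")
    m
  }
}
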