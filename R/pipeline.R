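#' Pipeline run configuration
#'
#' One master seed is fanned out deterministically to every stage
#' ([stage_seed()]), so any stage can be rerun in isolation. The config
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param data_dir directory holding `images/`, `cohort.csv`, `binding.csv`,
#'   `genotypes.vcf` (as written by [write_fixture_set()]).
#' @param out_dir output directory for tables and the manifest.
#' @param seed master seed.
#' @param threshold_fraction,min_object_px macro parameters (per channel).
#' @param close_radius_px crack-filling closing radius.
#' @param tau_chat_nbm,tau_chat_vp QC thresholds on ChAT area fraction.
#' @param transform_overrides named list metric -> "identity"/"sqrt"/"auto".
#' @param B permutation count.
#' @param k_folds CV folds.
#' @param pixel_size micrometres per pixel of the input images.
#' @return list of class `run_config`.
#' @export
run_config <- function(data_dir, out_dir, seed = 1L,
                       threshold_fraction = c(DAPI = 0.5, OXTR = 0.5, CHAT = 0.5),
                       min_object_px = c(DAPI = 1L, OXTR = 1L, CHAT = 1L),
                       close_radius_px = 2,
                       tau_chat_nbm = 0.01, tau_chat_vp = 0.005,
                       transform_overrides = list(),
                       B = 1000L, k_folds = 5L, pixel_size = 0.75) {
  structure(list(data_dir = data_dir, out_dir = out_dir, seed = as.integer(seed),
                 threshold_fraction = threshold_fraction,
                 min_object_px = min_object_px,
                 close_radius_px = close_radius_px,
                 tau_chat_nbm = tau_chat_nbm, tau_chat_vp = tau_chat_vp,
                 transform_overrides = transform_overrides,
                 B = as.integer(B), k_folds = as.integer(k_folds),
                 pixel_size = pixel_size),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  # yaml drops names on atomic vectors; maps round-trip losslessly
  x$threshold_fraction <- as.list(x$threshold_fraction)
  x$min_object_px <- as.list(x$min_object_px)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$threshold_fraction <- unlist(x$threshold_fraction)
  x$min_object_px <- unlist(x$min_object_px)
  do.call(run_config, x)
}

load_inputs <- function(config) {
  manifest <- jsonlite::read_json(file.path(config$data_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohort <- utils::read.csv(file.path(config$data_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  binding_path <- file.path(config$data_dir, "binding.csv")
  binding <- if (file.exists(binding_path))
    utils::read.csv(binding_path, stringsAsFactors = FALSE) else NULL
  geno_path <- file.path(config$data_dir, "genotypes.vcf")
  genotypes <- if (file.exists(geno_path)) read_genotypes(geno_path) else NULL
  list(manifest = manifest, cohort = cohort, binding = binding,
       genotypes = genotypes)
}

#' Validate pipeline inputs
#'
#' Report-only checks of the join keys (every image's specimen in the cohort,
#' genotype ids a subset of cohort ids), channel presence of each TIFF,
#' pixel size, and genotype coding domain.
#'
#' @param config a [run_config()].
#' @return data.frame of violations (zero rows when clean): check, id, detail.
#' @export
validate_inputs <- function(config) {
  inp <- load_inputs(config)
  v <- list()
  add <- function(check, id, detail)
    v[[length(v) + 1L]] <<- data.frame(check = check, id = id, detail = detail,
                                       stringsAsFactors = FALSE)
  imgs <- inp$manifest$images
  bad <- setdiff(unique(imgs$specimen_id), inp$cohort$specimen_id)
  for (b in bad) add("specimen_join", b, "image specimen missing from cohort")
  if (!is.null(inp$genotypes)) {
    bad <- setdiff(rownames(inp$genotypes), inp$cohort$specimen_id)
    for (b in bad) add("genotype_join", b, "genotype id not in cohort")
    dom <- inp$genotypes[!is.na(inp$genotypes)]
    if (any(!(dom %in% 0:2)))
      add("genotype_domain", "panel", "codes outside {0,1,2}")
  }
  if (config$pixel_size <= 0)
    add("pixel_size", "config", "pixel_size must be positive")
  for (i in seq_len(nrow(imgs))) {
    path <- file.path(config$data_dir, "images", imgs$path[i])
    if (!file.exists(path)) { add("missing_file", imgs$image_id[i], path); next }
    n_pages <- length(tiff::readTIFF(path, all = TRUE, info = FALSE))
    if (n_pages < 3L)
      add("missing_channel", imgs$image_id[i],
          paste0(n_pages, " pages, 3 expected"))
  }
  if (length(v) == 0L)
    return(data.frame(check = character(0), id = character(0),
                      detail = character(0)))
  do.call(rbind, v)
}

#' Run the full pipeline: quantify, group stats, SNP association, age
#'
#' Executes quantification (macro calibration, per-image metrics, QC,
#' specimen aggregation), neurotype group models with EMMs, mRNA-binding
#' correlations, D' estimation and ridge association with permutation
#' p-values, and the age-correlation suite with oldest-specimen sensitivity.
#' Writes every table as CSV under `config$out_dir` plus `manifest.json`
#' recording seeds, row counts, and per-file MD5s; `manifest_hash` is the MD5
#' over the sorted file hashes, so identical runs have identical hashes.
#' A missing binding table skips the correlation stage with a logged warning;
#' missing genotypes skip the SNP stage.
#'
#' @param config a [run_config()].
#' @return list with every stage's tables and the manifest (invisibly
#'   written to disk).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_inputs(config)
  stage <- "quantify"
  res <- tryCatch({
    imgs_meta <- inp$manifest$images
    images <- lapply(seq_len(nrow(imgs_meta)), function(i) {
      read_image_stack(file.path(config$data_dir, "images", imgs_meta$path[i]),
                       pixel_size = config$pixel_size,
                       specimen_id = imgs_meta$specimen_id[i],
                       region = imgs_meta$region[i],
                       batch_id = imgs_meta$batch_id[i],
                       image_id = imgs_meta$image_id[i])
    })
    macro <- calibrate_macro(images, threshold_macro(
      threshold_fraction = config$threshold_fraction,
      min_object_px = config$min_object_px))
    image_metrics <- do.call(rbind, lapply(images, compute_image_metrics,
                                           macro = macro,
                                           close_radius_px = config$close_radius_px))
    qc <- qc_filter_images(image_metrics,
                           qc_rules(config$tau_chat_nbm, config$tau_chat_vp))
    specimens <- aggregate_specimen(qc$included)
    batch_check <- batch_brightness_check(qc$included)
    list(image_metrics = image_metrics, qc = qc, specimens = specimens,
         batch_check = batch_check, macro = macro)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  # wide specimen x metric table joined to cohort covariates
  metric_cols <- c("nbm_oxtr_area", "chatplus_oxtr_area",
                   "chatminus_oxtr_area", "vp_oxtr_area")
  wide <- merge_specimen_table(res$specimens, inp$cohort, inp$binding)

  stage <- "group_stats"
  group <- tryCatch({
    fits <- lapply(metric_cols, function(m) {
      tr <- config$transform_overrides[[m]] %||% "auto"
      tryCatch(fit_group_model(wide, m, transform = tr),
               error = function(e) {
                 warning("group model for '", m, "' skipped: ",
                         conditionMessage(e))
                 NULL
               })
    })
    names(fits) <- metric_cols
    fitted <- metric_cols[!vapply(fits, is.null, logical(1))]
    emm <- do.call(rbind, lapply(fitted, function(m)
      cbind(metric = m, fits[[m]]$emm)))
    model_summary <- do.call(rbind, lapply(fitted, function(m)
      data.frame(metric = m, transform = fits[[m]]$transform,
                 p_neurotype = fits[[m]]$p_neurotype, n = fits[[m]]$n)))
    coloc <- percent_colocalization_summary(res$specimens, inp$cohort)
    list(fits = fits, emm = emm, model_summary = model_summary, coloc = coloc)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  stage <- "group_stats:correlations"
  correlations <- if (is.null(inp$binding)) {
    warning("stage 'group_stats:correlations' skipped: binding CSV missing")
    NULL
  } else {
    binding_pairs <- list(c("chatplus_oxtr_area", "binding_nbm"),
                          c("nbm_oxtr_area", "binding_nbm"),
                          c("chatminus_oxtr_area", "binding_nbm"),
                          c("vp_oxtr_area", "binding_vp"))
    do.call(rbind, lapply(binding_pairs, function(pr) {
      do.call(rbind, lapply(c("all", "ASD", "AST"), function(st)
        correlate_metric_binding(wide, pr[1], against = pr[2], stratum = st)))
    }))
  }

  stage <- "snp"
  snp <- if (is.null(inp$genotypes)) {
    warning("stage 'snp' skipped: genotypes missing")
    NULL
  } else tryCatch({
    ldm <- estimate_dprime(inp$genotypes)
    phen <- snp_phenotype_table(wide)
    assoc <- run_association_suite(inp$genotypes, phen, B = config$B,
                                   seed = stage_seed(config$seed, "snp"),
                                   k = config$k_folds)
    list(ld = ldm, assoc = assoc)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  stage <- "age"
  age <- tryCatch({
    base <- age_correlation_suite(wide)
    sens <- drop_oldest_sensitivity(wide)
    list(base = base, sensitivity = sens)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  # --- write outputs -------------------------------------------------------
  out <- config$out_dir
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
    name
  }
  files <- c(
    wr(res$image_metrics, "image_metrics.csv"),
    wr(res$qc$excluded, "exclusion_log.csv"),
    wr(res$specimens, "specimen_metrics.csv"),
    wr(res$batch_check, "batch_brightness.csv"),
    wr(group$emm, "emm_table.csv"),
    wr(group$model_summary, "group_models.csv"),
    wr(group$coloc$by_group, "percent_colocalization.csv"),
    wr(age$sensitivity, "age_correlations.csv"))
  if (!is.null(correlations)) files <- c(files, wr(correlations, "binding_correlations.csv"))
  if (!is.null(snp)) {
    dpr <- as.data.frame(snp$ld$dprime)
    dpr <- cbind(locus = rownames(dpr), dpr)
    files <- c(files, wr(dpr, "dprime_matrix.csv"),
               wr(snp$assoc, "snp_association.csv"))
  }
  md5 <- tools::md5sum(file.path(out, files))
  names(md5) <- files
  manifest <- list(
    seed = config$seed,
    stage_seeds = list(snp = stage_seed(config$seed, "snp")),
    config = unclass(config),
    tables = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(md5[[f]]),
           rows = nrow(utils::read.csv(file.path(out, f))))),
    manifest_hash = manifest_hash(md5)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(quantify = res, group = group, correlations = correlations,
                 snp = snp, age = age, wide = wide, manifest = manifest))
}

# order-independent hash over output file hashes
manifest_hash <- function(md5) {
  s <- paste(sort(paste(names(md5), md5, sep = ":")), collapse = ";")
  tmp <- tempfile()
  writeLines(s, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

#' Join specimen metrics, cohort covariates, and binding densities
#'
#' @param specimens from [aggregate_specimen()].
#' @param cohort cohort CSV (specimen_id, neurotype, age, batch_id, ...).
#' @param binding long binding CSV (specimen_id, region, binding_density) or
#'   NULL.
#' @return wide data.frame, one row per specimen, with the four metrics,
#'   `percent_colocalization`, and `binding_nbm`/`binding_vp`.
#' @export
merge_specimen_table <- function(specimens, cohort, binding = NULL) {
  nbm <- specimens[specimens$region == "NBM",
                   c("specimen_id", "nbm_oxtr_area", "chatplus_oxtr_area",
                     "chatminus_oxtr_area", "percent_colocalization")]
  vp <- specimens[specimens$region == "VP", c("specimen_id", "vp_oxtr_area")]
  wide <- merge(merge(cohort, nbm, by = "specimen_id", all.x = TRUE),
                vp, by = "specimen_id", all.x = TRUE)
  if (!is.null(binding)) {
    bn <- binding[binding$region == "NBM", c("specimen_id", "binding_density")]
    names(bn)[2] <- "binding_nbm"
    bv <- binding[binding$region == "VP", c("specimen_id", "binding_density")]
    names(bv)[2] <- "binding_vp"
    wide <- merge(merge(wide, bn, by = "specimen_id", all.x = TRUE),
                  bv, by = "specimen_id", all.x = TRUE)
  }
  wide[order(wide$specimen_id), ]
}

# long phenotype table for the association suite: binding and the region's
# mRNA metric, per region
snp_phenotype_table <- function(wide) {
  mk <- function(region, phen, col) {
    if (!col %in% names(wide)) return(NULL)
    data.frame(specimen_id = wide$specimen_id, neurotype = wide$neurotype,
               region = region, phenotype = phen, value = wide[[col]],
               stringsAsFactors = FALSE)
  }
  do.call(rbind, Filter(Negate(is.null), list(
    mk("NBM", "binding", "binding_nbm"),
    mk("NBM", "chatplus_mrna", "chatplus_oxtr_area"),
    mk("VP", "binding", "binding_vp"),
    mk("VP", "mrna", "vp_oxtr_area"))))
}
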