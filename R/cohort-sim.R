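#' Specification of a simulated postmortem cohort
#'
#' Defaults encode the structure of the basal-forebrain study cohort: 12 ASD
#' and 18 AST specimens with usable NBM tissue (a subset of each with VP),
#' three assay batches, multiplicative neurotype effects on the four mRNA
#' metrics taken from the reported group-mean ratios, region-specific
#' mRNA-binding correlation targets (positive in NBM ChAT+, negative in VP),
#' and a positive age slope in ASD specimens only.
#'
#' Group effects are multiplicative with log-normal specimen noise: area
#' metrics are nonnegative and right-skewed, which is what makes a square-root
#' transform necessary downstream.
#'
#' @param n_asd,n_ast specimens per neurotype (>= 2).
#' @param age_range donor age range in years, uniform sampling.
#' @param effect_chatplus,effect_vp,effect_nbm,effect_chatminus multiplicative
#'   ASD vs AST effects on the four metrics.
#' @param binding_corr_nbm,binding_corr_vp target Pearson correlations between
#'   latent mRNA (ChAT+ for NBM, total for VP) and binding density.
#' @param age_slope_asd,age_slope_ast per-year proportional change in latent
#'   mRNA by neurotype.
#' @param noise_cv coefficient of variation of specimen-level log-normal noise.
#' @param n_batches number of assay batches.
#' @param vp_fraction_asd,vp_fraction_ast fraction of each group with usable
#'   VP tissue (defaults mirror 7/12 and 14/18).
#' @param batch_effect_sd sd of a multiplicative batch effect (0 = none).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 12L, n_ast = 18L,
                        age_range = c(2, 67),
                        effect_chatplus = 31.3 / 18.7,
                        effect_vp = 6831 / 2292,
                        effect_nbm = 12409 / 6972,
                        effect_chatminus = 1.163 / 0.619,
                        binding_corr_nbm = 0.39,
                        binding_corr_vp = -0.42,
                        age_slope_asd = 0.04,
                        age_slope_ast = 0,
                        noise_cv = 0.5,
                        n_batches = 3L,
                        vp_fraction_asd = 7 / 12,
                        vp_fraction_ast = 14 / 18,
                        batch_effect_sd = 0,
                        seed = 1L) {
  stopifnot(n_asd >= 2L, n_ast >= 2L, age_range[1] >= 0,
            age_range[2] >= age_range[1], noise_cv > 0, n_batches >= 1L)
  if (abs(binding_corr_nbm) > 1 || abs(binding_corr_vp) > 1)
    stop("binding correlation targets must lie in [-1, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

# couple a response to x at target Pearson correlation r
couple_to <- function(x, r, mean_y, sd_y) {
  z <- as.numeric(scale(x))
  eps <- stats::rnorm(length(x))
  mean_y + sd_y * (r * z + sqrt(1 - r^2) * as.numeric(scale(eps)))
}

#' Simulate a cohort with ground-truth latent mRNA levels
#'
#' One row per specimen carries neurotype, age, batch, region availability,
#' latent mRNA level for each of the four metrics, and a binding-density
#' value per region coupled to the latent mRNA at the target correlation
#' (positive in NBM ChAT+, negative in VP).
#'
#' Latent level for metric m of specimen i:
#' `baseline_m * effect_m^[ASD] * exp(slope_g * (age - mean age)) * exp(e)`,
#' with `e ~ N(0, sigma^2)`, `sigma^2 = log(1 + noise_cv^2)`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame (class `cohort_table`): cohort covariates, latent
#'   metrics `latent_nbm`, `latent_chatplus`, `latent_chatminus`, `latent_vp`,
#'   and `binding_nbm`, `binding_vp`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_asd + spec$n_ast
  neurotype <- c(rep("ASD", spec$n_asd), rep("AST", spec$n_ast))
  specimen_id <- sprintf("SP%03d", seq_len(n))
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  batch <- sprintf("B%d", (seq_len(n) - 1L) %% spec$n_batches + 1L)
  has_nbm <- rep(TRUE, n)
  n_vp_asd <- round(spec$vp_fraction_asd * spec$n_asd)
  n_vp_ast <- round(spec$vp_fraction_ast * spec$n_ast)
  has_vp <- c(seq_len(spec$n_asd) %in% sample.int(spec$n_asd, n_vp_asd),
              seq_len(spec$n_ast) %in% sample.int(spec$n_ast, n_vp_ast))

  sigma <- sqrt(log(1 + spec$noise_cv^2))
  asd <- neurotype == "ASD"
  slope <- ifelse(asd, spec$age_slope_asd, spec$age_slope_ast)
  age_c <- age - mean(spec$age_range)
  baselines <- c(nbm = 6972, chatplus = 18.7, chatminus = 0.619, vp = 2292)
  effects <- c(nbm = spec$effect_nbm, chatplus = spec$effect_chatplus,
               chatminus = spec$effect_chatminus, vp = spec$effect_vp)
  batch_mult <- if (spec$batch_effect_sd > 0) {
    be <- stats::rnorm(spec$n_batches, 0, spec$batch_effect_sd)
    exp(be)[as.integer(sub("B", "", batch))]
  } else rep(1, n)
  latent <- sapply(names(baselines), function(m) {
    baselines[[m]] * effects[[m]]^asd * exp(slope * age_c) *
      exp(stats::rnorm(n, 0, sigma)) * batch_mult
  })
  colnames(latent) <- paste0("latent_", names(baselines))

  binding_nbm <- couple_to(latent[, "latent_chatplus"], spec$binding_corr_nbm,
                           mean_y = 40, sd_y = 10)
  binding_vp <- couple_to(latent[, "latent_vp"], spec$binding_corr_vp,
                          mean_y = 30, sd_y = 8)
  binding_vp[!has_vp] <- NA_real_
  out <- data.frame(specimen_id, neurotype, age = age, batch_id = batch,
                    has_nbm, has_vp, latent, binding_nbm, binding_vp,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
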