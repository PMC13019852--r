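#' Residual diagnostics and transform recommendation
#'
#' Shapiro-Wilk on the residuals plus a Breusch-Pagan test of the squared
#' residuals on the fitted values target the two assumptions checked in the
#' group models: normality and homoskedasticity. A square-root transform is
#' recommended iff either test rejects (p < 0.05) on the identity-scale fit
#' and the square-root refit improves both diagnostics, where "improves"
#' means each test's p-value either increases or stays above the rejection
#' threshold (a test that passed before and still passes does not veto the
#' transform).
#'
#' @param fit an `lm` fit of the metric on neurotype (identity scale).
#' @param alpha rejection threshold.
#' @return list: `shapiro` (stat, p), `bp` (stat, p), `recommendation`
#'   ("identity" or "sqrt"), `sqrt_diagnostics` when a sqrt refit was tried,
#'   `degenerate` flag.
#' @export
diagnose_residuals <- function(fit, alpha = 0.05) {
  r <- stats::residuals(fit)
  if (length(r) < 6L) stop("insufficient residuals (need >= 6)")
  if (stats::sd(r) == 0)
    return(list(shapiro = c(stat = NA, p = NA), bp = c(stat = NA, p = NA),
                recommendation = "identity", degenerate = TRUE))
  one <- function(f) {
    rr <- stats::residuals(f)
    sw <- stats::shapiro.test(rr)
    bp <- lmtest::bptest(f)
    list(shapiro = c(stat = unname(sw$statistic), p = unname(sw$p.value)),
         bp = c(stat = unname(bp$statistic), p = unname(bp$p.value)))
  }
  d_id <- one(fit)
  rec <- "identity"; d_sqrt <- NULL
  if (d_id$shapiro["p"] < alpha || d_id$bp["p"] < alpha) {
    mf <- stats::model.frame(fit)
    y <- stats::model.response(mf)
    if (all(y >= 0)) {
      mf[[1]] <- sqrt(y)
      refit <- stats::lm(stats::formula(fit), data = mf)
      d_sqrt <- one(refit)
      better <- function(p_new, p_old) p_new > p_old || p_new >= alpha
      if (better(d_sqrt$shapiro[["p"]], d_id$shapiro[["p"]]) &&
          better(d_sqrt$bp[["p"]], d_id$bp[["p"]])) rec <- "sqrt"
    }
  }
  list(shapiro = d_id$shapiro, bp = d_id$bp, recommendation = rec,
       sqrt_diagnostics = d_sqrt, degenerate = FALSE)
}

#' Fit the neurotype group model for one mRNA metric
#'
#' Ordinary least squares of the (possibly square-root transformed) metric on
#' the neurotype indicator, with residual diagnostics attached and estimated
#' marginal means on the reporting scale. The transform is data-driven by
#' [diagnose_residuals()] unless pinned via `transform`.
#'
#' @param table data.frame with columns `specimen_id`, `neurotype`
#'   (ASD/AST), and the metric column.
#' @param metric metric column name.
#' @param transform "auto", "identity", or "sqrt".
#' @return object of class `group_fit`: `lm`, `transform`, `p_neurotype`,
#'   `coefficients`, `diagnostics`, `emm` (see
#'   [estimate_marginal_means()]), `metric`, `n`.
#' @export
fit_group_model <- function(table, metric, transform = c("auto", "identity", "sqrt")) {
  transform <- match.arg(transform)
  d <- table[!is.na(table[[metric]]), c("neurotype", metric)]
  names(d) <- c("neurotype", "value")
  d$neurotype <- factor(d$neurotype, levels = c("AST", "ASD"))
  counts <- base::table(d$neurotype)
  if (any(counts == 0L)) stop("both neurotype groups must be present")
  if (any(counts < 3L)) stop("need n >= 3 per group")
  fit_id <- stats::lm(value ~ neurotype, data = d)
  diag <- diagnose_residuals(fit_id)
  use <- if (transform == "auto") diag$recommendation else transform
  if (use == "sqrt") {
    if (any(d$value < 0)) stop("sqrt transform requires nonnegative values")
    d$tvalue <- sqrt(d$value)
  } else d$tvalue <- d$value
  fit <- stats::lm(tvalue ~ neurotype, data = d)
  sm <- summary(fit)$coefficients
  out <- structure(list(
    lm = fit, transform = use, metric = metric,
    coefficients = stats::coef(fit),
    p_neurotype = sm["neurotypeASD", "Pr(>|t|)"],
    diagnostics = diag, n = nrow(d), data = d
  ), class = "group_fit")
  out$emm <- estimate_marginal_means(out)
  out
}

#' Estimated marginal means on the reporting scale
#'
#' EMMs, standard errors, and 95% confidence limits come from the model on
#' its (possibly transformed) scale via the emmeans machinery. Under the
#' square-root transform the reporting-scale mean and CI endpoints are the
#' squares of the transformed-scale values (squaring preserves order for
#' nonnegative values); the SE is reported on the model scale and the
#' convention is recorded in the output.
#'
#' @param fit a `group_fit`.
#' @return data.frame: neurotype, emm_model_scale, se_model_scale, mean, ci_lo,
#'   ci_hi, transform, back_transform.
#' @export
estimate_marginal_means <- function(fit) {
  stopifnot(inherits(fit, "group_fit"))
  em <- as.data.frame(emmeans::emmeans(fit$lm, "neurotype"))
  back <- if (fit$transform == "sqrt") function(x) x^2 else identity
  data.frame(
    neurotype = as.character(em$neurotype),
    emm_model_scale = em$emmean, se_model_scale = em$SE,
    mean = back(em$emmean),
    ci_lo = back(em$lower.CL), ci_hi = back(em$upper.CL),
    transform = fit$transform,
    back_transform = if (fit$transform == "sqrt") "square" else "none",
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation between an mRNA metric and binding density (or age)
#'
#' @param table data.frame with the metric column, the covariate column, and
#'   `neurotype`.
#' @param metric metric column name.
#' @param against covariate column name (binding density or age).
#' @param stratum "all", "ASD", or "AST".
#' @return data.frame: metric, against, stratum, r, p, n, flagged (zero
#'   variance or n < 3).
#' @export
correlate_metric_binding <- function(table, metric, against = "binding",
                                     stratum = c("all", "ASD", "AST")) {
  stratum <- match.arg(stratum)
  d <- table
  if (stratum != "all") d <- d[d$neurotype == stratum, , drop = FALSE]
  x <- d[[metric]]; y <- d[[against]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(metric = metric, against = against, stratum = stratum,
                      r = NA_real_, p = NA_real_, n = n, flagged = TRUE,
                      stringsAsFactors = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(metric = metric, against = against, stratum = stratum,
             r = unname(ct$estimate), p = ct$p.value, n = n, flagged = FALSE,
             stringsAsFactors = FALSE)
}
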