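#' Ridge (L2-penalised) regression with unpenalised intercept
#'
#' Predictors are standardised internally (mean 0, unit sd); the objective is
#' `(1/(2n)) * ||y - b0 - Xs b||^2 + (lambda/2) * ||b||^2`, so the closed form
#' in standardised coordinates is `b = (Xs'Xs/n + lambda I)^-1 Xs'yc/n`.
#' Coefficients are reported back on the input scale. Zero-variance columns
#' are dropped with a warning and get coefficient 0.
#'
#' @param X n x p numeric matrix.
#' @param y numeric response.
#' @param lambda nonnegative penalty.
#' @return list of class `ridge_fit`: `beta` (input scale), `beta_std`
#'   (standardised scale), `intercept`, `lambda`, `r_squared`, `fitted`,
#'   `dropped` (zero-variance columns), scaling info.
#' @export
fit_ridge <- function(X, y, lambda) {
  stopifnot(is.matrix(X), nrow(X) == length(y), lambda >= 0)
  n <- nrow(X); p <- ncol(X)
  cn <- colnames(X) %||% paste0("x", seq_len(p))
  mu <- colMeans(X)
  sdx <- apply(X, 2, stats::sd)
  dropped <- sdx == 0 | is.na(sdx)
  if (any(dropped))
    warning("zero-variance columns dropped: ", paste(cn[dropped], collapse = ", "))
  Xs <- sweep(sweep(X[, !dropped, drop = FALSE], 2, mu[!dropped]), 2,
              sdx[!dropped], "/")
  yc <- y - mean(y)
  k <- ncol(Xs)
  beta_std <- if (k > 0)
    solve(crossprod(Xs) / n + diag(lambda, k), crossprod(Xs, yc) / n)
  else matrix(numeric(0), 0, 1)
  beta <- rep(0, p); names(beta) <- cn
  beta[!dropped] <- as.numeric(beta_std) / sdx[!dropped]
  intercept <- mean(y) - sum(beta * mu)
  fitted <- as.numeric(intercept + X %*% beta)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, 1 - sum((y - fitted)^2) / sst) else NA_real_
  bs <- rep(0, p); names(bs) <- cn
  bs[!dropped] <- as.numeric(beta_std)
  structure(list(beta = beta, beta_std = bs, intercept = intercept,
                 lambda = lambda, r_squared = r2, fitted = fitted,
                 dropped = cn[dropped], x_mean = mu, x_sd = sdx,
                 y_mean = mean(y)),
            class = "ridge_fit")
}

#' Default lambda grid for ridge cross-validation
#'
#' 100 log-spaced values spanning `[1e-4, 1e4]` times `max |Xs' yc| / n`.
#'
#' @param X,y data (X standardised internally for the anchor).
#' @param length.out grid size.
#' @return decreasing numeric vector.
#' @export
default_lambda_grid <- function(X, y, length.out = 100L) {
  sdx <- apply(X, 2, stats::sd)
  keep <- sdx > 0 & !is.na(sdx)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, colMeans(X)[keep]), 2,
              sdx[keep], "/")
  anchor <- max(abs(crossprod(Xs, y - mean(y)))) / nrow(X)
  if (anchor == 0) anchor <- 1
  sort(anchor * 10^seq(-4, 4, length.out = length.out), decreasing = TRUE)
}

#' Select lambda by k-fold cross-validation
#'
#' Folds are a random partition (deterministic under `seed`); CV error is the
#' mean squared prediction error over held-out folds; ties go to the smallest
#' lambda.
#'
#' @param X,y data.
#' @param k number of folds (default 5).
#' @param lambda_grid candidate penalties; `NULL` uses
#'   [default_lambda_grid()].
#' @param seed integer seed for the fold partition.
#' @return list: `lambda` (selected), `cv_curve` data.frame (lambda,
#'   cv_error), `folds`.
#' @export
cv_select_lambda <- function(X, y, k = 5L, lambda_grid = NULL, seed = 1L) {
  n <- nrow(X)
  if (n < k) stop("n (", n, ") < k (", k, "); use a smaller k")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y)
  if (length(lambda_grid) == 0L) stop("empty lambda grid")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  errs <- matrix(NA_real_, length(lambda_grid), k)
  for (f in seq_len(k)) {
    tr <- folds != f
    for (li in seq_along(lambda_grid)) {
      fit <- suppressWarnings(
        fit_ridge(X[tr, , drop = FALSE], y[tr], lambda_grid[li]))
      pred <- fit$intercept + X[!tr, , drop = FALSE] %*% fit$beta
      errs[li, f] <- mean((y[!tr] - pred)^2)
    }
  }
  cv <- rowMeans(errs)
  best <- min(lambda_grid[cv == min(cv)])  # ties -> smallest lambda
  list(lambda = best,
       cv_curve = data.frame(lambda = lambda_grid, cv_error = cv),
       folds = folds)
}

#' Permutation p-values for ridge coefficients
#'
#' The response is permuted B times and the ridge model refit with lambda
#' fixed at the observed-data CV selection (optionally re-selected per
#' permutation). Per-locus two-sided p-value uses the `(1 + b) / (1 + B)`
#' Monte-Carlo convention on |beta| (standardised scale), so p is never zero.
#'
#' @param X,y data.
#' @param lambda_fixed penalty from the observed-data CV selection.
#' @param B number of permutations (study default 1000).
#' @param seed integer seed.
#' @param reselect_lambda re-run CV inside each permutation (off by default).
#' @param k folds if re-selecting.
#' @return data.frame: locus, beta (input scale), beta_std, raw p; attribute
#'   `B` and `seed`.
#' @export
permute_pvalues <- function(X, y, lambda_fixed, B = 1000L, seed = 1L,
                            reselect_lambda = FALSE, k = 5L) {
  stopifnot(B >= 1L)
  obs <- suppressWarnings(fit_ridge(X, y, lambda_fixed))
  stat_obs <- abs(obs$beta_std)
  set.seed(seed)
  exceed <- rep(0L, length(stat_obs))
  for (b in seq_len(B)) {
    yp <- y[sample.int(length(y))]
    lam <- if (reselect_lambda)
      cv_select_lambda(X, yp, k = k, seed = seed + b)$lambda else lambda_fixed
    fb <- suppressWarnings(fit_ridge(X, yp, lam))
    exceed <- exceed + as.integer(abs(fb$beta_std) >= stat_obs)
  }
  p <- (1 + exceed) / (1 + B)
  out <- data.frame(locus = names(obs$beta), beta = obs$beta,
                    beta_std = obs$beta_std, p_raw = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}

#' Benjamini-Hochberg FDR adjustment for one model's locus p-values
#'
#' The family is the per-locus p-values of a single fitted model (three loci
#' here), matching per-model reporting of adjusted p-values.
#'
#' @param p raw p-values.
#' @return adjusted p-values (monotone, >= raw, capped at 1).
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Per-genotype phenotype means with SEM
#'
#' @param genotypes n x m matrix of 0/1/2 codes.
#' @param phenotype numeric vector aligned with rows.
#' @return data.frame: locus, genotype (0/1/2), mean, sem, n; genotype codes
#'   absent from the data are reported with NA mean.
#' @export
summarize_by_genotype <- function(genotypes, phenotype) {
  stopifnot(nrow(genotypes) == length(phenotype))
  loci <- colnames(genotypes) %||% paste0("locus", seq_len(ncol(genotypes)))
  out <- list()
  for (j in seq_along(loci)) {
    for (g in 0:2) {
      v <- phenotype[!is.na(genotypes[, j]) & genotypes[, j] == g &
                       !is.na(phenotype)]
      out[[length(out) + 1L]] <- data.frame(
        locus = loci[j], genotype = g,
        mean = if (length(v)) mean(v) else NA_real_,
        sem = sem(v), n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Ridge association suite across regions, strata, and phenotypes
#'
#' For each region x stratum (ASD, AST, combined) x phenotype (binding and
#' the region's mRNA metric): five-fold CV lambda selection, ridge fit,
#' permutation p-values at the selected lambda, and per-model BH-FDR
#' adjustment. Missing genotypes are mean-imputed per locus within the
#' analysis sample; strata with fewer than `min_n` complete observations are
#' skipped with a logged warning row.
#'
#' @param genotypes matrix with rownames = specimen ids, columns = loci.
#' @param phenotypes data.frame: specimen_id, neurotype, region, phenotype
#'   (name), value.
#' @param B permutations (study default 1000).
#' @param seed integer seed (fanned per model).
#' @param min_n minimum stratum size.
#' @param k CV folds.
#' @return data.frame, one row per model x locus, plus `skipped` attribute
#'   listing strata below `min_n`.
#' @export
run_association_suite <- function(genotypes, phenotypes, B = 1000L, seed = 1L,
                                  min_n = 6L, k = 5L) {
  stopifnot(!is.null(rownames(genotypes)))
  combos <- unique(phenotypes[, c("region", "phenotype")])
  strata <- c("combined", "ASD", "AST")
  rows <- list(); skipped <- list()
  for (ci in seq_len(nrow(combos))) {
    reg <- combos$region[ci]; ph <- combos$phenotype[ci]
    sub0 <- phenotypes[phenotypes$region == reg &
                         phenotypes$phenotype == ph &
                         !is.na(phenotypes$value), , drop = FALSE]
    for (st in strata) {
      sub <- if (st == "combined") sub0 else sub0[sub0$neurotype == st, , drop = FALSE]
      sub <- sub[sub$specimen_id %in% rownames(genotypes), , drop = FALSE]
      if (nrow(sub) < min_n) {
        skipped[[length(skipped) + 1L]] <- sprintf("%s/%s/%s (n=%d)", reg, ph,
                                                   st, nrow(sub))
        warning("stratum skipped: ", reg, "/", ph, "/", st,
                " has n = ", nrow(sub), " < ", min_n)
        next
      }
      X <- genotypes[sub$specimen_id, , drop = FALSE]
      storage.mode(X) <- "double"
      for (j in seq_len(ncol(X))) {        # mean imputation within stratum
        miss <- is.na(X[, j])
        if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
      }
      y <- sub$value
      mseed <- stage_seed(seed, paste("assoc", reg, ph, st))
      cv <- cv_select_lambda(X, y, k = k, seed = mseed)
      fit <- suppressWarnings(fit_ridge(X, y, cv$lambda))
      perm <- permute_pvalues(X, y, cv$lambda, B = B, seed = mseed + 1L)
      perm$p_fdr <- adjust_fdr(perm$p_raw)
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, phenotype = ph, stratum = st, n = nrow(sub),
        lambda = cv$lambda, r_squared = fit$r_squared,
        locus = perm$locus, beta = perm$beta, p_raw = perm$p_raw,
        p_fdr = perm$p_fdr, B = B, seed = mseed,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- unlist(skipped)
  out
}
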