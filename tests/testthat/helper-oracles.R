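# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the code paths they verify.

# per-pixel double loop partition of oxtr by chat region
brute_partition <- function(oxtr, chat, pixel_size) {
  in_px <- 0L; out_px <- 0L
  for (i in seq_len(nrow(oxtr))) for (j in seq_len(ncol(oxtr))) {
    if (oxtr[i, j]) {
      if (chat[i, j]) in_px <- in_px + 1L else out_px <- out_px + 1L
    }
  }
  list(in_area = in_px * pixel_size^2, out_area = out_px * pixel_size^2,
       in_px = in_px, out_px = out_px)
}

# brute-force binary dilation/erosion with a disk structuring element
# (disk footprint: centre offsets within radius r + 0.5, the usual odd-sized
# raster disc of width 2r + 1)
brute_dilate <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= (r + 0.5)^2, ]
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ii <- idx[k, 1] + offs$di; jj <- idx[k, 2] + offs$dj
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    out[cbind(ii[ok], jj[ok])] <- TRUE
  }
  out
}
brute_erode <- function(m, r) !brute_dilate(!m, r)
brute_close <- function(m, r) brute_erode(brute_dilate(m, r), r)

# two-locus log-likelihood of unphased genotype table at haplotype freqs
# (p11, p10, p01, p00); vectorised over a D grid at fixed allele freqs
ll_at_D <- function(tab, pa, pb, D) {
  p11 <- pa * pb + D; p10 <- pa * (1 - pb) - D
  p01 <- (1 - pa) * pb - D; p00 <- (1 - pa) * (1 - pb) + D
  P <- list(
    `00` = p00^2, `01` = 2 * p00 * p01, `02` = p01^2,
    `10` = 2 * p00 * p10, `11` = 2 * (p11 * p00 + p10 * p01),
    `12` = 2 * p01 * p11,
    `20` = p10^2, `21` = 2 * p10 * p11, `22` = p11^2)
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    nij <- tab[i + 1, j + 1]
    if (nij > 0) ll <- ll + nij * log(pmax(P[[paste0(i, j)]], 1e-300))
  }
  ll
}

# brute-force grid search over haplotype frequencies maximising the
# multinomial likelihood; allele margins fixed at sample frequencies (their
# MLE), leaving D the single free parameter, refined on a two-stage grid
grid_search_haplotypes <- function(g1, g2) {
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  pa <- mean(g1) / 2; pb <- mean(g2) / 2
  lo <- max(-pa * pb, -(1 - pa) * (1 - pb))
  hi <- min(pa * (1 - pb), (1 - pa) * pb)
  grid <- seq(lo, hi, length.out = 4001L)
  ll <- ll_at_D(tab, pa, pb, grid)
  best <- grid[which.max(ll)]
  step <- (hi - lo) / 4000
  fine <- seq(max(lo, best - step), min(hi, best + step), length.out = 4001L)
  llf <- ll_at_D(tab, pa, pb, fine)
  D <- fine[which.max(llf)]
  c(p11 = pa * pb + D, p10 = pa * (1 - pb) - D,
    p01 = (1 - pa) * pb - D, p00 = (1 - pa) * (1 - pb) + D)
}

# two-locus pair simulator: haplotypes drawn straight from the pair margin
# implied by allele freqs and a (positive-D) D' target
sim_pair_genotypes <- function(pa, pb, dprime, n) {
  dmax <- min(pa * (1 - pb), (1 - pa) * pb)
  D <- dprime * dmax
  pr <- c(pa * pb + D, pa * (1 - pb) - D, (1 - pa) * pb - D,
          (1 - pa) * (1 - pb) + D)
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  draw <- sample.int(4L, 2L * n, replace = TRUE, prob = pr)
  h <- hap[draw, , drop = FALSE]
  h[seq_len(n), ] + h[n + seq_len(n), ]
}

# independent iterative optimiser for the ridge objective
# (1/(2n))||y - b0 - Xs b||^2 + (lambda/2)||b||^2 in standardised coordinates
ridge_optim_oracle <- function(X, y, lambda) {
  n <- nrow(X)
  mu <- colMeans(X); sdx <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sdx, "/")
  obj <- function(par) {
    b0 <- par[1]; b <- par[-1]
    sum((y - b0 - Xs %*% b)^2) / (2 * n) + lambda * sum(b^2) / 2
  }
  gr <- function(par) {
    b0 <- par[1]; b <- par[-1]
    r <- as.numeric(y - b0 - Xs %*% b)
    c(-sum(r) / n, -as.numeric(crossprod(Xs, r)) / n + lambda * b)
  }
  fit <- optim(rep(0, ncol(X) + 1), obj, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  # restart to polish: the objective is quadratic, so a fresh Hessian
  # approximation from the near-solution reaches machine precision
  fit <- optim(fit$par, obj, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  fit$par[-1]  # standardised-scale coefficients
}

# hand BH step-up
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small cohort-derived analysis table used across stats tests
latent_table <- function(spec) {
  co <- simulate_cohort(spec)
  data.frame(specimen_id = co$specimen_id, neurotype = co$neurotype,
             age = co$age, batch_id = co$batch_id,
             nbm_oxtr_area = co$latent_nbm,
             chatplus_oxtr_area = co$latent_chatplus,
             chatminus_oxtr_area = co$latent_chatminus,
             vp_oxtr_area = ifelse(co$has_vp, co$latent_vp, NA),
             binding_nbm = co$binding_nbm, binding_vp = co$binding_vp,
             stringsAsFactors = FALSE)
}

# random blobby mask for property tests
random_mask <- function(h, w, p = 0.3) matrix(runif(h * w) < p, h, w)
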