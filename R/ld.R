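#' Specification of a three-locus SNP panel with linkage disequilibrium
#'
#' Defaults place the pairwise D' targets inside the medium-to-high band
#' (0.328-0.625) that motivates the ridge-regression treatment of the
#' association models.
#'
#' @param maf minor-allele frequency per locus, three values in (0, 0.5].
#' @param dprime_targets pairwise D' targets in [0,1], order (1,2), (1,3),
#'   (2,3).
#' @param loci locus identifiers.
#' @return object of class `ld_spec`.
#' @export
ld_spec <- function(maf = c(0.25, 0.30, 0.40),
                    dprime_targets = c(0.33, 0.63, 0.50),
                    loci = c("rs2268491", "rs2268495", "rs237885")) {
  stopifnot(length(maf) == 3L, all(maf > 0), all(maf <= 0.5),
            length(dprime_targets) == 3L,
            all(dprime_targets >= 0), all(dprime_targets <= 1),
            length(loci) == 3L)
  structure(list(maf = maf, dprime_targets = dprime_targets, loci = loci),
            class = "ld_spec")
}

# two-locus haplotype margin (P11,P10,P01,P00) at allele freqs pa, pb and
# positive-D D' target
pair_margin <- function(pa, pb, dprime) {
  dmax <- min(pa * (1 - pb), (1 - pa) * pb)
  D <- dprime * dmax
  m <- c(`11` = pa * pb + D, `10` = pa * (1 - pb) - D,
         `01` = (1 - pa) * pb - D, `00` = (1 - pa) * (1 - pb) + D)
  if (any(m < -1e-12))
    stop("infeasible D'/MAF combination: |D| exceeds Dmax = ", signif(dmax, 4))
  pmax(m, 0)
}

#' Three-locus haplotype frequencies matching MAFs and pairwise D' targets
#'
#' Builds the 2x2x2 haplotype distribution by iterative proportional fitting
#' (IPF) to the three two-way margins implied by the MAFs and D' targets
#' (positive-D convention). Deterministic; errors if the margins are jointly
#' incompatible.
#'
#' @param ld an [ld_spec()].
#' @param tol margin tolerance.
#' @param maxit IPF iteration cap.
#' @return numeric array dim c(2,2,2); index 1 = REF allele, 2 = ALT.
#' @export
haplotype_frequencies <- function(ld, tol = 1e-10, maxit = 10000L) {
  stopifnot(inherits(ld, "ld_spec"))
  p <- ld$maf
  targets <- list(
    `12` = pair_margin(p[1], p[2], ld$dprime_targets[1]),
    `13` = pair_margin(p[1], p[3], ld$dprime_targets[2]),
    `23` = pair_margin(p[2], p[3], ld$dprime_targets[3]))
  # q[a1, a2, a3], allele index 1 = REF (0), 2 = ALT (1)
  f <- function(pa) c(1 - pa, pa)
  q <- outer(outer(f(p[1]), f(p[2])), f(p[3]))
  dim(q) <- c(2, 2, 2)
  tmarg <- function(t) matrix(c(t["00"], t["01"], t["10"], t["11"]), 2, 2, byrow = TRUE)
  T12 <- tmarg(targets$`12`); T13 <- tmarg(targets$`13`); T23 <- tmarg(targets$`23`)
  pairs <- list(list(m = c(1, 2), t = T12), list(m = c(1, 3), t = T13),
                list(m = c(2, 3), t = T23))
  for (it in seq_len(maxit)) {
    for (pr in pairs) {
      cur <- apply(q, pr$m, sum)
      ratio <- ifelse(cur > 0, pr$t / cur, 0)
      q <- sweep_pair(q, pr$m, ratio)
    }
    err <- max(abs(apply(q, c(1, 2), sum) - T12),
               abs(apply(q, c(1, 3), sum) - T13),
               abs(apply(q, c(2, 3), sum) - T23))
    if (err < tol) break
  }
  if (err >= 1e-6)
    stop("infeasible D'/MAF combination: pairwise margins jointly ",
         "incompatible (IPF residual ", signif(err, 3), ")")
  q / sum(q)
}

# multiply q by a 2x2 factor indexed by the margin dims in `m`
sweep_pair <- function(q, m, ratio) {
  idx <- as.matrix(expand.grid(a1 = 1:2, a2 = 1:2, a3 = 1:2))
  fac <- ratio[cbind(idx[, m[1]], idx[, m[2]])]
  array(q[idx] * fac, dim = c(2, 2, 2))
}

#' Simulate unphased genotypes from a haplotype distribution
#'
#' Each individual is two independent haplotypes drawn from the three-locus
#' haplotype distribution of [haplotype_frequencies()], so pairwise D' is a
#' real property of the data and is recoverable by the EM estimator.
#'
#' @param ld an [ld_spec()].
#' @param n number of individuals.
#' @param seed integer seed.
#' @return list: `genotypes` (n x 3 matrix of 0/1/2 ALT-allele counts, column
#'   names = loci), `haplotypes` (2n x 3 binary matrix, truth for oracle
#'   checks), `hap_freqs` (the generating 2x2x2 array).
#' @export
simulate_genotypes <- function(ld, n, seed = 1L) {
  stopifnot(inherits(ld, "ld_spec"), n >= 1L)
  q <- haplotype_frequencies(ld)
  set.seed(seed)
  idx <- as.matrix(expand.grid(a1 = 0:1, a2 = 0:1, a3 = 0:1))
  draw <- sample.int(8L, 2L * n, replace = TRUE, prob = as.numeric(q))
  haps <- idx[draw, , drop = FALSE]
  geno <- haps[seq_len(n), , drop = FALSE] +
    haps[n + seq_len(n), , drop = FALSE]
  colnames(geno) <- ld$loci
  colnames(haps) <- ld$loci
  list(genotypes = geno, haplotypes = haps, hap_freqs = q)
}

#' Two-locus haplotype-frequency EM on unphased genotypes
#'
#' Resolves the double-heterozygote phase ambiguity by
#' expectation-maximisation over the four haplotype frequencies under
#' Hardy-Weinberg random union. The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param g1,g2 integer vectors of ALT-allele counts (0/1/2), missing allowed.
#' @param tol log-likelihood convergence tolerance.
#' @param maxit iteration cap.
#' @return list: `freqs` named (p11, p10, p01, p00), `D`, `dprime`,
#'   `loglik` trace, `iterations`, `n`.
#' @export
em_haplotype_pair <- function(g1, g2, tol = 1e-12, maxit = 2000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < 2L) stop("need >= 2 individuals with non-missing genotypes")
  pa <- mean(g1) / 2; pb <- mean(g2) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    return(list(freqs = c(p11 = pa * pb, p10 = pa * (1 - pb),
                          p01 = (1 - pa) * pb, p00 = (1 - pa) * (1 - pb)),
                D = 0, dprime = NA_real_, monomorphic = TRUE,
                loglik = numeric(0), iterations = 0L, n = n))
  }
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  p <- c(p11 = pa * pb, p10 = pa * (1 - pb),
         p01 = (1 - pa) * pb, p00 = (1 - pa) * (1 - pb))
  ll_trace <- numeric(0)
  ll_of <- function(p) {
    s <- 0
    for (i in 0:2) for (j in 0:2) {
      nij <- tab[i + 1, j + 1]
      if (nij > 0) s <- s + nij * log(genotype_prob(p, i, j))
    }
    s
  }
  for (it in seq_len(maxit)) {
    # E-step: expected haplotype counts; only (1,1) is ambiguous
    denom <- p["p11"] * p["p00"] + p["p10"] * p["p01"]
    x <- if (denom > 0) as.numeric(p["p11"] * p["p00"] / denom) else 0.5
    ndh <- tab[2, 2]
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + x * ndh
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - x) * ndh
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + (1 - x) * ndh
    c00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + x * ndh
    p_new <- c(p11 = c11, p10 = c10, p01 = c01, p00 = c00) / (2 * n)
    ll <- ll_of(p_new)
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) < tol) { p <- p_new; break }
    p <- p_new
  }
  pa_hat <- p["p11"] + p["p10"]; pb_hat <- p["p11"] + p["p01"]
  D <- as.numeric(p["p11"] - pa_hat * pb_hat)
  dmax <- if (D > 0) min(pa_hat * (1 - pb_hat), (1 - pa_hat) * pb_hat)
          else min(pa_hat * pb_hat, (1 - pa_hat) * (1 - pb_hat))
  dprime <- if (dmax > 0) abs(D) / as.numeric(dmax) else NA_real_
  list(freqs = p, D = D, dprime = min(dprime, 1), monomorphic = FALSE,
       loglik = ll_trace, iterations = length(ll_trace), n = n)
}

# P(unphased genotype pair) from haplotype freqs under random union
genotype_prob <- function(p, g1, g2) {
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  pr <- 0
  for (a in 1:4) for (b in 1:4) {
    if (haps[a, 1] + haps[b, 1] == g1 && haps[a, 2] + haps[b, 2] == g2)
      pr <- pr + p[a] * p[b]
  }
  as.numeric(pr)
}

#' Pairwise D' matrix for a genotype panel
#'
#' @param genotypes n x m matrix of 0/1/2 codes (missing allowed); column
#'   names are locus ids.
#' @return list: `dprime` (m x m matrix, NA diagonal), `fits` (per-pair EM
#'   results), `loci`.
#' @export
estimate_dprime <- function(genotypes) {
  m <- ncol(genotypes)
  loci <- colnames(genotypes) %||% paste0("locus", seq_len(m))
  dp <- matrix(NA_real_, m, m, dimnames = list(loci, loci))
  fits <- list()
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    fit <- em_haplotype_pair(genotypes[, i], genotypes[, j])
    dp[i, j] <- dp[j, i] <- fit$dprime
    fits[[paste(loci[i], loci[j], sep = ":")]] <- fit
  }
  list(dprime = dp, fits = fits, loci = loci)
}
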