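test_that("EM haplotype frequencies match the brute-force likelihood search", {
  set.seed(12)
  tried <- 0L
  for (i in 1:40) {
    g <- sim_pair_genotypes(runif(1, 0.15, 0.5), runif(1, 0.15, 0.5),
                            runif(1, 0, 0.9), sample(15:30, 1))
    if (length(unique(g[, 1])) == 1L || length(unique(g[, 2])) == 1L) next
    tried <- tried + 1L
    em <- em_haplotype_pair(g[, 1], g[, 2])
    oracle <- grid_search_haplotypes(g[, 1], g[, 2])
    expect_lt(max(abs(em$freqs - oracle)), 1e-4)
    if (tried >= 30L) break
  }
  expect_gte(tried, 30L)
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(4)
  for (i in 1:10) {
    g <- simulate_genotypes(ld_spec(), 40L, seed = i)
    em <- em_haplotype_pair(g$genotypes[, 1], g$genotypes[, 2])
    if (length(em$loglik) > 1L)
      expect_true(all(diff(em$loglik) >= -1e-9))
  }
})

test_that("D' is 1 under complete LD and recovered within +-0.08 at n = 2000", {
  # two haplotypes only (AB and ab): both loci carried by the same haplotype
  g1 <- c(rep(0L, 20), rep(1L, 20), rep(2L, 10))
  em <- em_haplotype_pair(g1, g1)
  expect_equal(em$dprime, 1, tolerance = 1e-9)

  ld <- ld_spec(dprime_targets = c(0.33, 0.63, 0.50))
  g <- simulate_genotypes(ld, 2000L, seed = 99L)
  dp <- estimate_dprime(g$genotypes)$dprime
  got <- c(dp[1, 2], dp[1, 3], dp[2, 3])
  expect_true(all(abs(got - ld$dprime_targets) <= 0.08))

  # monomorphic locus flagged
  em_mono <- em_haplotype_pair(rep(0L, 30), rbinom(30, 2, 0.4))
  expect_true(em_mono$monomorphic)
  expect_true(is.na(em_mono$dprime))
})

test_that("ridge closed form agrees with OLS at lambda 0 and shrinks to zero", {
  set.seed(3)
  X <- matrix(rnorm(90), 30, 3); y <- rnorm(30, X %*% c(1, -2, 0.5))
  f0 <- fit_ridge(X, y, 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(f0$beta - ols[-1])) / max(abs(ols[-1])), 1e-10)
  expect_lt(abs(f0$intercept - ols[1]), 1e-10)

  fbig <- fit_ridge(X, y, 1e8 * max(eigen(crossprod(scale(X)) / 30)$values))
  expect_lt(sqrt(sum(fbig$beta^2)), 1e-6 * sqrt(sum(f0$beta^2)))

  # zero-variance column dropped with zero coefficient
  Xz <- cbind(X, 1)
  expect_warning(fz <- fit_ridge(Xz, y, 0.1), "zero-variance")
  expect_identical(unname(fz$beta[4]), 0)
})

test_that("ridge solution matches an independent iterative optimiser", {
  set.seed(17)
  for (i in 1:15) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    y <- rnorm(20)
    lambda <- 10^runif(1, -3, 1)
    fit <- fit_ridge(X, y, lambda)
    oracle <- ridge_optim_oracle(X, y, lambda)
    expect_lt(max(abs(unname(fit$beta_std) - oracle)), 1e-8)
  }
})

test_that("coefficient norm is non-increasing along the lambda path", {
  set.seed(23)
  X <- matrix(rnorm(90), 30, 3); y <- rnorm(30, X %*% c(2, 0, -1))
  grid <- default_lambda_grid(X, y)
  norms <- vapply(grid, function(l) sqrt(sum(fit_ridge(X, y, l)$beta_std^2)),
                  numeric(1))
  expect_true(all(diff(norms) >= -1e-12))  # grid is decreasing in lambda
})

test_that("CV lambda selection is deterministic and responds to signal strength", {
  set.seed(41)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y_strong <- as.numeric(X %*% c(3, -3, 2)) + rnorm(200, 0, 0.5)
  cv1 <- cv_select_lambda(X, y_strong, seed = 5L)
  cv2 <- cv_select_lambda(X, y_strong, seed = 5L)
  expect_identical(cv1$lambda, cv2$lambda)
  grid <- cv1$cv_curve$lambda
  expect_lte(cv1$lambda, sort(grid)[ceiling(length(grid) / 3)])  # lower third

  noise_hits <- vapply(1:20, function(s) {
    set.seed(s + 500)
    Xn <- matrix(rnorm(400 * 3), 400, 3); yn <- rnorm(400)
    cv <- cv_select_lambda(Xn, yn, seed = s)
    g <- sort(cv$cv_curve$lambda)
    cv$lambda >= g[ceiling(2 * length(g) / 3)]
  }, logical(1))
  expect_gte(mean(noise_hits), 0.8)

  expect_error(cv_select_lambda(X[1:3, ], y_strong[1:3], k = 5), "smaller k")
})

test_that("permutation p-values honour the (1+b)/(1+B) convention", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3)
  y <- as.numeric(X %*% c(8, 0, 0)) + rnorm(20, 0, 0.1)  # x1 dominates
  pp <- permute_pvalues(X, y, lambda_fixed = 0.01, B = 200L, seed = 2L)
  expect_equal(pp$p_raw[1], 1 / 201)            # exceeds all permutations
  expect_true(all(pp$p_raw >= 1 / 201 & pp$p_raw <= 1))
  pp2 <- permute_pvalues(X, y, lambda_fixed = 0.01, B = 200L, seed = 2L)
  expect_identical(pp$p_raw, pp2$p_raw)          # deterministic under seed
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  set.seed(30)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1))
    adj <- adjust_fdr(p)
    expect_equal(adj, bh_by_hand(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("genotype summaries match a brute-force group-by", {
  set.seed(19)
  g <- simulate_genotypes(ld_spec(), 40L, seed = 8L)$genotypes
  ph <- rnorm(40)
  s <- summarize_by_genotype(g, ph)
  for (j in 1:3) for (code in 0:2) {
    v <- ph[g[, j] == code]
    row <- s[s$locus == colnames(g)[j] & s$genotype == code, ]
    if (length(v) == 0) expect_true(is.na(row$mean))
    else expect_equal(row$mean, mean(v))
  }
  # hand example
  s2 <- summarize_by_genotype(matrix(c(0, 0, 2, 2), ncol = 1), c(2, 4, 6, 8))
  expect_equal(s2$mean[s2$genotype == 0], 3)
  expect_equal(s2$mean[s2$genotype == 2], 7)
  expect_equal(s2$sem[s2$genotype == 0], 1)
  expect_true(is.na(s2$mean[s2$genotype == 1]))
})

test_that("association suite finds a causal SNP and is deterministic", {
  run_once <- function(seed) {
    g <- simulate_genotypes(ld_spec(), 60L, seed = seed)$genotypes
    rownames(g) <- sprintf("S%02d", 1:60)
    set.seed(seed + 1000)
    y <- 2 * g[, 2] + rnorm(60, 0, 1)   # locus 2 causal
    phen <- data.frame(specimen_id = rownames(g), neurotype = "ASD",
                       region = "NBM", phenotype = "binding", value = y)
    suppressWarnings(run_association_suite(g, phen, B = 100L, seed = seed))
  }
  hits <- vapply(1:10, function(s) {
    a <- run_once(s)
    a <- a[a$stratum == "ASD", ]
    a$locus[which.min(a$p_fdr)] == "rs2268495"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_identical(run_once(3)$p_raw, run_once(3)$p_raw)

  # a stratum below the minimum n is skipped with a warning
  g <- simulate_genotypes(ld_spec(), 8L, seed = 1L)$genotypes
  rownames(g) <- sprintf("S%d", 1:8)
  phen <- data.frame(specimen_id = rownames(g),
                     neurotype = rep(c("ASD", "AST"), 4),
                     region = "NBM", phenotype = "binding", value = rnorm(8))
  expect_warning(a <- run_association_suite(g, phen, B = 20L, seed = 1L),
                 "skipped")
  expect_false("ASD" %in% a$stratum)
})
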