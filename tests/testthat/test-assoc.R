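test_that("association scan matches the lm least-squares oracle", {
  arch <- small_arch(n_snps = 20, seed = 1)
  coh <- simulate_cohort(arch, 500, 0, seed = 2)
  sc <- snp_scan(coh)
  y <- coh$individuals$phenotype
  for (j in seq_len(20)) {
    ref <- summary(stats::lm(y ~ coh$genotypes[, j]))$coefficients[2, ]
    expect_equal(sc$estimate[j], unname(ref[1]), tolerance = 1e-8)
    expect_equal(sc$std_error[j], unname(ref[2]), tolerance = 1e-8)
    expect_equal(sc$p_value[j], unname(ref[4]), tolerance = 1e-8)
  }
  expect_equal(attr(sc, "n"), 500)
})

test_that("scan p-values are null-calibrated under a permuted phenotype", {
  arch <- trait_architecture(seed = 3)
  coh <- simulate_cohort(arch, 2000, 0, seed = 4)
  y_perm <- withr::with_seed(5, sample(coh$individuals$phenotype))
  sc <- snp_scan(coh$genotypes, y_perm)
  # type-I error at 0.05 within binomial error over 2500 null tests
  rate <- mean(sc$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 2500))
  # and roughly uniform overall
  expect_gt(suppressWarnings(ks.test(sc$p_value, "punif"))$p.value, 1e-4)
})

test_that("monomorphic SNPs are flagged, not fatal", {
  G <- cbind(rep(1L, 50), simulate_genotypes(0.5, 50, seed = 6))
  y <- rnorm(50)
  sc <- snp_scan(G, y)
  expect_true(sc$monomorphic[1])
  expect_identical(sc$p_value[1], 1)
  expect_false(sc$monomorphic[2])
})

test_that("a strongly contributing variant is found at genome-wide scale", {
  # one SNP with gv = 0.003 at n = 20,000: expected chi-square ~ 1 + n*gv/(1-gv)
  stats <- vapply(1:8, function(r) {
    withr::with_seed(100 + r, {
      g <- rbinom(20000, 2, 0.5)
      beta <- effect_size(0.003, 0.5)
      y <- beta * g + rnorm(20000, 0, sqrt(1 - 0.003))
    })
    sc <- snp_scan(cbind(g), y)
    c(chisq = sc$statistic^2, sig = sc$p_value < 5e-8)
  }, numeric(2))
  expect_equal(median(stats[1, ]), 1 + 20000 * 0.003 / (1 - 0.003),
               tolerance = 0.35)
  expect_gte(mean(stats[2, ]), 0.5)
})

test_that("two-stage discovery pools samples and nests thresholds", {
  # null trait: essentially nothing reaches 5e-8
  arch0 <- small_arch(seed = 7)
  arch0$beta_anc <- arch0$beta_mod <- rep(0, nrow(arch0))
  ts0 <- two_stage_discovery(arch0, 0, 3000, 3000, seed = 8)
  expect_identical(attr(ts0, "significant"), integer(0))

  # scaled-down polygenic trait: survivors nest, pooled p computed on union
  arch <- small_arch(seed = 9)
  ts <- two_stage_discovery(arch, 0, 4000, 4000, p1 = 1e-3, p2 = 1e-5,
                            seed = 10)
  expect_true(all(ts$p_discovery < 1e-3))
  expect_true(all(ts$significant == (ts$p_pooled < 1e-5)))
  expect_true(all(attr(ts, "significant") %in% ts$snp))
  expect_identical(attr(ts, "n_total"), 8000)

  # determinism
  ts2 <- two_stage_discovery(arch, 0, 4000, 4000, p1 = 1e-3, p2 = 1e-5,
                             seed = 10)
  expect_identical(ts$p_pooled, ts2$p_pooled)
})

test_that("GxE scan equals the lm interaction oracle", {
  arch <- small_arch(n_snps = 12, fraction = 0.25, fold = 1.8, seed = 11)
  coh <- simulate_cohort(arch, 300, 300, seed = 12)
  gxe <- gxe_scan(coh, 1:12)
  y <- coh$individuals$phenotype
  env <- coh$individuals$env
  for (j in 1:12) {
    ref <- lm_interaction(y, coh$genotypes[, j], env)
    expect_equal(gxe$estimate[j], ref$estimate, tolerance = 1e-8)
    expect_equal(gxe$std_error[j], ref$std_error, tolerance = 1e-8)
    expect_equal(gxe$p_value[j], ref$p_value, tolerance = 1e-8)
  }
  expect_error(gxe_scan(simulate_cohort(arch, 100, 0, seed = 13), 1:3),
               "single-environment")
})

test_that("GxE estimates recover the (fold-1)*beta interaction", {
  # mean interaction estimate across replicates ~ (f-1)*beta_anc for a
  # perturbed SNP; type-I error controlled at unperturbed SNPs
  f <- 1.6
  arch <- small_arch(n_snps = 100, fraction = 0.1, fold = f, seed = 14)
  snp <- which(arch$perturbed)[1]
  null_snp <- which(!arch$perturbed)[1]
  est <- matrix(NA_real_, 200, 2)
  pnull <- numeric(200)
  for (r in 1:200) {
    coh <- simulate_cohort(arch, 400, 400, seed = 2000 + r)
    g <- gxe_scan(coh, c(snp, null_snp))
    est[r, ] <- g$estimate
    pnull[r] <- g$p_value[2]
  }
  target <- (f - 1) * arch$beta_anc[snp]
  se <- stats::sd(est[, 1]) / sqrt(200)
  expect_lt(abs(mean(est[, 1]) - target), 3 * se)
  se0 <- stats::sd(est[, 2]) / sqrt(200)
  expect_lt(abs(mean(est[, 2])), 3 * se0)
  expect_lt(abs(mean(pnull < 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / 200))
})

test_that("unweighted GRS counts causal alleles", {
  G <- matrix(0L, 5, 4)
  expect_identical(grs(G, 1:4), rep(0L, 5))
  G2 <- simulate_genotypes(0.4, 10000, seed = 15)
  expect_equal(mean(grs(G2, 1L)), 0.8, tolerance = 0.05)
  G3 <- matrix(2L, 3, 250)
  expect_identical(grs(G3, 1:250), rep(500L, 3))
  expect_equal(grs(G3, 1:250), rowSums(G3[, 1:250]))
})

test_that("GRSxE test matches lm and the covariance-ratio closed form", {
  arch <- small_arch(n_snps = 60, fraction = 0.25, fold = 1.5, seed = 16)
  coh <- simulate_cohort(arch, 400, 400, seed = 17)
  set <- which(arch$perturbed)
  gx <- grsxe_test(coh, set)
  ref <- lm_interaction(coh$individuals$phenotype,
                        as.numeric(grs(coh, set)), coh$individuals$env)
  expect_equal(gx$estimate, ref$estimate, tolerance = 1e-8)
  expect_equal(gx$std_error, ref$std_error, tolerance = 1e-8)
  expect_equal(gx$p_value, ref$p_value, tolerance = 1e-8)

  # empty set: defined-missing, not an error
  gx0 <- grsxe_test(coh, integer(0))
  expect_true(is.na(gx0$p_value))
  expect_identical(gx0$n_snps, 0L)

  # mean estimate across replicates ~ (f-1) * sum_pert 2pq beta / sum_set 2pq
  tp <- 2 * arch$eaf * (1 - arch$eaf)
  target <- 0.5 * sum(tp[set] * arch$beta_anc[set]) / sum(tp[set])
  ests <- vapply(1:200, function(r) {
    grsxe_test(simulate_cohort(arch, 300, 300, seed = 4000 + r), set)$estimate
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(200)
  expect_lt(abs(mean(ests) - target), 3 * se)
})

test_that("GRSxE is null under fold = 1", {
  arch <- small_arch(n_snps = 60, fraction = 0.25, fold = 1, seed = 18)
  set <- which(arch$perturbed)
  ps <- vapply(1:100, function(r) {
    grsxe_test(simulate_cohort(arch, 200, 200, seed = 6000 + r), set)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / 100))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-4)
})

test_that("association power degrades monotonically with perturbation", {
  # full-width architecture, scaled-down cohorts: the focal gv is raised so
  # n * gv matches the flagship demo, while the mixed-cohort variance
  # inflation (driven by the modern-ancestral mean shift) keeps its size
  demo <- power_degradation_demo(
    gv_focal = 0.015, n = 4000, background_fraction = 0.10,
    folds = c(1, 1.5, 2), replicates = 60, seed = 19
  )
  med <- tapply(-log10(demo$p_value), demo$fold, median)
  expect_true(all(diff(med) <= 0))
  expect_gt(med[["1"]], -log10(5e-8)) # unperturbed arm is genome-wide strong

  # a null focal variant stays uniform at every fold
  demo0 <- power_degradation_demo(
    gv_focal = 0, n = 500, background_fraction = 0.10,
    folds = c(1, 2), replicates = 100, n_snps = 60,
    n_head = 17, head_total = 0.16 * 17 / 701, gv_max = 0.0019, seed = 20
  )
  for (f in c(1, 2)) {
    p <- demo0$p_value[demo0$fold == f]
    expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-4)
  }
})
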