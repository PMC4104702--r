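# Closed-form simple linear regression from per-SNP sufficient statistics.
# Returns estimate, std_error, statistic, p_value, monomorphic for each SNP.
ols_from_sums <- function(sx, sx2, sxy, n, sy, sy2, df_extra = 0) {
  Sxx <- sx2 - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- sy2 - sy^2 / n
  mono <- Sxx <= 0
  Sxx_safe <- ifelse(mono, 1, Sxx)
  b <- Sxy / Sxx_safe
  df <- n - 2 - df_extra
  ss <- pmax(Syy - b * Sxy, 0)
  sigma2 <- ss / df
  se <- sqrt(sigma2 / Sxx_safe)
  tt <- b / se
  p <- 2 * pt(-abs(tt), df)
  b[mono] <- 0
  se[mono] <- NA_real_
  tt[mono] <- NA_real_
  p[mono] <- 1
  list(estimate = b, std_error = se, statistic = tt, p_value = p,
       monomorphic = mono)
}

#' Per-SNP association scan
#'
#' Regresses the quantitative phenotype on allele dosage at each SNP
#' (intercept + dosage, ordinary least squares, two-sided t test on the
#' slope). Environment is never a covariate. Monomorphic SNPs (zero dosage
#' variance) are flagged and given p = 1 rather than raising an error, so
#' grid runs never abort.
#'
#' @param genotypes Integer dosage matrix (individuals x SNPs) or a `cohort`.
#' @param phenotype Phenotype vector (ignored when a `cohort` is given).
#' @param snp_set Optional 1-based SNP indices to scan (default: all).
#' @return A tibble of class `scan_result`: `snp`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `monomorphic`, with attribute `n`.
#' @examples
#' arch <- trait_architecture(seed = 1)
#' coh <- simulate_cohort(arch, 2000, 0, seed = 2)
#' head(snp_scan(coh))
#' @export
snp_scan <- function(genotypes, phenotype = NULL, snp_set = NULL) {
  if (inherits(genotypes, "cohort")) {
    phenotype <- genotypes$individuals$phenotype
    genotypes <- genotypes$genotypes
  }
  n <- nrow(genotypes)
  stopifnot(n >= 3, length(phenotype) == n, ncol(genotypes) >= 1)
  cols <- if (is.null(snp_set)) integer(0) else as.integer(snp_set)
  sums <- cpp_scan_sums(genotypes, as.numeric(phenotype), cols)
  sy <- sum(phenotype)
  sy2 <- sum(phenotype^2)
  fit <- ols_from_sums(sums[, 1], sums[, 2], sums[, 3], n, sy, sy2)
  out <- tibble::tibble(
    snp = if (is.null(snp_set)) seq_len(ncol(genotypes)) else as.integer(snp_set),
    estimate = fit$estimate, std_error = fit$std_error,
    statistic = fit$statistic, p_value = fit$p_value,
    monomorphic = fit$monomorphic
  )
  structure(out, class = c("scan_result", class(out)), n = n)
}

#' Two-stage GWAS discovery
#'
#' Stage 1 scans all SNPs in a discovery sample of `n_discovery` individuals
#' and keeps SNPs with p below `p1`. Stage 2 re-tests the survivors by pooled
#' ("mega-analysis") regression on the joined discovery + replication sample
#' of `n_discovery + n_replication` individuals and declares SNPs with pooled
#' p below `p2` significant. The environment composition of both samples is
#' set by `prop_modern` (0 = all ancestral, 1 = all modern / scenario B,
#' 0.5 = mixed / scenario C); environment is not in the regression model.
#'
#' @param arch A [trait_architecture()].
#' @param prop_modern Proportion of individuals from the modern environment.
#' @param n_discovery,n_replication Sample sizes of the two stages.
#' @param p1,p2 Stage thresholds (defaults 1e-5 and 5e-8).
#' @param seed Optional master seed.
#' @return A tibble of class `two_stage_result` with one row per stage-1
#'   survivor: `snp`, `p_discovery`, `estimate_pooled`, `std_error_pooled`,
#'   `p_pooled`, `significant`; attributes `significant` (indices),
#'   `n_discovery`, `n_total`, `p1`, `p2`.
#' @examples
#' arch <- trait_architecture(seed = 1)
#' ts <- two_stage_discovery(arch, 0, 3000, 3000, p1 = 1e-3, p2 = 1e-4,
#'                           seed = 2)
#' attr(ts, "significant")
#' @export
two_stage_discovery <- function(arch, prop_modern = 0,
                                n_discovery = 50000, n_replication = 50000,
                                p1 = 1e-5, p2 = 5e-8, seed = NULL) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            prop_modern >= 0, prop_modern <= 1)
  n_mod_d <- round(prop_modern * n_discovery)
  disc <- simulate_cohort(arch, n_discovery - n_mod_d, n_mod_d,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, "discovery"))
  s1 <- snp_scan(disc)
  surv <- which(s1$p_value < p1)
  if (length(surv) == 0) {
    out <- tibble::tibble(
      snp = integer(0), p_discovery = numeric(0),
      estimate_pooled = numeric(0), std_error_pooled = numeric(0),
      p_pooled = numeric(0), significant = logical(0)
    )
    return(structure(out, class = c("two_stage_result", class(out)),
                     significant = integer(0), n_discovery = n_discovery,
                     n_total = n_discovery + n_replication, p1 = p1, p2 = p2))
  }
  n_mod_r <- round(prop_modern * n_replication)
  repl <- simulate_cohort(arch, n_replication - n_mod_r, n_mod_r,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, "replication"))
  # pooled regression on the union of the two samples, survivor SNPs only
  G_pool <- rbind(disc$genotypes[, surv, drop = FALSE],
                  repl$genotypes[, surv, drop = FALSE])
  y_pool <- c(disc$individuals$phenotype, repl$individuals$phenotype)
  s2 <- snp_scan(G_pool, y_pool)
  out <- tibble::tibble(
    snp = surv,
    p_discovery = s1$p_value[surv],
    estimate_pooled = s2$estimate,
    std_error_pooled = s2$std_error,
    p_pooled = s2$p_value,
    significant = s2$p_value < p2
  )
  structure(out, class = c("two_stage_result", class(out)),
            significant = surv[out$significant],
            n_discovery = n_discovery,
            n_total = n_discovery + n_replication, p1 = p1, p2 = p2)
}

# Two-group (environment 0/1) closed form of the 4-parameter interaction
# model y ~ 1 + x + env + x:env. The model saturates the two groups, so the
# fit equals separate per-group simple regressions with a pooled residual
# variance on n - 4 degrees of freedom, and the interaction coefficient is
# the modern-minus-ancestral slope difference.
interaction_from_group_sums <- function(gs, n0, n1, sy0, sy20, sy1, sy21) {
  n <- n0 + n1
  Sxx0 <- gs[, 2] - gs[, 1]^2 / n0
  Sxy0 <- gs[, 3] - gs[, 1] * sy0 / n0
  Sxx1 <- gs[, 5] - gs[, 4]^2 / n1
  Sxy1 <- gs[, 6] - gs[, 4] * sy1 / n1
  Syy0 <- sy20 - sy0^2 / n0
  Syy1 <- sy21 - sy1^2 / n1
  mono <- Sxx0 <= 0 | Sxx1 <= 0
  Sxx0s <- ifelse(mono, 1, Sxx0)
  Sxx1s <- ifelse(mono, 1, Sxx1)
  b0 <- Sxy0 / Sxx0s
  b1 <- Sxy1 / Sxx1s
  ss <- pmax(Syy0 - b0 * Sxy0, 0) + pmax(Syy1 - b1 * Sxy1, 0)
  df <- n - 4
  sigma2 <- ss / df
  est <- b1 - b0
  se <- sqrt(sigma2 * (1 / Sxx0s + 1 / Sxx1s))
  tt <- est / se
  p <- 2 * pt(-abs(tt), df)
  est[mono] <- 0
  se[mono] <- NA_real_
  tt[mono] <- NA_real_
  p[mono] <- 1
  list(estimate = est, std_error = se, statistic = tt, p_value = p,
       monomorphic = mono, slope_ancestral = b0, slope_modern = b1)
}

#' Per-SNP gene-by-environment interaction scan
#'
#' For each SNP in `snp_set`, fits
#' `y ~ 1 + dosage + env + dosage:env` on a mixed cohort and reports the
#' interaction coefficient, its standard error and two-sided p-value
#' (t reference on n - 4 df). SNPs monomorphic in either environment are
#' flagged with p = 1.
#'
#' @param cohort A mixed-environment `cohort`.
#' @param snp_set 1-based indices of SNPs to test (non-empty).
#' @param p_threshold Genome-wide significance level used for the hit count
#'   attribute (default 5e-8).
#' @return A tibble of class `gxe_result`: `snp`, `estimate` (interaction
#'   coefficient), `std_error`, `statistic`, `p_value`, `monomorphic`,
#'   `significant`; attributes `n`, `n_hits`.
#' @export
gxe_scan <- function(cohort, snp_set, p_threshold = 5e-8) {
  stopifnot(inherits(cohort, "cohort"), length(snp_set) > 0)
  env <- cohort$individuals$env
  if (length(unique(env)) < 2) {
    stop("GxE interaction is inestimable in a single-environment cohort")
  }
  y <- cohort$individuals$phenotype
  gs <- cpp_group_scan_sums(cohort$genotypes, y, env, as.integer(snp_set))
  n0 <- sum(env == 0L)
  n1 <- sum(env == 1L)
  fit <- interaction_from_group_sums(gs, n0, n1,
                                     sum(y[env == 0L]), sum(y[env == 0L]^2),
                                     sum(y[env == 1L]), sum(y[env == 1L]^2))
  out <- tibble::tibble(
    snp = as.integer(snp_set),
    estimate = fit$estimate, std_error = fit$std_error,
    statistic = fit$statistic, p_value = fit$p_value,
    monomorphic = fit$monomorphic,
    significant = fit$p_value < p_threshold
  )
  structure(out, class = c("gxe_result", class(out)),
            n = n0 + n1, n_hits = sum(out$significant))
}

#' Unweighted genetic risk score
#'
#' Per-individual count of trait-increasing alleles over a SNP set, without
#' effect-size weighting. All effect alleles are trait-increasing by
#' construction, so the score is simply the dosage sum; its range is
#' `[0, 2 * length(snp_set)]`.
#'
#' @param genotypes Dosage matrix or `cohort`.
#' @param snp_set 1-based SNP indices (non-empty).
#' @return Integer vector of scores, one per individual.
#' @export
grs <- function(genotypes, snp_set) {
  if (inherits(genotypes, "cohort")) {
    genotypes <- genotypes$genotypes
  }
  stopifnot(length(snp_set) > 0)
  cpp_grs(genotypes, as.integer(snp_set))
}

#' Genetic-risk-score-by-environment interaction test
#'
#' Fits `y ~ 1 + GRS + env + GRS:env` on a mixed cohort, with the unweighted
#' [grs()] over `snp_set` as the genetic predictor — one test per simulated
#' cohort. An empty `snp_set` yields a defined-missing (all-`NA`) result
#' rather than an error, mirroring grid cells where no SNPs were discovered.
#'
#' @param cohort A mixed-environment `cohort`.
#' @param snp_set 1-based SNP indices (may be empty).
#' @return One-row tibble of class `grsxe_result`: `n_snps`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
grsxe_test <- function(cohort, snp_set) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(snp_set) == 0) {
    out <- tibble::tibble(n_snps = 0L, estimate = NA_real_,
                          std_error = NA_real_, statistic = NA_real_,
                          p_value = NA_real_)
    return(structure(out, class = c("grsxe_result", class(out))))
  }
  env <- cohort$individuals$env
  if (length(unique(env)) < 2) {
    stop("GRSxE interaction is inestimable in a single-environment cohort")
  }
  score <- as.numeric(grs(cohort, snp_set))
  y <- cohort$individuals$phenotype
  n0 <- sum(env == 0L)
  n1 <- sum(env == 1L)
  x0 <- score[env == 0L]
  x1 <- score[env == 1L]
  y0 <- y[env == 0L]
  y1 <- y[env == 1L]
  gs <- matrix(c(sum(x0), sum(x0^2), sum(x0 * y0),
                 sum(x1), sum(x1^2), sum(x1 * y1)), nrow = 1)
  fit <- interaction_from_group_sums(gs, n0, n1, sum(y0), sum(y0^2),
                                     sum(y1), sum(y1^2))
  out <- tibble::tibble(
    n_snps = length(snp_set),
    estimate = fit$estimate, std_error = fit$std_error,
    statistic = fit$statistic, p_value = fit$p_value
  )
  structure(out, class = c("grsxe_result", class(out)))
}

#' GWAS power degradation under increasing perturbation
#'
#' Demonstrates how a focal variant's association signal decays in a mixed
#' cohort as the modern environment perturbs effect sizes more strongly. For
#' each fold, a cohort of `n` individuals (half ancestral, half modern) is
#' simulated in which `background_fraction` of the background SNPs and the
#' focal SNP itself are perturbed at that fold; the focal SNP is then scanned
#' (environment-blind simple regression), over `replicates` replicates.
#'
#' @param gv_focal Variance fraction explained by the focal SNP (ancestral).
#' @param n Cohort size (split 50/50 between environments when fold > 1;
#'   all-ancestral at fold 1, matching the unperturbed reference GWAS).
#' @param background_fraction Fraction of background SNPs perturbed.
#' @param folds Fold factors to profile, e.g. `c(1, 1.25, 1.5, 1.75, 2)`.
#' @param replicates Replicates per fold.
#' @param n_snps Number of background SNPs (+1 focal, stored first).
#' @param seed Optional master seed.
#' @param ... Further arguments to [trait_architecture()].
#' @return Tibble: `fold`, `replicate`, `estimate`, `p_value`.
#' @export
power_degradation_demo <- function(gv_focal = 0.003, n = 20000,
                                   background_fraction = 0.10,
                                   folds = c(1, 1.25, 1.5, 1.75, 2),
                                   replicates = 10, n_snps = 2500,
                                   seed = NULL, ...) {
  stopifnot(gv_focal >= 0, gv_focal < 1)
  purrr::map_dfr(folds, function(f) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      aseed <- if (is.null(seed)) NULL else derive_seed(seed, "arch", f, r)
      arch <- trait_architecture(n_snps = n_snps, model = 1,
                                 fraction = background_fraction,
                                 fold = f, seed = aseed, ...)
      # focal variant: fixed gv, perturbed along with the background
      arch$gv[1] <- gv_focal
      arch$beta_anc[1] <- effect_size(gv_focal, arch$eaf[1])
      arch$perturbed[1] <- TRUE
      arch$beta_mod <- perturb(arch$beta_anc, arch$perturbed, f)
      cseed <- if (is.null(seed)) NULL else derive_seed(seed, "cohort", f, r)
      coh <- if (f == 1) {
        simulate_cohort(arch, n, 0, seed = cseed)
      } else {
        simulate_cohort(arch, n %/% 2, n - n %/% 2, seed = cseed)
      }
      sc <- snp_scan(coh$genotypes, coh$individuals$phenotype, snp_set = 1L)
      tibble::tibble(fold = f, replicate = r,
                     estimate = sc$estimate, p_value = sc$p_value)
    })
  })
}
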