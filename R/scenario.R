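#' Summarize a significant SNP set against the perturbation mask
#'
#' @param significant Integer indices of significant SNPs.
#' @param perturbed Logical perturbation mask over all SNPs.
#' @return One-row tibble: `n_hits`, `n_perturbed_hits`,
#'   `pct_perturbed_hits` (percentage; `NA` when there are no hits).
#' @examples
#' summarize_hits(c(1, 3), c(TRUE, FALSE, TRUE, FALSE))
#' @export
summarize_hits <- function(significant, perturbed) {
  n <- length(significant)
  np <- sum(perturbed[significant])
  tibble::tibble(
    n_hits = n,
    n_perturbed_hits = np,
    pct_perturbed_hits = if (n == 0) NA_real_ else 100 * np / n
  )
}

#' Run one full simulation replicate under scenario A, B or C
#'
#' One replicate draws a fresh architecture (new EAFs, effect sizes and —
#' under model 1 — perturbation mask), selects the SNPs to test for GxE, and
#' evaluates per-SNP GxE and GRSxE interactions on a fresh mixed cohort:
#'
#' * **Scenario A** — the perturbed SNPs are taken as known and forwarded
#'   directly to the interaction tests (no GWAS; an upper bound).
#' * **Scenario B** — two-stage GWAS discovery on all-modern samples; the
#'   genome-wide significant set is forwarded.
#' * **Scenario C** — discovery on a 50/50 ancestral/modern mixture, with
#'   environment absent from the GWAS model; the significant set is
#'   forwarded.
#'
#' The GWAS cohorts and the GxE cohort share the architecture draw but are
#' disjoint samples. The GxE cohort is always a 50/50 mixture. When the
#' tested set is empty (nothing discovered, or fraction 0 under scenario A)
#' the interaction fields are defined-missing `NA`s and the record is still
#' complete.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param model Perturbation-selection model, 1 or 2.
#' @param fraction Proportion of SNPs perturbed.
#' @param fold Effect-size multiplier of the modern environment.
#' @param sizes Cohort-size bundle, see [replicate_sizes()].
#' @param p1,p2 Two-stage thresholds (1e-5, 5e-8).
#' @param seed Master seed of the replicate.
#' @param ... Further arguments to [trait_architecture()].
#' @return One-row tibble (the replicate record): scenario, model, fraction,
#'   fold, seed, `h2_ancestral`, `h2_modern`, `mean_shift_sd`, `n_tested`,
#'   `n_gwas_hits`, `n_perturbed_hits`, `pct_perturbed_hits`, `n_gxe_hits`,
#'   `grsxe_beta`, `grsxe_p`.
#' @examples
#' run_replicate("A", model = 1, fraction = 0.1, fold = 1.5,
#'               sizes = replicate_sizes(n_gxe_ancestral = 1000,
#'                                       n_gxe_modern = 1000),
#'               seed = 1, n_snps = 200, n_head = 56, head_total = 0.0128)
#' @export
run_replicate <- function(scenario = c("A", "B", "C"), model = 1,
                          fraction, fold, sizes = replicate_sizes(),
                          p1 = 1e-5, p2 = 5e-8, seed = NULL, ...) {
  scenario <- match.arg(scenario)
  arch <- trait_architecture(model = model, fraction = fraction, fold = fold,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, "arch"),
                             ...)
  gwas <- NULL
  if (scenario == "A") {
    tested <- which(arch$perturbed)
    n_gwas_hits <- NA_integer_
    n_pert_hits <- NA_integer_
    pct_pert <- NA_real_
  } else {
    prop_modern <- if (scenario == "B") 1 else 0.5
    gwas <- two_stage_discovery(
      arch, prop_modern,
      n_discovery = sizes$n_discovery, n_replication = sizes$n_replication,
      p1 = p1, p2 = p2,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "gwas")
    )
    tested <- attr(gwas, "significant")
    hs <- summarize_hits(tested, arch$perturbed)
    n_gwas_hits <- hs$n_hits
    n_pert_hits <- hs$n_perturbed_hits
    pct_pert <- hs$pct_perturbed_hits
  }
  gxe_cohort <- simulate_cohort(
    arch, sizes$n_gxe_ancestral, sizes$n_gxe_modern,
    seed = if (is.null(seed)) NULL else derive_seed(seed, "gxe-cohort")
  )
  ind <- gxe_cohort$individuals
  h2_anc <- realized_heritability(ind[ind$env == 0L, ])
  h2_mod <- realized_heritability(ind[ind$env == 1L, ])
  if (length(tested) > 0) {
    gxe <- gxe_scan(gxe_cohort, tested, p_threshold = p2)
    n_gxe_hits <- attr(gxe, "n_hits")
    gx <- grsxe_test(gxe_cohort, tested)
    grsxe_beta <- gx$estimate
    grsxe_p <- gx$p_value
  } else {
    n_gxe_hits <- NA_integer_
    grsxe_beta <- NA_real_
    grsxe_p <- NA_real_
  }
  tibble::tibble(
    scenario = scenario, model = model, fraction = fraction, fold = fold,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    h2_ancestral = h2_anc, h2_modern = h2_mod,
    mean_shift_sd = mean_shift_sd(arch),
    n_tested = length(tested),
    n_gwas_hits = n_gwas_hits,
    n_perturbed_hits = n_pert_hits,
    pct_perturbed_hits = pct_pert,
    n_gxe_hits = n_gxe_hits,
    grsxe_beta = grsxe_beta,
    grsxe_p = grsxe_p
  )
}

#' Cohort-size bundle for a replicate
#'
#' Defaults are the study design sizes: 50,000-individual discovery GWAS,
#' 50,000 replication (pooled to 100,000), and a 20,000 + 20,000 mixed
#' cohort for the interaction tests. All are configurable for scaled-down
#' runs.
#'
#' @param n_discovery,n_replication GWAS stage sizes.
#' @param n_gxe_ancestral,n_gxe_modern Interaction-cohort arm sizes.
#' @return A named list.
#' @export
replicate_sizes <- function(n_discovery = 50000, n_replication = 50000,
                            n_gxe_ancestral = 20000, n_gxe_modern = 20000) {
  list(n_discovery = n_discovery, n_replication = n_replication,
       n_gxe_ancestral = n_gxe_ancestral, n_gxe_modern = n_gxe_modern)
}
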