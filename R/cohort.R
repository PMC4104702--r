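#' Simulate Hardy-Weinberg genotypes
#'
#' Dosages at SNP `i` are independent Binomial(2, `eaf[i]`) draws across
#' individuals, i.e. genotype frequencies (1-p)^2, 2p(1-p), p^2.
#'
#' @param eaf Vector of effect-allele frequencies in (0, 1).
#' @param n_individuals Number of individuals.
#' @param seed Optional seed for a dedicated stream.
#' @return Integer matrix (`n_individuals` x `length(eaf)`) of dosages in
#'   \{0, 1, 2\}.
#' @examples
#' G <- simulate_genotypes(c(0.4, 0.9), 1000, seed = 1)
#' colMeans(G) # ~ 2 * eaf
#' @export
simulate_genotypes <- function(eaf, n_individuals, seed = NULL) {
  stopifnot(n_individuals >= 1)
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("`eaf` must be strictly inside (0, 1)")
  }
  with_substream(seed, "genotypes",
                 cpp_sim_genotypes(as.integer(n_individuals), as.numeric(eaf)))
}

#' Simulate a cohort of individuals under an architecture
#'
#' Draws genotypes for `n_ancestral + n_modern` individuals, assigns
#' environments (0 = ancestral, 1 = modern) in random interleaved order,
#' computes additive genetic values with the environment-specific effect
#' sizes (`beta_anc` vs `beta_mod`), and adds a Normal(0, V_E) residual. The
#' residual stream is drawn once for the whole cohort, identically in both
#' environments, so ancestral/modern contrasts differ only through the
#' effect sizes.
#'
#' @param arch A [trait_architecture()].
#' @param n_ancestral,n_modern Individuals per environment.
#' @param seed Optional master seed (substreams: `env-order`, `genotypes`,
#'   `residuals`).
#' @return A `cohort` object: list with `genotypes` (integer dosage matrix)
#'   and `individuals` (tibble: `id`, `env`, `genetic_value`, `phenotype`),
#'   plus the generating architecture's `ve`.
#' @examples
#' arch <- trait_architecture(fraction = 0.2, fold = 1.2, seed = 1)
#' coh <- simulate_cohort(arch, 500, 500, seed = 2)
#' glance(coh)
#' @export
simulate_cohort <- function(arch, n_ancestral, n_modern, seed = NULL) {
  n <- n_ancestral + n_modern
  stopifnot(n >= 1)
  env <- c(rep(0L, n_ancestral), rep(1L, n_modern))
  if (n_ancestral > 0 && n_modern > 0) {
    env <- with_substream(seed, "env-order", sample(env))
  }
  G <- simulate_genotypes(arch$eaf, n, seed = seed)
  gval <- numeric(n)
  anc <- which(env == 0L)
  mod <- which(env == 1L)
  if (length(anc) > 0) {
    gval[anc] <- cpp_genetic_value(G, arch$beta_anc, anc)
  }
  if (length(mod) > 0) {
    gval[mod] <- cpp_genetic_value(G, arch$beta_mod, mod)
  }
  ve <- attr(arch, "ve")
  resid <- with_substream(seed, "residuals", rnorm(n, 0, sqrt(ve)))
  structure(
    list(
      genotypes = G,
      individuals = tibble::tibble(
        id = paste0("ind", seq_len(n)),
        env = env,
        genetic_value = gval,
        phenotype = gval + resid
      ),
      ve = ve
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d individuals (%d ancestral, %d modern) x %d SNPs\n",
    nrow(x$genotypes), sum(x$individuals$env == 0L),
    sum(x$individuals$env == 1L), ncol(x$genotypes)
  ))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.cohort <- function(x, ...) {
  x$individuals
}

#' @export
glance.cohort <- function(x, ...) {
  ind <- x$individuals
  tibble::tibble(
    n = nrow(ind),
    n_ancestral = sum(ind$env == 0L),
    n_modern = sum(ind$env == 1L),
    var_phenotype = var(ind$phenotype),
    var_genetic = var(ind$genetic_value),
    h2 = realized_heritability(x)
  )
}

#' Realized heritability of a cohort
#'
#' Ratio of the sample variance of genetic values to the sample variance of
#' phenotypes. For mixed cohorts the between-environment shift in mean
#' genetic value is part of var(genetic value), so the ratio reflects the
#' cohort actually analysed, not a single environment.
#'
#' @param cohort A `cohort`, or its `individuals` tibble (columns
#'   `genetic_value`, `phenotype`).
#' @return Heritability in `[0, 1]` (sampling noise aside).
#' @export
realized_heritability <- function(cohort) {
  ind <- if (inherits(cohort, "cohort")) cohort$individuals else cohort
  stopifnot(nrow(ind) >= 2)
  vp <- var(ind$phenotype)
  if (vp == 0) {
    stop("zero phenotype variance: heritability undefined")
  }
  var(ind$genetic_value) / vp
}

#' Expected modern-ancestral phenotype shift, in ancestral SD units
#'
#' Closed form for the mean phenotype difference induced by the perturbation:
#' each perturbed SNP contributes `2 * eaf * (fold - 1) * beta_anc` to the
#' mean (mean dosage is `2 * eaf`), and the ancestral phenotypic SD is
#' `sqrt(V_G + V_E)` (= 1 at the defaults).
#'
#' @param arch A [trait_architecture()].
#' @return Standardized expected shift (scalar).
#' @examples
#' arch <- trait_architecture(fraction = 0.2, fold = 1.2, seed = 1)
#' mean_shift_sd(arch)
#' @export
mean_shift_sd <- function(arch) {
  fold <- attr(arch, "fold")
  sd_anc <- sqrt(attr(arch, "target_vg") + attr(arch, "ve"))
  sum(2 * arch$eaf[arch$perturbed] * (fold - 1) * arch$beta_anc[arch$perturbed]) /
    sd_anc
}

#' Binned phenotype distributions across cohorts
#'
#' Histograms of phenotype per environment and pooled, on a common
#' Freedman-Diaconis grid over the pooled range.
#'
#' @param ... One or more `cohort` objects (pooled together).
#' @param binwidth Optional fixed bin width; Freedman-Diaconis when `NULL`.
#' @return Tibble with columns `group` (`"ancestral"`, `"modern"`,
#'   `"pooled"`), `bin_mid`, `bin_lo`, `bin_hi`, `count`.
#' @export
phenotype_histogram <- function(..., binwidth = NULL) {
  inds <- dplyr::bind_rows(lapply(list(...), function(x) x$individuals))
  y <- inds$phenotype
  if (is.null(binwidth)) {
    binwidth <- 2 * stats::IQR(y) / length(y)^(1 / 3)
  }
  breaks <- seq(floor(min(y) / binwidth) * binwidth,
                max(y) + binwidth, by = binwidth)
  cut_tab <- function(v, group) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    tibble::tibble(group = group, bin_mid = h$mids,
                   bin_lo = utils::head(breaks, -1),
                   bin_hi = breaks[-1], count = h$counts)
  }
  dplyr::bind_rows(
    if (any(inds$env == 0L)) cut_tab(y[inds$env == 0L], "ancestral"),
    if (any(inds$env == 1L)) cut_tab(y[inds$env == 1L], "modern"),
    cut_tab(y, "pooled")
  )
}

#' Plot phenotype distributions
#'
#' @param hist_tbl Output of [phenotype_histogram()].
#' @return A ggplot object.
#' @export
plot_phenotype_histogram <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "phenotype", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}
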