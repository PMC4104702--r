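#' Assign per-SNP variance-explained fractions
#'
#' Builds the variance-explained (gv) spectrum of the simulated trait: a
#' "head" of `n_head` variants whose contributions range from `gv_min` to
#' `gv_max` and jointly account for `head_total` of the phenotypic variance,
#' plus a "tail" of `n_snps - n_head` variants pinned at `gv_min`. The head
#' follows the parametric rank curve
#' `gv(r) = gv_min + (gv_max - gv_min) * (r / n_head)^alpha`, with `alpha`
#' solved numerically so the head sums to `head_total`; a user-supplied head
#' table can be substituted via `head_gv`. Finally all values are rescaled by
#' a common factor so the grand sum equals `target_vg` (skipped when
#' `target_vg = NULL`).
#'
#' @param n_snps Total number of causal SNPs.
#' @param n_head Number of head variants (0 for a flat spectrum).
#' @param gv_min,gv_max Bounds of the per-SNP variance fraction (of V_P = 1).
#' @param head_total Variance fraction jointly explained by the head before
#'   rescaling.
#' @param target_vg Total genetic variance after rescaling, or `NULL` to skip
#'   the rescale.
#' @param alpha Optional fixed exponent of the rank curve; solved from
#'   `head_total` when `NULL`.
#' @param head_gv Optional explicit vector of `n_head` head values in
#'   `[gv_min, gv_max]`, replacing the parametric curve.
#' @return Numeric vector of `n_snps` variance fractions, head first
#'   (ascending rank), tail after.
#' @examples
#' gv <- assign_variance_fractions(2500, 701, 0.00012, 0.0028, 0.16, 0.36)
#' sum(gv)
#' @export
assign_variance_fractions <- function(n_snps = 2500, n_head = 701,
                                      gv_min = 0.00012, gv_max = 0.0028,
                                      head_total = 0.16, target_vg = 0.36,
                                      alpha = NULL, head_gv = NULL) {
  stopifnot(n_head <= n_snps, gv_min > 0, gv_min <= gv_max)
  if (n_head > 0 && head_total < n_head * gv_min - 1e-12) {
    stop("`head_total` is below n_head * gv_min: head distribution infeasible")
  }
  if (!is.null(head_gv)) {
    stopifnot(length(head_gv) == n_head,
              all(head_gv >= gv_min - 1e-12), all(head_gv <= gv_max + 1e-12))
    head <- as.numeric(head_gv)
  } else if (n_head == 0) {
    head <- numeric(0)
  } else {
    r <- seq_len(n_head) / n_head
    if (is.null(alpha)) {
      if (gv_max == gv_min) {
        alpha <- 1 # rank curve is flat; exponent irrelevant
      } else {
        # achievable head totals: the top rank always sits at gv_max, the
        # rest interpolate down to gv_min as alpha grows
        lo <- (n_head - 1) * gv_min + gv_max
        hi <- n_head * gv_max
        if (head_total < lo - 1e-12 || head_total > hi + 1e-12) {
          stop(sprintf(
            "`head_total` must lie in [%.3g, %.3g] for these gv bounds (infeasible)",
            lo, hi
          ))
        }
        f <- function(a) n_head * gv_min + (gv_max - gv_min) * sum(r^a) - head_total
        alpha <- stats::uniroot(f, c(1e-6, 1e3), tol = 1e-12,
                                extendInt = "downX")$root
      }
    }
    head <- gv_min + (gv_max - gv_min) * r^alpha
  }
  gv <- c(head, rep(gv_min, n_snps - n_head))
  if (!is.null(target_vg)) {
    gv <- gv * target_vg / sum(gv)
  }
  gv
}

#' Draw effect-allele frequencies
#'
#' EAFs of the causal variants are uniform on (`low`, `high`); the default
#' 0.05-0.95 window mimics the common-variant ascertainment of GWAS arrays.
#'
#' @param n_snps Number of SNPs.
#' @param low,high Frequency bounds, `0 < low < high < 1`.
#' @param seed Optional seed for a dedicated reproducible stream.
#' @return Numeric vector of frequencies in (`low`, `high`).
#' @examples
#' range(draw_eaf(1000, seed = 1))
#' @export
draw_eaf <- function(n_snps, low = 0.05, high = 0.95, seed = NULL) {
  stopifnot(low > 0, high < 1, low < high)
  with_substream(seed, "eaf", runif(n_snps, low, high))
}

#' Per-allele effect size from variance explained
#'
#' Inverts the single-SNP variance decomposition
#' `gv = 2 * beta^2 * EAF * (1 - EAF)` for the additive per-allele effect:
#' `beta = sqrt(gv / (2 * EAF * (1 - EAF)))`. All effects are non-negative,
#' i.e. the effect allele is always the trait-increasing allele.
#'
#' @param gv Variance fraction(s) explained by the SNP (on V_P = 1).
#' @param eaf Effect-allele frequency(ies), strictly inside (0, 1).
#' @return Effect size(s) in phenotype units per allele copy.
#' @examples
#' effect_size(0.0028, 0.4) # ~0.076 per allele
#' @export
effect_size <- function(gv, eaf) {
  stopifnot(all(gv >= 0))
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("`eaf` must be strictly inside (0, 1)")
  }
  sqrt(gv / (2 * eaf * (1 - eaf)))
}

#' Select the SNPs perturbed by the modern environment
#'
#' Model 1 picks `round(fraction * n)` SNPs uniformly at random; model 2
#' picks the SNPs with the largest variance explained (ties broken by SNP
#' index, ascending, for determinism).
#'
#' @param gv Vector of per-SNP variance fractions.
#' @param model 1 (random) or 2 (largest variance explained).
#' @param fraction Proportion of SNPs perturbed, in `[0, 1]`.
#' @param seed Optional seed for the model-1 stream (model 2 is
#'   deterministic).
#' @return Logical mask over SNPs.
#' @examples
#' gv <- assign_variance_fractions()
#' sum(select_perturbed(gv, model = 2, fraction = 0.1))
#' @export
select_perturbed <- function(gv, model = 1, fraction, seed = NULL) {
  stopifnot(model %in% c(1, 2), fraction >= 0, fraction <= 1)
  n <- length(gv)
  n_sel <- floor(fraction * n + 0.5) # half-up; integer on the default grid
  mask <- rep(FALSE, n)
  if (n_sel == 0) {
    return(mask)
  }
  idx <- if (model == 2) {
    order(-gv, seq_len(n))[seq_len(n_sel)]
  } else {
    with_substream(seed, "mask", sample.int(n, n_sel))
  }
  mask[idx] <- TRUE
  mask
}

#' Apply the multiplicative effect-size perturbation
#'
#' The modern environment multiplies the effect size of each perturbed SNP by
#' a constant `fold`; unperturbed SNPs keep their ancestral effect.
#'
#' @param beta_anc Ancestral effect sizes.
#' @param perturbed Logical mask of perturbed SNPs.
#' @param fold Multiplicative factor, `> 0`.
#' @return Modern effect sizes.
#' @examples
#' perturb(0.06, TRUE, 1.5) # 0.09
#' @export
perturb <- function(beta_anc, perturbed, fold) {
  stopifnot(fold > 0, length(perturbed) == length(beta_anc))
  ifelse(perturbed, fold * beta_anc, beta_anc)
}

#' Construct the genetic architecture of the simulated trait
#'
#' One architecture draw fixes, for each of `n_snps` causal SNPs, its variance
#' fraction, effect-allele frequency, ancestral and modern per-allele effect
#' sizes, and whether the modern environment perturbs it. The gv spectrum
#' itself (head + tail, see [assign_variance_fractions()]) is fixed; EAFs,
#' head positions and (under model 1) the perturbation mask are redrawn from
#' the seed, so repeated calls with different seeds emulate independent
#' simulations of the same trait.
#'
#' @param n_snps,n_head,gv_min,gv_max,head_total,target_vg,alpha,head_gv
#'   Passed to [assign_variance_fractions()].
#' @param model,fraction Passed to [select_perturbed()].
#' @param fold Effect-size multiplier of the modern environment.
#' @param ve Residual (environmental) variance V_E.
#' @param seed Optional master seed; substreams `"eaf"`, `"head-positions"`
#'   and `"mask"` are derived from it.
#' @return A tibble of class `trait_architecture` with columns `snp_id`,
#'   `gv`, `eaf`, `beta_anc`, `beta_mod`, `perturbed` and attributes
#'   `fold`, `ve`, `model`, `fraction`, `target_vg`.
#' @examples
#' arch <- trait_architecture(fraction = 0.1, fold = 1.3, seed = 1)
#' arch
#' sum(arch$gv)
#' @export
trait_architecture <- function(n_snps = 2500, n_head = 701,
                               gv_min = 0.00012, gv_max = 0.0028,
                               head_total = 0.16, target_vg = 0.36,
                               ve = 0.64, model = 1, fraction = 0, fold = 1,
                               alpha = NULL, head_gv = NULL, seed = NULL) {
  gv <- assign_variance_fractions(n_snps, n_head, gv_min, gv_max,
                                  head_total, target_vg, alpha, head_gv)
  # scatter the head across random SNP positions
  pos <- with_substream(seed, "head-positions", sample.int(n_snps, n_snps))
  gv <- gv[order(pos)]
  eaf <- draw_eaf(n_snps, seed = seed)
  beta_anc <- effect_size(gv, eaf)
  perturbed <- select_perturbed(gv, model, fraction, seed = seed)
  beta_mod <- perturb(beta_anc, perturbed, fold)
  out <- tibble::tibble(
    snp_id = paste0("snp", seq_len(n_snps)),
    gv = gv, eaf = eaf, beta_anc = beta_anc, beta_mod = beta_mod,
    perturbed = perturbed
  )
  structure(out,
            class = c("trait_architecture", class(out)),
            fold = fold, ve = ve, model = model, fraction = fraction,
            target_vg = if (is.null(target_vg)) sum(gv) else target_vg)
}

#' @export
glance.trait_architecture <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    vg_ancestral = sum(x$gv),
    vg_modern = sum(x$gv[!x$perturbed]) +
      attr(x, "fold")^2 * sum(x$gv[x$perturbed]),
    ve = attr(x, "ve"),
    model = attr(x, "model"),
    fraction = attr(x, "fraction"),
    fold = attr(x, "fold"),
    n_perturbed = sum(x$perturbed),
    mean_shift_sd = mean_shift_sd(x)
  )
}

#' Write / read a trait architecture as TSV
#'
#' The table carries the per-SNP columns; `fold`, `ve`, `model` and
#' `fraction` travel in `# key: value` header comments so a round trip
#' restores the full object.
#'
#' @param arch A `trait_architecture`.
#' @param path File path.
#' @return `write_architecture()` returns `arch` invisibly;
#'   `read_architecture()` returns a `trait_architecture`.
#' @export
write_architecture <- function(arch, path) {
  hdr <- sprintf("# %s: %.17g", c("fold", "ve", "model", "fraction", "target_vg"),
                 c(attr(arch, "fold"), attr(arch, "ve"), attr(arch, "model"),
                   attr(arch, "fraction"), attr(arch, "target_vg")))
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(arch), path, append = TRUE,
                   col_names = TRUE)
  invisible(arch)
}

#' @rdname write_architecture
#' @param path File path.
#' @export
read_architecture <- function(path) {
  hdr <- grep("^# ", readLines(path, n = 10L), value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), ": "))
  meta <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  structure(tibble::as_tibble(tab),
            class = c("trait_architecture", class(tibble::tibble())),
            fold = meta[["fold"]], ve = meta[["ve"]], model = meta[["model"]],
            fraction = meta[["fraction"]], target_vg = meta[["target_vg"]])
}
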