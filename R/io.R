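#' Export a cohort as VCF + phenotype TSV
#'
#' Writes genotypes as a minimal VCF (GT field only, one record per SNP,
#' synthetic chromosome/position) and a companion TSV with `individual_id`,
#' `env`, `phenotype`. [read_cohort()] restores the pair (genotype parsing
#' via the vcfR package).
#'
#' @param cohort A `cohort`.
#' @param vcf_path,pheno_path Output paths.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, vcf_path, pheno_path) {
  G <- cohort$genotypes
  ind <- cohort$individuals
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gxesim",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind$id), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(G))) {
    writeLines(paste(c("1", j, paste0("snp", j), "A", "T", ".", ".", ".",
                       "GT", gt_code[G[, j] + 1L]), collapse = "\t"), con)
  }
  readr::write_tsv(
    tibble::tibble(individual_id = ind$id, env = ind$env,
                   phenotype = ind$phenotype),
    pheno_path
  )
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(vcf_path, pheno_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package `vcfR` is required to read cohort VCFs")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v) # SNPs x individuals, "0/0" etc.
  G <- t(matrix((gt == "0/1") + 2L * (gt == "1/1"),
                nrow = nrow(gt), dimnames = dimnames(gt)))
  pheno <- readr::read_tsv(pheno_path, show_col_types = FALSE)
  stopifnot(identical(rownames(G), pheno$individual_id))
  structure(
    list(genotypes = unname(G),
         individuals = tibble::tibble(id = pheno$individual_id,
                                      env = as.integer(pheno$env),
                                      genetic_value = NA_real_,
                                      phenotype = pheno$phenotype),
         ve = NA_real_),
    class = "cohort"
  )
}

#' Write association / interaction results as TSV
#'
#' @param x A `scan_result`, `two_stage_result`, `gxe_result` or a tibble of
#'   replicate records.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' Read a run configuration file
#'
#' Plain-text `key: value` (YAML subset) configuration covering the grid
#' bounds, cohort sizes, thresholds, variance components and seed. Any key
#' may be omitted; `defaults` fills the gaps. Recognised keys include
#' `fractions`, `folds` (either explicit lists or `{from, to, by}` maps),
#' `replicates`, `scenario`, `model`, `seed`, `p1`, `p2`, `n_discovery`,
#' `n_replication`, `n_gxe_ancestral`, `n_gxe_modern`, `n_snps`, `n_head`,
#' `gv_min`, `gv_max`, `head_total`, `target_vg`, `ve`.
#'
#' @param path Config file path.
#' @param defaults Named list of fallback values.
#' @return A [grid_spec()].
#' @export
read_config <- function(path, defaults = list()) {
  cfg <- utils::modifyList(defaults, yaml::read_yaml(path))
  axis <- function(x, default) {
    if (is.null(x)) {
      default
    } else if (is.list(x)) {
      seq(x$from, x$to, by = x$by)
    } else {
      as.numeric(x)
    }
  }
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  arch_keys <- c("n_snps", "n_head", "gv_min", "gv_max", "head_total",
                 "target_vg", "ve")
  grid_spec(
    fractions = axis(cfg$fractions, seq(0.01, 0.20, by = 0.01)),
    folds = axis(cfg$folds, seq(1.05, 2.00, by = 0.05)),
    replicates = pick("replicates", 5),
    scenario = pick("scenario", "A"),
    model = pick("model", 1),
    seed = pick("seed", 1),
    sizes = replicate_sizes(
      n_discovery = pick("n_discovery", 50000),
      n_replication = pick("n_replication", 50000),
      n_gxe_ancestral = pick("n_gxe_ancestral", 20000),
      n_gxe_modern = pick("n_gxe_modern", 20000)
    ),
    p1 = pick("p1", 1e-5),
    p2 = pick("p2", 5e-8),
    arch_args = cfg[intersect(arch_keys, names(cfg))]
  )
}
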