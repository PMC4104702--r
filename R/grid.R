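#' Specify a parameter-grid run
#'
#' The default grid is the full study design: perturbed fractions 1-20% in
#' 1% steps by fold factors 1.05-2.00 in 0.05 steps (400 cells), five
#' replicates per cell (2000 simulations) for one (scenario, model) pair.
#'
#' @param fractions,folds Grid axes.
#' @param replicates Replicates per cell.
#' @param scenario,model Scenario (`"A"`, `"B"`, `"C"`) and perturbation
#'   model (1, 2).
#' @param seed Base seed; every replicate derives its own seed from
#'   (seed, scenario, model, fraction, fold, replicate).
#' @param sizes Cohort sizes, see [replicate_sizes()].
#' @param p1,p2 Two-stage thresholds.
#' @param arch_args Named list of extra [trait_architecture()] arguments
#'   (e.g. a scaled-down `n_snps`).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(fractions = seq(0.01, 0.20, by = 0.01),
                      folds = seq(1.05, 2.00, by = 0.05),
                      replicates = 5, scenario = "A", model = 1,
                      seed = 1, sizes = replicate_sizes(),
                      p1 = 1e-5, p2 = 5e-8, arch_args = list()) {
  stopifnot(all(fractions > 0), all(folds > 0), replicates >= 1)
  structure(list(fractions = fractions, folds = folds,
                 replicates = replicates, scenario = scenario, model = model,
                 seed = seed, sizes = sizes, p1 = p1, p2 = p2,
                 arch_args = arch_args),
            class = "grid_spec")
}

#' Run a parameter grid
#'
#' Executes [run_replicate()] for every (fraction, fold, replicate) cell of
#' the spec. Replicate seeds are derived deterministically, so replicates are
#' independent and any execution order (or a resumed run) yields identical
#' records. When `out_dir` is given, one TSV per cell is written and cells
#' already on disk are skipped on re-runs. A replicate that errors is logged
#' and recorded as a failed row (`status = "error"`); it never aborts the
#' grid.
#'
#' @param spec A [grid_spec()].
#' @param out_dir Optional directory for resumable per-cell TSVs.
#' @param verbose Print one progress line per replicate.
#' @return Tibble of replicate records (one row per cell x replicate), with
#'   a `status` column (`"ok"` or `"error"`).
#' @export
run_grid <- function(spec, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cells <- tidyr::expand_grid(fraction = spec$fractions, fold = spec$folds)
  records <- purrr::pmap_dfr(cells, function(fraction, fold) {
    cell_file <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("cell_f%.2f_x%.2f.tsv", fraction, fold))
    }
    if (!is.null(cell_file) && file.exists(cell_file)) {
      return(readr::read_tsv(cell_file, show_col_types = FALSE))
    }
    recs <- purrr::map_dfr(seq_len(spec$replicates), function(rep) {
      rseed <- derive_seed(spec$seed, spec$scenario, spec$model,
                           fraction, fold, rep)
      t0 <- proc.time()[["elapsed"]]
      rec <- tryCatch(
        dplyr::mutate(
          do.call(run_replicate,
                  c(list(scenario = spec$scenario, model = spec$model,
                         fraction = fraction, fold = fold,
                         sizes = spec$sizes, p1 = spec$p1, p2 = spec$p2,
                         seed = rseed),
                    spec$arch_args)),
          replicate = rep, status = "ok"
        ),
        error = function(e) {
          tibble::tibble(scenario = spec$scenario, model = spec$model,
                         fraction = fraction, fold = fold,
                         seed = rseed, replicate = rep,
                         status = paste("error:", conditionMessage(e)))
        }
      )
      if (verbose) {
        message(sprintf(
          "grid %s m%d f=%.2f x%.2f rep %d seed %d [%.1fs] hits=%s gxe=%s",
          spec$scenario, spec$model, fraction, fold, rep, rseed,
          proc.time()[["elapsed"]] - t0,
          if ("n_gwas_hits" %in% names(rec)) rec$n_gwas_hits else NA,
          if ("n_gxe_hits" %in% names(rec)) rec$n_gxe_hits else NA
        ))
      }
      rec
    })
    if (!is.null(cell_file)) {
      readr::write_tsv(recs, cell_file)
    }
    recs
  })
  records
}

#' Aggregate replicate records into one row per grid cell
#'
#' Summaries follow the heat-map conventions of the study: SNP-count panels
#' record the **largest** per-SNP GxE hit count across replicates; GRSxE
#' p-value panels use the median (configurable via `grsxe_summary`); the
#' remaining quantities are replicate means.
#'
#' @param records Output of [run_grid()].
#' @param grsxe_summary Summary function for the per-cell GRSxE p-value
#'   (default [stats::median()]).
#' @return Tibble with one row per (scenario, model, fraction, fold):
#'   `n_replicates`, `mean_h2_modern`, `mean_n_gwas_hits`,
#'   `max_n_gwas_hits`, `mean_pct_perturbed_hits`, `max_n_gxe_hits`,
#'   `grsxe_p`, `prop_grsxe_sig` (fraction of replicates with GRSxE
#'   p < 0.05), `mean_shift_sd`.
#' @export
aggregate_grid <- function(records, grsxe_summary = stats::median) {
  ok <- dplyr::filter(records, .data$status == "ok")
  dplyr::summarise(
    dplyr::group_by(ok, .data$scenario, .data$model, .data$fraction,
                    .data$fold),
    n_replicates = dplyr::n(),
    mean_h2_modern = mean(.data$h2_modern),
    mean_n_gwas_hits = mean(.data$n_gwas_hits),
    max_n_gwas_hits = if (all(is.na(.data$n_gwas_hits))) NA_integer_ else
      max(.data$n_gwas_hits, na.rm = TRUE),
    mean_pct_perturbed_hits = mean(.data$pct_perturbed_hits, na.rm = TRUE),
    max_n_gxe_hits = if (all(is.na(.data$n_gxe_hits))) NA_integer_ else
      max(.data$n_gxe_hits, na.rm = TRUE),
    prop_grsxe_sig = mean(.data$grsxe_p < 0.05, na.rm = TRUE),
    grsxe_p = if (all(is.na(.data$grsxe_p))) NA_real_ else
      grsxe_summary(.data$grsxe_p[!is.na(.data$grsxe_p)]),
    mean_shift_sd = mean(.data$mean_shift_sd),
    .groups = "drop"
  )
}

#' Heat-map of an aggregated grid metric
#'
#' @param agg Output of [aggregate_grid()].
#' @param metric Column of `agg` to fill by (string), e.g.
#'   `"max_n_gxe_hits"` or `"grsxe_p"`.
#' @param log10_p Plot `-log10` of the metric (for p-value panels).
#' @return A ggplot object (tile map, fraction on x, fold on y; cells with
#'   missing values are left blank, mirroring grid cells with no discovered
#'   SNPs).
#' @export
plot_grid_heatmap <- function(agg, metric = "max_n_gxe_hits",
                              log10_p = grepl("_p$", metric)) {
  val <- agg[[metric]]
  if (log10_p) {
    val <- -log10(val)
  }
  agg$.value <- val
  ggplot2::ggplot(agg, ggplot2::aes(x = 100 * .data$fraction, y = .data$fold,
                                    fill = .data$.value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(
      name = if (log10_p) paste0("-log10 ", metric) else metric,
      na.value = "white"
    ) +
    ggplot2::labs(x = "% of SNPs perturbed", y = "fold change in effect size") +
    ggplot2::theme_minimal()
}
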