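# gxesim

Power simulations for gene-by-environment (GxE) interactions in
genome-wide association studies.

Complex-trait GWAS rarely find per-SNP GxE interactions, yet interaction
signal often appears once risk alleles are summed into a genetic risk score
(GRS). `gxesim` is for statistical geneticists who want to quantify when
that pattern is expected. It simulates a polygenic quantitative trait
(2500 independent causal SNPs, Hardy–Weinberg genotypes, heritability 36%,
V<sub>P</sub> = 1) in two environments: an "ancestral" baseline and a
"modern" environment that multiplies the per-allele effect size
β<sub>i</sub> of a fraction *q* of the SNPs by a constant fold *f*
(β<sup>mod</sup> = f·β<sup>anc</sup>). Effects follow from each SNP's
variance-explained fraction,

> gv<sub>i</sub> = 2 β<sub>i</sub>² p<sub>i</sub>(1 − p<sub>i</sub>),  p<sub>i</sub> ~ U(0.05, 0.95),

with a head of 701 variants spanning 0.012–0.28% of V<sub>P</sub> (16% in
total) and a tail of 1799 variants at 0.012%. On top of the generator the
package provides:

* vectorised per-SNP association scans and a two-stage discovery design
  (50k at P < 10⁻⁵, pooled 100k at P < 5×10⁻⁸),
* per-SNP GxE and single-shot GRSxE interaction tests
  (Y = β₀ + β_G χ_G + β_E χ_E + β_GxE χ_G χ_E on 20k + 20k mixed cohorts),
* scenario orchestration (A: perturbed SNPs known; B: discovery in
  all-modern samples; C: discovery in a 50/50 mixture),
* a seeded, resumable 20×20 parameter-grid runner (fractions 1–20%,
  folds 1.05–2.0) with per-cell aggregation and ggplot2 heat maps,
* tidy outputs everywhere: tibbles in and out, `tidy()`/`glance()` methods,
  TSV/VCF/YAML-config I/O, and a thin CLI (`inst/cli/gxesim.R`).

## Worked example

Perturb 10% of the SNPs by 1.3-fold, treat the perturbed set as known
(scenario A), and test interactions in a 40,000-individual mixed cohort:

```r
library(gxesim)

arch <- trait_architecture(model = 1, fraction = 0.10, fold = 1.3, seed = 1)
glance(arch)
#> # A tibble: 1 × 9
#>   n_snps vg_ancestral vg_modern    ve model fraction  fold n_perturbed
#>    <int>        <dbl>     <dbl> <dbl> <dbl>    <dbl> <dbl>       <int>
#> 1   2500         0.36     0.388  0.64     1      0.1   1.3         250
#> # i 1 more variable: mean_shift_sd <dbl>

rec <- run_replicate("A", model = 1, fraction = 0.10, fold = 1.3, seed = 1)
rec[, c("h2_modern", "mean_shift_sd", "n_tested", "n_gxe_hits", "grsxe_p")]
#>   h2_modern mean_shift_sd n_tested n_gxe_hits      grsxe_p
#> 1 0.3685834      1.437656      250          0 2.000569e-10
```

Read: the perturbation lifts the genetic variance from 0.360 to 0.388
(modern-cohort h² ≈ 0.37) and shifts the mean modern phenotype ~1.4
ancestral SDs upward. None of the 250 perturbed SNPs reaches genome-wide
significance in its individual interaction test (`n_gxe_hits = 0`), but the
single GRSxE test over the same SNPs is unambiguous (P ≈ 2×10⁻¹⁰) — the
package's central contrast: interaction effects invisible per SNP, obvious
in aggregate.

A grid sweep and heat map:

```r
spec <- grid_spec(scenario = "A", model = 1, replicates = 5, seed = 1)
records <- run_grid(spec, out_dir = "run")   # resumable
agg <- aggregate_grid(records)
plot_grid_heatmap(agg, "grsxe_p")
```

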