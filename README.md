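# atacreg

Downstream analysis of multi-cell-type ATAC-seq regulomes, for studies that
profile chromatin accessibility across sorted cell populations and clinical
states — e.g. immune and stromal cells from normal skin versus the
clinically unaffected and affected skin of systemic sclerosis patients.
`atacreg` starts where peak calling ends: it takes a merged peak set, a
peak-by-sample read-count matrix and sample metadata, and provides the
statistics that turn them into cell-type and disease biology. A seeded
synthetic-data generator with machine-readable ground truth makes every
stage testable without any sequencing data.

## What it computes

Let `D[i, j]` be raw read counts over `N` merged peaks and `M` samples.

- **Normalization and intensity.** Quantile normalization forces every
  sample onto a common empirical distribution (rank-mean algorithm, ties
  averaged over their rank run); *peak intensity* is
  `log2(normalized + 1)`.
- **Differential accessibility.** Per-peak two-sided Welch t-tests on
  intensities with Benjamini–Hochberg correction;
  `log2FC = mean(A) − mean(B)` of intensities.
- **Cell-type-specific peaks.** One-vs-rest calls requiring, jointly:
  `P < 0.005`, `log2FC > 2`, coefficient of variation within the focal
  cell type (`inCov`) `< 0.5` and across all other samples (`outCov`)
  `< 0.5`.
- **Six-state classification.** Differential peaks of one cell type across
  normal / unaffected / affected skin (`P < 0.01`, `|log2FC| > 2`) are
  assigned one of six enrichment patterns (normal-only, normal+unaffected,
  unaffected-only, unaffected+affected, affected-only, normal+affected)
  when every in-pattern group mean exceeds every out-of-pattern mean by
  `> 0.8` and each group's intensity range is `< 1.5`.
- **GWAS-SNP enrichment.** Trait-associated SNP sets (filtered at
  association `P` thresholds 0.05 … 1e-8; traits with < 20 SNPs dropped)
  are overlapped with peaks, and each trait-sample *deviation score*
  `(O − E)/E` measures the excess accessibility of the trait's peaks, with
  an accessibility-matched background z-score; averaging over samples per
  cell type ranks cell types by trait relevance.
- **Signature scores vs clinical severity.** Cell-type signature genes
  (nearest genes of specific peaks, treatment-response genes removed) are
  averaged per expression array and correlated with the modified Rodnan
  skin score (Pearson r, two-tailed t-statistic P), plus a paired
  Low-vs-High mRSS contrast per patient (patients with span > 5).
- **TF footprinting.** Reads are shifted +4/−5 bp by strand to Tn5
  insertion positions, depth-equalized across groups, and aggregated
  around motif sites into 100 bp profiles whose central dip reveals bound
  factors.
- **Motif enrichment.** A 0/1 peak-by-motif occupancy matrix feeds a
  module-map-style hypergeometric test per (motif, peak set) with BH
  correction and signed `−log10(adjusted P)` scores.
- **Cell-cell communication (SIA).** Gene-level accessibility is the sum
  of intensities of a gene's peaks; the Alteration Score
  `AS = log2((mean_affected + 1)/(mean_normal + 1))` per cell type; for a
  receptor R in cell type A and its ligand L in cell type B,

  ```
  SIA = 0                          if |AS_R| < 1 or |AS_L| < 1
      = AS_R + AS_L                otherwise
  ```

  and interactions with `|SIA| > 7` are retained, direction by sign.

## Worked example

```r
library(atacreg)

cfg   <- sim_config(seed = 1)        # default synthetic study
study <- simulate_study(cfg)         # counts, SNPs, expression, motifs, LR
study$matrix
#> <atac_matrix> 5000 peaks x 48 samples
#>   normalized: FALSE | intensity: FALSE
#>   cell types: CD4 (6), CD8 (6), DC (6), EC (6), Fib (6), KC (6), LC (6), Mac (6)

res <- run_pipeline(study, seed = 1)

res$mrss_cor                         # signature score vs clinical severity
#> # A tibble: 8 × 4
#>   cell_type        r        p     n
#>   <chr>        <dbl>    <dbl> <int>
#> 1 CD4       -0.00599 0.952      105
#> 2 CD8        0.126   0.199      105
#> 3 DC         0.367   0.000116   105
#> 4 EC         0.0841  0.394      105
#> # … 4 more rows
```

The dendritic-cell signature is the only one correlated with the fibrosis
score — exactly the coupling the generator planted (`rho = 0.4` for DC).
The communication stage recovers the six planted receptor–ligand
alterations, none spurious, with DC ranked first on up-regulated
interactions:

```r
res$interactions[, c("sender", "receiver", "sia", "direction")]
#> # A tibble: 6 × 4
#>   sender receiver   sia direction
#> 1 DC     CD4       9.31 up
#> 2 DC     CD8       9.19 up
#> 3 DC     LC        8.56 up
#> 4 KC     CD4      -8.68 down
#> 5 KC     CD8      -8.66 down
#> 6 KC     DC       -9.33 down

res$interaction_summary
#> # A tibble: 5 × 3
#>   cell_type  n_up n_down
#> 1 DC            3      1
#> 2 CD4           1      1
#> 3 CD8           1      1
#> 4 LC            1      0
#> 5 KC            0      3
```

Result objects have `tidy()`, `glance()` and `autoplot()` methods, e.g.
`autoplot(res$footprints)` draws the per-group insertion profiles with the
protected group's central dip, and `glance(res$six_state)` tabulates the
six cluster counts and ratios.

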