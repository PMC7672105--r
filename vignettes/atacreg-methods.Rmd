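---
title: "Methods: multi-cell-type ATAC-seq regulome analysis with atacreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cell-type ATAC-seq regulome analysis with atacreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacreg)
```

`atacreg` implements the downstream statistics of a multi-cell-type,
multi-state chromatin accessibility study: eight sorted skin cell
populations (CD4+ and CD8+ T cells, dendritic cells, Langerhans cells,
endothelial cells, macrophages, fibroblasts, keratinocytes) profiled by
ATAC-seq in normal donors and in the clinically unaffected and affected
skin of fibrosis patients. This vignette explains each model, its
assumptions, the tunable parameters, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## The data model

The backbone is the `atac_matrix`: an `N x M` matrix of raw read counts
over merged peaks (rows) and samples (columns), carried together with peak
coordinates (BED-style, 0-based half-open everywhere inside the package;
1-based inputs such as SNP catalogs are converted on read) and sample
metadata (`cell_type`, clinical `state` from the closed set
normal/unaffected/affected, `donor_id`). Two derived layers are filled in
by the user-facing verbs:

- `quantile_normalize()` replaces each column by the reference
  distribution (per-rank mean of the sorted columns). Ties are resolved by
  averaging the reference values across the tied run, the classic
  rank-mean rule; this choice keeps every column total equal to the
  reference total even with heavily tied counts. A consequence worth
  knowing: with ties, the *multisets* of column values are no longer
  exactly identical across samples (an averaged value is specific to the
  column whose run produced it) — sorted columns are identical exactly on
  tie-free data.
- `peak_intensity()` computes `log2(normalized + 1)`. The unit pseudocount
  is a deliberate choice: zeros occur in real count matrices, the
  transform must stay finite, and `log2(x + 1)` maps zero counts to zero
  intensity while being indistinguishable from `log2(x)` at typical peak
  depths (tens to hundreds of reads).

Peak-to-gene annotation assigns each peak to the gene whose TSS is nearest
to the peak center. The center is `floor((start + end) / 2)`; signed
distance is `center - tss`. Equidistant TSSs are broken by
lexicographically smallest gene id so that annotation is deterministic. We
impose no distance cap by default (`max_dist = Inf`): anchoring of
signature genes should not silently lose distal regulation; a cap is
available for users who want promoter-proximal annotation only. Distal
elements are peaks whose nearest TSS is strictly more than 1 kb away.

## Differential accessibility

Per-peak tests are two-sided Welch t-tests on intensities. Welch rather
than pooled-variance Student is the deliberate default: replicate groups
of 2–4 samples with no reason to assume equal variances. The log2 fold
change is the **difference of mean log2 intensities**, not the log2 of the
ratio of mean counts; the two differ under skew, and the difference form
is the one consistent with testing on the intensity scale (a configurable
point, documented here because the phrase "fold change of mean peak
intensity" admits both readings). Benjamini–Hochberg adjustment is
`stats::p.adjust(method = "BH")`.

Degenerate inputs follow limit conventions rather than erroring: a peak
with zero variance in both groups gets `p = 1` when the means agree and
`p = 0` when they differ; conditions with a single replicate must use
`mode = "fc_only"`, which calls significance on `|log2FC|` alone — the
design used for cell types where only one sample per state could be
collected (macrophages, endothelial cells).

### Cell-type-specific peaks

`cell_type_specific_peaks()` runs one-vs-rest per cell type and requires
four criteria *jointly*: `P < 0.005`, `log2FC > 2` (focal above rest —
one-sided by construction), and coefficients of variation below 0.5 both
within the focal group (`inCov`) and across all remaining samples
(`outCov`). CVs are computed on normalized counts (linear scale): the CV
of log-scale values depends on the arbitrary log base and origin, so it is
not a well-defined dispersion measure there. A zero mean in a CV
denominator yields `+Inf` (the filter fails) with a warning rather than a
division error.

### Six-state classification

For one cell type across the three clinical states,
`classify_six_states()` works in two stages. Stage 1 collects candidate
peaks as the **union** of significant peaks over the three pairwise
comparisons (`P < 0.01`, `|log2FC| > 2`; fold-change-only when a state has
one sample). The union was a genuinely open design point — assigning each
pairwise list independently could label a peak twice; the union plus a
single assignment rule cannot. Stage 2 assigns each candidate the
enrichment pattern `S` (one of the six singletons/pairs of states) for
which every in-`S` group mean exceeds every out-of-`S` group mean by more
than 0.8 intensity units, provided every group's within-group range is
below 1.5 — the range cap keeps heterogeneous groups out of any cluster.
With strict gaps at most one pattern can qualify; at exact boundary ties
the smallest subset wins, then cluster order C1 < … < C6. Candidates
matching no pattern stay `unassigned`. Reported ratios divide cluster
counts by the total number of candidates.

## SNP-set deviation scores

To rank cell types by relevance to a trait, trait-associated SNPs are
filtered at an association threshold (the standard sweep is 0.05, 1e-3,
1e-5, 1e-6, 1e-8), traits with fewer than 20 retained SNPs are dropped as
statistically unstable, and the rest are overlapped with peaks (a SNP at
0-based position `p` hits `[start, end)` iff `start <= p < end`).
Membership is binary at the peak level: a peak hosting three SNPs of a
trait counts once — SNP multiplicity reflects LD block density more than
regulatory dosage.

For trait `t` and sample `j`, with membership `m`, counts `D`, per-peak
cross-sample mean counts `xbar` and sample totals `T`:

- observed `O = sum_i m_i D_ij`,
- expected `E = f_t T_j` where `f_t = sum_i m_i xbar_i / sum_i xbar_i`,
- raw deviation `y = (O - E) / E`.

The all-peaks set has `y = 0` identically, and `y` is invariant to scaling
any sample's depth — the two sanity anchors of the construction. On top of
the raw deviation a background z-score is computed against `n_background`
(default 50, a desk-scale compromise) random peak sets drawn to match the
trait set's profile across `n_bins = 10` mean-accessibility bins. The
matching is on accessibility only: synthetic peaks carry no sequence, so
GC matching — which sequence-aware implementations add — has no meaning
here. Both the raw and the background-normalized averages per cell type
are reported, since either may be the quantity a downstream consumer
wants. Background sampling is seeded and bit-reproducible.

## Signature scores and clinical correlation

Signature genes of a cell type are the deduplicated nearest genes of its
specific peaks. Before any clinical correlation, treatment-response genes
are removed: genes differential between treated (12/24-month) and baseline
arrays at `|log2FC| > 2`, `P < 0.005`. We apply the same exclusion to both
the correlation and the paired Low/High analysis — the exclusion exists to
keep drug response out of disease-severity signal, and that argument does
not distinguish the two analyses.

The signature score of a cell type in an array is the mean normalized
expression of its (post-exclusion, measured) signature genes. Scores are
correlated with the modified Rodnan skin score (mRSS, the standard
clinical measure of skin fibrosis severity, unitless, higher = worse) by
Pearson correlation with the two-tailed t-statistic p-value on `n - 2`
degrees of freedom. The paired analysis selects, per patient, the
timepoints of minimal and maximal mRSS (ties resolved to the earliest
timepoint — deterministic), keeps patients whose span strictly exceeds 5,
and runs a paired two-tailed t-test on the score differences. All-zero
differences give `p = 1`; constant non-zero differences give the `p = 0`
limit, both flagged by a warning.

The module accepts an already-normalized expression matrix; microarray
preprocessing is upstream of this package's scope, and the synthetic
generator emits normalized values directly.

## Footprinting

`tn5_shift()` converts mapped reads to Tn5 insertion positions: `start +
4` on the plus strand, `end - 1 - 5` on the minus strand (the 5' base of a
minus-strand read is its last aligned base in 0-based coordinates; the
-5 bp shift moves it to the cleavage center). The result is tagged with a
provenance class, and shifting an already-shifted set errors — the
operation is not idempotent and a silent double shift is a classic
pipeline bug. `downsample_insertions()` equalizes depth across sample
groups by seeded sampling without replacement; the default `n = "min"`
(the smallest group's depth) is the robust reading of a fixed per-group
read target when group sizes vary.

`aggregate_footprint()` bins insertions by offset from each motif-site
center, mirrors minus-strand sites into motif orientation, and averages
over sites. The default window is halfwidth 50 — a 101-position profile
covering the 100 bp region centered on the motif; the halfwidth must be at
least half the motif length. Point insertions (not reads extended to
50 bp) are aggregated: extension is a smoothing choice for browser tracks,
while footprint depth estimation wants the unsmoothed cleavage positions.
The profile's total mass equals in-window insertions divided by site
count, an exact bookkeeping identity used as a test invariant.

## Motif enrichment

Motif hits overlapping peaks (half-open interval logic) give a 0/1
peak-by-motif occupancy matrix. For each motif and each peak set,
enrichment is tested against the peak universe with the hypergeometric
distribution: two one-sided tails decide direction (enriched/depleted),
the smaller tail is the p-value, BH correction runs across all
(motif, set) pairs, and the signed score is `-log10(adjusted p)` with
positive = enriched. This is a reimplementation of the module-map idea on
its standard statistical core, not an emulation of any specific binary.
The universe is an explicit argument (the occupancy matrix you pass):
enrichment against all peaks and enrichment against differential peaks
answer different questions, and the choice is left to the caller.

## Communication scoring

Gene-level accessibility sums the intensities of all peaks annotated to a
gene — a chromatin proxy for expression. The Alteration Score of gene `g`
in cell type `c` is

`AS = log2((mean_affected + 1) / (mean_normal + 1))`

with per-state means taken across replicate samples first. The log2 scale
is a considered decision: the interaction score below needs a symmetric
null zone (`|AS| < 1`) and a negative branch, both of which are coherent
only on a signed log scale — on a raw ratio scale "down-regulation" would
live in (0, 1) and the null zone would be asymmetric.

For every ordered (receiver, sender) pair of cell types and every known
receptor–ligand pair, `SIA = AS_receptor + AS_ligand` unless either side
is inside the null zone, in which case `SIA = 0`. By default we also zero
sign-discordant pairs (`concordance_required = TRUE`): an interaction
whose receptor opens while its ligand closes is not coherently up- or
down-regulated; setting the flag to `FALSE` recovers the literal piecewise
sum. Interactions with `|SIA|` strictly above 7 are retained; positive
means up-regulated in the affected state. Summaries count, per cell type,
the retained up and down interactions in which it participates as sender
or receiver.

## The synthetic-data generator

`sim_config()` + `simulate_study()` produce every input the pipeline
consumes, as a pure function of (config, seed), with ground truth recorded
alongside. What it emulates:

- a single synthetic chromosome with evenly spaced 500 bp peaks laid out
  in blocks of three, one gene TSS at each block's middle peak — so every
  planted peak maps to a known gene and planted signatures are exact;
- negative-binomial raw counts (`size = 100`, mild overdispersion) around
  per-peak log2 baselines uniform on [4, 7], with planted effects added on
  the log2 scale plus normal noise (`noise_sd = 0.2` by default);
- 100 specific peaks per cell type at +4 log2 units; 100 peaks per
  six-state pattern (gap 3) in a focal cell type; 48 samples by default
  (8 cell types x 3 states x 2 replicates);
- a SNP catalog whose target trait lands ~95% of its SNPs
  (`odds = 20`) inside the target cell type's specific peaks, with
  log-uniform association p-values so threshold sweeps bite;
- 105 expression arrays from 30 patients with declining mRSS
  trajectories; the target cell type's signature genes are coupled to
  standardized mRSS at `rho = 0.4`; 20 treatment-response genes shifted by
  +5 in treated arrays, a few of them deliberately inside the target
  signature so that exclusion matters. Residual signature variation is
  split 70% patient-level / 30% array-level — between-patient differences
  (cell composition) dominate real signature variation, and this split is
  what lets within-patient paired contrasts be sharper than the marginal
  correlation;
- Poisson insertion tracks around motif sites with a protection factor
  (default 0.2) inside motifs for protected groups;
- ligand–receptor gene blocks whose silent state is essentially unread
  chromatin (log2 counts -6) and whose active state is high (13): with
  three peaks per gene this is what makes planted `|AS| >= 1` on both
  sides and `|SIA| > 7` hold after quantile normalization, which floors
  silent peaks at the reference distribution's bottom ranks.

What it does **not** emulate, hence what passing tests do not show about
real data: genomic sequence (no GC composition, no motif-sequence
relationship, so the deviation background matches on accessibility only);
overlapping and irregularly sized peaks; chromosome structure and LD
(trait SNPs are placed independently); batch effects, donor covariance
structure, and library-complexity artifacts; fragment-length periodicity.
Recovery rates on this generator are upper bounds for such conditions, not
estimates of performance on real studies.

## Problem sizes and runtime

The default study is 5,000 peaks x 48 samples and the full pipeline runs
in a few seconds on one core; the test suite uses this size for end-to-end
checks, a 5,000 x 24 single-state design for specificity recovery, a
3,000-peak one-cell-type design (3 replicates per state, noise sd 0.1) for
six-state recovery, and batches of ~300-peak studies for replicated
SNP-deviation checks. These sizes were chosen to make simulation-based
tests sharp (planted effects many standard errors above noise) while the
entire suite stays fast enough to run on every change.

## Known limitations

- The t-test operates on log intensities of quantile-normalized counts;
  for very low counts a count model (negative-binomial GLM) would be more
  efficient. The choice mirrors the analysis this package reproduces.
- Deviation z-scores use accessibility-binned background sets; with only
  50 background draws the z's granularity is limited (raw deviations are
  reported alongside for this reason).
- Nearest-gene annotation is a heuristic; enhancer-gene maps from
  chromatin conformation would reassign some distal peaks.
- `classify_six_states()` assumes exactly the three canonical states;
  designs with more states need the general differential machinery
  directly.
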