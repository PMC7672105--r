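#' Run the full downstream analysis on a (simulated or real) study
#'
#' Chains every stage of the package over one input bundle: quantile
#' normalization and intensity transform, one-vs-rest cell-type-specific
#' peak calling, six-state classification of the focal cell type,
#' SNP-set deviation enrichment across association thresholds, signature
#' scoring with treatment-response-gene removal and clinical correlation,
#' paired Low/High testing, motif enrichment over the specific peak sets,
#' footprint aggregation per sample group, and receptor-ligand interaction
#' alteration scoring. All randomized steps derive their seeds from
#' `seed`, so a fixed seed gives byte-identical results across reruns.
#'
#' @param study A list shaped like the output of [simulate_study()]
#'   (`matrix`, `peaks`, `meta`, `genes`, `catalog`, `expr`, `clinical`,
#'   `motif_sites`, `insertions`, `lr_pairs`, `motif_hits`).
#' @param seed Integer seed for the randomized stages.
#' @param snp_thresholds Association p-value sweep (default
#'   `c(0.05, 1e-5)`, a short sweep; pass the full
#'   `c(0.05, 1e-3, 1e-5, 1e-6, 1e-8)` for the complete analysis).
#' @param six_state_cell_type Cell type for six-state classification
#'   (default `"DC"`).
#' @param sia_threshold Retention threshold on `|SIA|` (default 7).
#' @return A list of stage results: `matrix` (normalized), `specific`,
#'   `six_state`, `snp_enrichment`, `signature_scores`, `mrss_cor`,
#'   `paired`, `response_genes`, `motif_enrichment`, `footprints`,
#'   `interactions`, `interaction_summary`.
#' @export
run_pipeline <- function(study, seed,
                         snp_thresholds = c(0.05, 1e-5),
                         six_state_cell_type = "DC",
                         sia_threshold = 7) {
  if (missing(seed)) abort("seed is required")
  x <- study$matrix |>
    quantile_normalize() |>
    peak_intensity()

  specific <- cell_type_specific_peaks(x)
  six_state <- classify_six_states(x, cell_type = six_state_cell_type)

  snp_enr <- snp_enrichment_sweep(
    study$catalog, x, study$peaks,
    thresholds = snp_thresholds, seed = seed + 11L
  )

  annotation <- annotate_nearest_gene(study$peaks, study$genes)
  gene_sets <- signature_genes(specific, annotation)
  response <- treatment_response_genes(study$expr, study$clinical)
  scores <- signature_scores(
    study$expr, gene_sets,
    exclude = response$gene_id
  )
  mrss_cor <- correlate_mrss(scores, study$clinical)
  paired <- paired_low_high(scores, study$clinical)

  occupancy <- occupancy_matrix(study$peaks, study$motif_hits)
  sets <- specific |>
    dplyr::filter(.data$specific) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(ids = list(.data$peak_id), .groups = "drop")
  motif_enr <- module_map(
    occupancy, setNames(sets$ids, sets$cell_type)
  )

  insertions <- downsample_insertions(
    study$insertions,
    n = "min", seed = seed + 21L
  )
  footprints <- aggregate_footprint(insertions, study$motif_sites)

  gene_acc <- gene_accessibility(x, annotation)
  as_table <- alteration_scores(gene_acc, study$meta)
  interactions <- altered_interactions(
    as_table, study$lr_pairs,
    threshold = sia_threshold
  )

  list(
    matrix = x,
    specific = specific,
    six_state = six_state,
    snp_enrichment = snp_enr,
    signature_scores = scores,
    mrss_cor = mrss_cor,
    paired = paired,
    response_genes = response,
    motif_enrichment = motif_enr,
    footprints = footprints,
    interactions = interactions,
    interaction_summary = interaction_summary(interactions)
  )
}
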