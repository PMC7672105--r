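#' Read gene models from TSV
#'
#' Gene models anchor peaks to genes through the transcription start site
#' (TSS). Accepts either a `tss` column directly, or `start`/`end` interval
#' columns from which the TSS is located using the strand (interval start
#' for `+` genes, `end - 1` for `-` genes, 0-based).
#'
#' @param path TSV with columns `gene_id`, `chrom`, and either `tss` or
#'   `start` + `end`; optional `strand` (defaults to `+`).
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_models <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  as_gene_models(tab)
}

#' Coerce a data frame to a gene-model table
#'
#' @param genes Data frame with `gene_id`, `chrom` and `tss` (or
#'   `start`/`end` plus `strand`).
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
as_gene_models <- function(genes) {
  stopifnot(all(c("gene_id", "chrom") %in% names(genes)))
  genes <- tibble::as_tibble(genes)
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  if (!"tss" %in% names(genes)) {
    if (!all(c("start", "end") %in% names(genes))) {
      abort("gene models need a tss column or start/end intervals")
    }
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  }
  if (any(genes$tss < 0)) abort("negative TSS coordinate")
  genes$tss <- as.integer(genes$tss)
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in gene models")
  genes[, c("gene_id", "chrom", "tss", "strand")]
}

#' Annotate peaks with their nearest gene
#'
#' Assigns each peak to the gene whose TSS is closest to the peak center
#' (`floor((start + end) / 2)`) on the same chromosome. The signed distance
#' is `center - tss`, so positive values lie downstream of a `+`-strand
#' TSS in genomic coordinates. Equidistant TSSs are broken deterministically
#' in favour of the lexicographically smallest `gene_id`. Peaks on
#' chromosomes absent from the gene models get `gene_id = NA`.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `peak_id`).
#' @param genes Gene-model table ([as_gene_models()]).
#' @param max_dist Optional cap: assignments farther than this (absolute
#'   distance in bp) are set to `NA`. Default `Inf` (no cap).
#' @return A tibble with columns `peak_id`, `gene_id`, `distance`.
#' @export
annotate_nearest_gene <- function(peaks, genes, max_dist = Inf) {
  validate_peaks(peaks)
  genes <- as_gene_models(genes)
  centers <- peak_center(peaks)
  out_gene <- rep(NA_character_, nrow(peaks))
  out_dist <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pk_idx <- which(peaks$chrom == chr)
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) == 0) next
    # Bracket each peak center between its flanking TSS values, then pick
    # the lexicographically smallest gene_id among all genes achieving the
    # minimal |center - tss| (both flanks can tie).
    u <- sort(unique(g$tss))
    ctr <- centers[pk_idx]
    lo <- findInterval(ctr, u) # index of last tss <= center (0 if none)
    for (k in seq_along(ctr)) {
      cand_tss <- c(
        if (lo[k] >= 1) u[lo[k]],
        if (lo[k] < length(u)) u[lo[k] + 1L]
      )
      d <- abs(ctr[k] - cand_tss)
      best_tss <- cand_tss[d == min(d)]
      ids <- g$gene_id[g$tss %in% best_tss]
      gid <- min(ids)
      out_gene[pk_idx[k]] <- gid
      out_dist[pk_idx[k]] <- ctr[k] - g$tss[match(gid, g$gene_id)]
    }
  }
  if (is.finite(max_dist)) {
    over <- !is.na(out_dist) & abs(out_dist) > max_dist
    out_gene[over] <- NA_character_
    out_dist[over] <- NA_real_
  }
  tibble::tibble(
    peak_id = peaks$peak_id, gene_id = out_gene, distance = out_dist
  )
}

#' Classify peaks as distal or proximal
#'
#' Distal regulatory elements are peaks whose nearest TSS lies more than
#' `min_dist` bp away (strictly); everything else, including peaks with no
#' annotatable gene, is proximal or `NA` respectively.
#'
#' @inheritParams annotate_nearest_gene
#' @param min_dist Distance threshold in bp (default 1000: the 1 kb
#'   convention for distal enhancers).
#' @return A tibble with columns `peak_id`, `distance`, `class`
#'   (`"distal"` / `"proximal"`, `NA` when unannotated).
#' @export
classify_distal <- function(peaks, genes, min_dist = 1000) {
  ann <- annotate_nearest_gene(peaks, genes)
  ann$class <- dplyr::case_when(
    is.na(ann$distance) ~ NA_character_,
    abs(ann$distance) > min_dist ~ "distal",
    TRUE ~ "proximal"
  )
  ann[, c("peak_id", "distance", "class")]
}

#' Gene-level accessibility by summing peak intensities
#'
#' The accessibility of a gene in a sample is the sum of the log2
#' intensities of all peaks imputed (annotated) to that gene — a chromatin
#' proxy for expression used by the communication stage. Genes with no
#' assigned peak are absent from the output.
#'
#' @param x An `atac_matrix` with intensities computed.
#' @param annotation Peak-to-gene annotation from
#'   [annotate_nearest_gene()].
#' @return A long tibble with columns `gene_id`, `sample_id`,
#'   `accessibility`.
#' @export
gene_accessibility <- function(x, annotation) {
  intens <- get_intensity(x)
  ann <- annotation[!is.na(annotation$gene_id), c("peak_id", "gene_id")]
  ann <- ann[ann$peak_id %in% rownames(intens), ]
  if (nrow(ann) == 0) {
    return(tibble::tibble(
      gene_id = character(), sample_id = character(),
      accessibility = numeric()
    ))
  }
  grp <- factor(ann$gene_id)
  summed <- rowsum(intens[ann$peak_id, , drop = FALSE], grp)
  tibble::as_tibble(summed, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id",
      names_to = "sample_id", values_to = "accessibility"
    )
}
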