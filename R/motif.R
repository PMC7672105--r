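#' Peak-by-motif occupancy matrix
#'
#' Builds the 0/1 matrix recording, for every peak and every motif, whether
#' at least one motif hit overlaps the peak (half-open interval overlap:
#' `hit.start < peak.end` and `hit.end > peak.start`).
#'
#' @param peaks Peak tibble.
#' @param motif_hits Tibble with columns `chrom`, `start`, `end`,
#'   `motif_id` (or a BED `name` column).
#' @return An integer matrix (peaks x motifs) of 0/1 entries, with peak
#'   ids as rownames and motif ids as colnames.
#' @export
occupancy_matrix <- function(peaks, motif_hits) {
  validate_peaks(peaks)
  if ("name" %in% names(motif_hits) && !"motif_id" %in% names(motif_hits)) {
    motif_hits$motif_id <- motif_hits$name
  }
  stopifnot(all(c("chrom", "start", "end", "motif_id") %in% names(motif_hits)))
  if (nrow(motif_hits) > 0) validate_intervals(motif_hits, "motif hit")
  motifs <- sort(unique(motif_hits$motif_id))
  occ <- matrix(
    0L, nrow(peaks), length(motifs),
    dimnames = list(peaks$peak_id, motifs)
  )
  for (chr in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == chr, ]
    hits <- motif_hits[motif_hits$chrom == chr, ]
    if (nrow(hits) == 0) next
    pk <- pk[order(pk$start), ]
    # a hit [s, e) overlaps peaks whose start < e and end > s; peaks may
    # overlap each other, so scan a start window bounded by max peak width
    maxw <- max(pk$end - pk$start)
    hi <- findInterval(hits$end - 1L, pk$start)
    lo <- findInterval(hits$start - maxw, pk$start) + 1L
    for (k in seq_len(nrow(hits))) {
      if (hi[k] < lo[k]) next
      cand <- lo[k]:hi[k]
      cand <- cand[pk$end[cand] > hits$start[k]]
      if (length(cand) > 0) {
        occ[pk$peak_id[cand], hits$motif_id[k]] <- 1L
      }
    }
  }
  occ
}

#' Module-map motif enrichment over peak sets
#'
#' For every motif and every peak set (e.g. each cell type's specific
#' peaks), tests whether motif-bearing peaks are over- or under-represented
#' in the set relative to the peak universe using the hypergeometric
#' distribution: two one-sided tail tests give the direction, the smaller
#' tail is the p-value, and Benjamini-Hochberg correction is applied across
#' all (motif, set) pairs. The signed score is
#' `-log10(adjusted p)` with positive sign for enrichment and negative for
#' depletion.
#'
#' @param occupancy 0/1 matrix from [occupancy_matrix()].
#' @param peak_sets Named list of peak-id character vectors, each a subset
#'   of the occupancy matrix's rows.
#' @param alpha Significance level for the `significant` flag applied to
#'   adjusted p-values (default 0.05).
#' @return A tibble with columns `motif`, `set`, `n_set`, `n_motif`,
#'   `n_overlap`, `p`, `adj_p`, `direction` (`enriched` / `depleted`),
#'   `score`, `significant`.
#' @export
module_map <- function(occupancy, peak_sets, alpha = 0.05) {
  stopifnot(is.matrix(occupancy))
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    abort("peak_sets must be a named list")
  }
  universe <- rownames(occupancy)
  n_univ <- length(universe)
  res <- purrr::imap(peak_sets, function(ids, set_name) {
    missing <- setdiff(ids, universe)
    if (length(missing) > 0) {
      abort(paste0(
        "peak set ", set_name, " contains peak outside the universe: ",
        missing[1]
      ))
    }
    n_set <- length(ids)
    if (n_set == 0) {
      return(tibble::tibble(
        motif = colnames(occupancy), set = set_name,
        n_set = 0L, n_motif = colSums(occupancy), n_overlap = NA_integer_,
        p = NA_real_, direction = NA_character_
      ))
    }
    in_set <- occupancy[ids, , drop = FALSE]
    k <- unname(colSums(in_set)) # motif-bearing peaks inside the set
    big_k <- unname(colSums(occupancy)) # motif-bearing peaks in the universe
    p_enr <- phyper(k - 1, big_k, n_univ - big_k, n_set, lower.tail = FALSE)
    p_dep <- phyper(k, big_k, n_univ - big_k, n_set, lower.tail = TRUE)
    enriched <- p_enr <= p_dep
    tibble::tibble(
      motif = colnames(occupancy), set = set_name,
      n_set = n_set, n_motif = unname(big_k), n_overlap = as.integer(k),
      p = unname(ifelse(enriched, p_enr, p_dep)),
      direction = ifelse(enriched, "enriched", "depleted")
    )
  }) |>
    dplyr::bind_rows()
  res$adj_p <- rep(NA_real_, nrow(res))
  ok <- !is.na(res$p)
  res$adj_p[ok] <- p.adjust(res$p[ok], method = "BH")
  res$score <- ifelse(
    res$direction == "enriched", 1, -1
  ) * -log10(res$adj_p)
  res$significant <- !is.na(res$adj_p) & res$adj_p < alpha
  res[, c(
    "motif", "set", "n_set", "n_motif", "n_overlap",
    "p", "adj_p", "direction", "score", "significant"
  )]
}

#' Heatmap of signed motif enrichment scores
#'
#' @param enrichment Tibble from [module_map()].
#' @return A ggplot object (red enriched, blue depleted).
#' @export
plot_motif_enrichment <- function(enrichment) {
  ggplot2::ggplot(
    enrichment,
    ggplot2::aes(x = .data$set, y = .data$motif, fill = .data$score)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick", midpoint = 0
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "signed\n-log10 adj p"
    ) +
    ggplot2::theme_minimal()
}
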