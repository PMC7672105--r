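# Independent oracles and small fixture builders shared across tests.

# Classic rank-mean quantile normalization, written independently of the
# package: reference = per-rank mean of sorted columns; every tied value
# gets the mean of the reference values over the ranks its run occupies.
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    res <- numeric(length(col))
    for (v in unique(col)) {
      at <- which(col == v)
      lo <- sum(col < v) + 1L
      res[at] <- mean(ref[lo:(lo + length(at) - 1L)])
    }
    res
  })
  dimnames(out) <- dimnames(m)
  out
}

# Step-up Benjamini-Hochberg written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# All-pairs nearest-TSS search with lexicographic tie-break.
nearest_gene_oracle <- function(peaks, genes) {
  centers <- floor((peaks$start + peaks$end) / 2)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) {
      return(list(gene_id = NA_character_, distance = NA_real_))
    }
    d <- abs(centers[i] - g$tss)
    best <- which(d == min(d))
    best <- best[order(g$gene_id[best])][1]
    list(gene_id = g$gene_id[best], distance = centers[i] - g$tss[best])
  })
  tibble::tibble(
    peak_id = peaks$peak_id,
    gene_id = vapply(res, `[[`, character(1), "gene_id"),
    distance = vapply(res, `[[`, numeric(1), "distance")
  )
}

# All-pairs SNP-in-peak containment (0-based point in half-open interval).
overlap_oracle <- function(catalog, peaks) {
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    for (j in seq_len(nrow(peaks))) {
      if (catalog$chrom[i] == peaks$chrom[j] &&
        catalog$pos[i] >= peaks$start[j] &&
        catalog$pos[i] < peaks$end[j]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = catalog$trait[i], peak_id = peaks$peak_id[j]
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(trait = character(), peak_id = character()))
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

# Piecewise SIA written straight from its definition.
sia_oracle <- function(r, l, concordance = TRUE) {
  if (is.na(r) || is.na(l)) {
    return(NA_real_)
  }
  if (abs(r) < 1 || abs(l) < 1) {
    return(0)
  }
  if (concordance && sign(r) != sign(l)) {
    return(0)
  }
  r + l
}

# Exhaustive hypergeometric tails by enumerating every size-n subset of a
# universe with K marked elements.
hyper_enum <- function(n_univ, k_marked, n_set, k_obs) {
  subsets <- utils::combn(n_univ, n_set)
  marked <- seq_len(k_marked)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  c(
    p_ge = mean(hits >= k_obs),
    p_le = mean(hits <= k_obs)
  )
}

# Build an atac_matrix with explicit normalized/intensity slots so filter
# logic can be tested on exact values.
make_matrix <- function(intensity, meta = NULL, normalized = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- sprintf("pk%02d", seq_len(nrow(intensity)))
  }
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- sprintf("s%02d", seq_len(ncol(intensity)))
  }
  if (is.null(normalized)) normalized <- 2^intensity - 1
  counts <- matrix(
    0L, nrow(intensity), ncol(intensity),
    dimnames = dimnames(intensity)
  )
  x <- atac_matrix(counts, meta = meta)
  x$normalized <- normalized
  x$intensity <- intensity
  x
}

make_meta <- function(sample_ids, cell_type, state = "normal",
                      donor = NULL) {
  tibble::tibble(
    sample_id = sample_ids,
    cell_type = rep_len(cell_type, length(sample_ids)),
    state = rep_len(state, length(sample_ids)),
    donor_id = donor %||% paste0("d", seq_along(sample_ids))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_clinical <- function(n_patients = 4, timepoints = c(0, 12),
                          mrss = NULL) {
  grid <- expand.grid(
    timepoint = timepoints,
    patient_id = sprintf("pt%02d", seq_len(n_patients))
  )
  tibble::tibble(
    array_id = sprintf("a%03d", seq_len(nrow(grid))),
    patient_id = as.character(grid$patient_id),
    timepoint = grid$timepoint,
    mrss = mrss %||% seq_len(nrow(grid)),
    phase = ifelse(grid$timepoint == 0, "baseline", "treated")
  )
}
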