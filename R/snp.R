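#' Read a trait-SNP association catalog
#'
#' Reads a GWAS-style catalog of trait-associated SNPs. Input positions are
#' 1-based (the catalog convention) and are converted to the package's
#' internal 0-based convention on read.
#'
#' @param path TSV with columns `trait`, `chrom`, `pos` (1-based),
#'   `assoc_p`.
#' @return A tibble with columns `trait`, `chrom`, `pos` (0-based),
#'   `assoc_p`.
#' @export
read_snp_catalog <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("trait", "chrom", "pos", "assoc_p")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("catalog lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(tab$pos < 1)) abort("1-based SNP position < 1")
  if (any(tab$assoc_p <= 0 | tab$assoc_p > 1)) {
    abort("association p-values must lie in (0, 1]")
  }
  tibble::tibble(
    trait = as.character(tab$trait),
    chrom = as.character(tab$chrom),
    pos = as.integer(tab$pos) - 1L,
    assoc_p = as.numeric(tab$assoc_p)
  )
}

#' Filter a trait-SNP catalog by association significance
#'
#' Retains SNPs with association p-value strictly below `p_threshold` and
#' drops traits left with fewer than `min_snps` SNPs (the catalog-noise
#' guard: traits with under 20 associated SNPs are discarded to avoid
#' unstable deviation estimates).
#'
#' @param catalog Catalog tibble from [read_snp_catalog()].
#' @param p_threshold Association p-value threshold in (0, 1].
#' @param min_snps Minimal retained SNP count per trait (default 20).
#' @return The filtered catalog tibble.
#' @export
filter_catalog <- function(catalog, p_threshold, min_snps = 20) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  if (nrow(catalog) == 0) {
    warn("empty SNP catalog")
    return(catalog)
  }
  kept <- catalog[catalog$assoc_p < p_threshold, ]
  counts <- table(kept$trait)
  keep_traits <- names(counts)[counts >= min_snps]
  kept[kept$trait %in% keep_traits, ]
}

#' Overlap trait SNP sets with peaks
#'
#' Builds the trait-by-peak membership used by deviation scoring: a trait
#' is a member of a peak when at least one of its retained SNPs lies inside
#' the peak. A SNP at 0-based position `p` overlaps the half-open peak
#' `[start, end)` iff `start <= p < end`.
#'
#' @param catalog Filtered catalog tibble (0-based positions).
#' @param peaks Peak tibble.
#' @return A tibble with columns `trait`, `peak_id` listing memberships
#'   (one row per trait-peak pair), with attribute `n_snps` (named vector
#'   of retained SNPs per trait).
#' @export
overlap_traits_peaks <- function(catalog, peaks) {
  validate_peaks(peaks)
  n_snps <- table(catalog$trait)
  hits <- list()
  for (chr in unique(catalog$chrom)) {
    snp <- catalog[catalog$chrom == chr, ]
    pk <- peaks[peaks$chrom == chr, ]
    if (nrow(pk) == 0) next
    pk <- pk[order(pk$start), ]
    # candidate peaks have start <= pos and start > pos - max width; peaks
    # may overlap, so every candidate in that window is checked against
    # its own end
    maxw <- max(pk$end - pk$start)
    hi <- findInterval(snp$pos, pk$start)
    lo <- findInterval(snp$pos - maxw, pk$start) + 1L
    pair <- purrr::map2(lo, hi, function(l, h) {
      if (h < l) integer(0) else l:h
    })
    snp_idx <- rep(seq_len(nrow(snp)), lengths(pair))
    pk_idx <- unlist(pair, use.names = FALSE)
    inside <- snp$pos[snp_idx] < pk$end[pk_idx]
    if (any(inside)) {
      hits[[chr]] <- tibble::tibble(
        trait = snp$trait[snp_idx[inside]],
        peak_id = pk$peak_id[pk_idx[inside]]
      )
    }
  }
  out <- if (length(hits) > 0) {
    dplyr::distinct(dplyr::bind_rows(hits))
  } else {
    tibble::tibble(trait = character(), peak_id = character())
  }
  attr(out, "n_snps") <- n_snps
  out
}

# Membership tibble -> logical matrix (traits x peaks) over the full
# peak universe of the matrix.
membership_matrix <- function(membership, peak_ids) {
  traits <- sort(unique(membership$trait))
  m <- matrix(
    FALSE, length(traits), length(peak_ids),
    dimnames = list(traits, peak_ids)
  )
  if (nrow(membership) > 0) {
    keep <- membership$peak_id %in% peak_ids
    m[cbind(
      match(membership$trait[keep], traits),
      match(membership$peak_id[keep], peak_ids)
    )] <- TRUE
  }
  m
}

#' Deviation scores of trait peak sets per sample
#'
#' Quantifies how much more (or less) accessible a trait's SNP-bearing
#' peaks are in a sample than expected from that sample's sequencing depth.
#' For trait `t` and sample `j`, the raw deviation is
#' `y = (O - E) / E` with `O` the summed raw counts over member peaks,
#' `E = f_t * T_j` the expectation, `f_t` the member peaks' share of total
#' mean accessibility (cross-sample mean counts) and `T_j` the sample's
#' total counts. A background z-score is computed against `n_background`
#' random peak sets drawn to match the trait set's profile across
#' `n_bins` mean-accessibility bins (accessibility-bias matching in the
#' style of chromVAR).
#'
#' @param membership Trait-peak membership from [overlap_traits_peaks()].
#' @param x An `atac_matrix` (raw counts are used).
#' @param n_background Number of matched background peak sets (default 50).
#' @param n_bins Number of mean-accessibility bins (default 10).
#' @param seed Integer seed controlling background sampling (required for
#'   reproducibility).
#' @return A tibble with columns `trait`, `sample_id`, `deviation`
#'   (raw), `z` (background-corrected).
#' @export
deviation_scores <- function(membership, x, n_background = 50, n_bins = 10,
                             seed) {
  stopifnot(inherits(x, "atac_matrix"))
  if (missing(seed)) abort("seed is required")
  counts <- x$counts
  peak_ids <- rownames(counts)
  m <- membership_matrix(membership, peak_ids)
  if (nrow(m) == 0) {
    return(tibble::tibble(
      trait = character(), sample_id = character(),
      deviation = numeric(), z = numeric()
    ))
  }
  xbar <- rowMeans(counts)
  total_xbar <- sum(xbar)
  t_j <- colSums(counts)

  raw_dev <- function(member) {
    o <- colSums(counts[member, , drop = FALSE])
    f <- sum(xbar[member]) / total_xbar
    e <- f * t_j
    y <- rep(NA_real_, length(e))
    ok <- e > 0
    y[ok] <- (o[ok] - e[ok]) / e[ok]
    if (any(!ok)) warn("zero expected counts; deviation set to NA")
    y
  }

  # accessibility bins on cross-sample mean counts
  brk <- unique(quantile(xbar, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(xbar, breaks = brk, include.lowest = TRUE, labels = FALSE)
  bin_pool <- split(seq_along(xbar), bins)

  withr::with_seed(seed, {
    res <- purrr::map(rownames(m), function(tr) {
      member <- which(m[tr, ])
      y <- raw_dev(member)
      prof <- table(bins[member])
      bg <- vapply(seq_len(n_background), function(b) {
        bg_idx <- unlist(lapply(names(prof), function(bn) {
          pool <- bin_pool[[bn]]
          k <- prof[[bn]]
          if (length(pool) <= k) pool else sample(pool, k)
        }), use.names = FALSE)
        raw_dev(bg_idx)
      }, numeric(ncol(counts)))
      if (ncol(counts) == 1) bg <- matrix(bg, nrow = 1)
      mu_bg <- rowMeans(bg)
      sd_bg <- apply(bg, 1, sd)
      z <- (y - mu_bg) / sd_bg
      z[sd_bg == 0] <- NA_real_
      tibble::tibble(
        trait = tr, sample_id = colnames(counts),
        deviation = y, z = z
      )
    })
  })
  dplyr::bind_rows(res)
}

#' Average deviation scores per cell type
#'
#' @param deviations Tibble from [deviation_scores()].
#' @param meta Sample metadata tibble.
#' @return A tibble with columns `trait`, `cell_type`, `mean_deviation`,
#'   `mean_z`.
#' @export
enrichment_by_cell_type <- function(deviations, meta) {
  meta <- validate_metadata(meta)
  missing <- setdiff(unique(deviations$sample_id), meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("sample id not in metadata: ", missing[1]))
  }
  deviations |>
    dplyr::inner_join(
      meta[, c("sample_id", "cell_type")],
      by = "sample_id"
    ) |>
    dplyr::group_by(.data$trait, .data$cell_type) |>
    dplyr::summarise(
      mean_deviation = mean(.data$deviation),
      mean_z = mean(.data$z),
      .groups = "drop"
    )
}

#' Sweep SNP-set enrichment across association thresholds
#'
#' Runs the full deviation-scoring stage (catalog filtering, peak overlap,
#' deviation scores, per-cell-type averaging) at each association p-value
#' threshold, the standard sweep being 0.05, 1e-3, 1e-5, 1e-6, 1e-8.
#'
#' @param catalog Catalog tibble (0-based positions).
#' @param x An `atac_matrix` with metadata.
#' @param peaks Peak tibble matching `x`.
#' @param thresholds Numeric vector of association p thresholds.
#' @param min_snps Minimal SNPs per trait after filtering (default 20).
#' @param n_background,n_bins,seed Passed to [deviation_scores()].
#' @return A long tibble with columns `threshold`, `trait`, `cell_type`,
#'   `mean_deviation`, `mean_z`.
#' @export
snp_enrichment_sweep <- function(catalog, x, peaks,
                                 thresholds = c(0.05, 1e-3, 1e-5, 1e-6, 1e-8),
                                 min_snps = 20, n_background = 50,
                                 n_bins = 10, seed) {
  if (missing(seed)) abort("seed is required")
  if (is.null(x$meta)) abort("sample metadata required")
  purrr::map(thresholds, function(thr) {
    kept <- filter_catalog(catalog, thr, min_snps = min_snps)
    if (nrow(kept) == 0) {
      return(tibble::tibble(
        threshold = numeric(), trait = character(),
        cell_type = character(), mean_deviation = numeric(),
        mean_z = numeric()
      ))
    }
    membership <- overlap_traits_peaks(kept, peaks)
    dev <- deviation_scores(
      membership, x,
      n_background = n_background, n_bins = n_bins, seed = seed
    )
    enr <- enrichment_by_cell_type(dev, x$meta)
    dplyr::mutate(enr, threshold = thr, .before = 1)
  }) |>
    dplyr::bind_rows()
}
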