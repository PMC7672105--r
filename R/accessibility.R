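#' Construct an accessibility matrix object
#'
#' The backbone container of the pipeline: an N x M matrix of raw read
#' counts (peaks by samples) together with the peak coordinates and sample
#' metadata. Normalized counts and log2 intensities are filled in by
#' [quantile_normalize()] and [peak_intensity()].
#'
#' @param counts Integer matrix, peaks in rows (rownames are peak ids),
#'   samples in columns (colnames are sample ids). All values must be
#'   non-negative integers.
#' @param peaks Optional peak tibble (`chrom`, `start`, `end`, `peak_id`)
#'   covering every row of `counts`, in any order.
#' @param meta Optional sample metadata tibble with columns `sample_id`,
#'   `cell_type`, `state`, `donor_id` covering every column of `counts`.
#' @return An object of class `atac_matrix`: a list with elements `counts`,
#'   `peaks`, `meta`, and (once computed) `normalized` and `intensity`.
#' @export
atac_matrix <- function(counts, peaks = NULL, meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("counts must have peak ids as rownames")
  if (is.null(colnames(counts))) {
    abort("counts must have sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(paste0(
      "duplicate peak id in counts: ",
      rownames(counts)[duplicated(rownames(counts))][1]
    ))
  }
  if (anyDuplicated(colnames(counts))) abort("duplicate sample id in counts")
  if (any(counts < 0)) abort("raw counts must be non-negative")
  if (any(counts != round(counts))) abort("raw counts must be integers")
  storage.mode(counts) <- "double"
  if (!is.null(peaks)) {
    validate_peaks(peaks)
    missing <- setdiff(rownames(counts), peaks$peak_id)
    if (length(missing) > 0) {
      abort(paste0("peak ", missing[1], " absent from peak table"))
    }
    peaks <- peaks[match(rownames(counts), peaks$peak_id), ]
  }
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    missing <- setdiff(colnames(counts), meta$sample_id)
    if (length(missing) > 0) {
      abort(paste0("sample ", missing[1], " absent from metadata"))
    }
    meta <- meta[match(colnames(counts), meta$sample_id), ]
  }
  structure(
    list(
      counts = counts, peaks = peaks, meta = meta,
      normalized = NULL, intensity = NULL
    ),
    class = "atac_matrix"
  )
}

#' @export
print.atac_matrix <- function(x, ...) {
  cat(
    "<atac_matrix> ", nrow(x$counts), " peaks x ", ncol(x$counts),
    " samples\n",
    sep = ""
  )
  cat(
    "  normalized: ", !is.null(x$normalized),
    " | intensity: ", !is.null(x$intensity), "\n",
    sep = ""
  )
  if (!is.null(x$meta)) {
    ct <- table(x$meta$cell_type)
    cat(
      "  cell types: ",
      paste0(names(ct), " (", as.integer(ct), ")", collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
dim.atac_matrix <- function(x) dim(x$counts)

#' Validate a sample metadata table
#'
#' Checks that the metadata carries unique sample ids and that the clinical
#' state labels come from the closed set `normal`, `unaffected`, `affected`.
#'
#' @param meta Data frame with columns `sample_id`, `cell_type`, `state`,
#'   `donor_id`.
#' @return The metadata as a tibble, invisibly usable downstream.
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "cell_type", "state", "donor_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  valid_states <- c("normal", "unaffected", "affected")
  bad <- setdiff(unique(meta$state), valid_states)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown clinical state '", bad[1], "'; must be one of ",
      paste(valid_states, collapse = ", ")
    ))
  }
  tibble::as_tibble(meta)
}

#' Read a peak-by-sample count matrix from TSV
#'
#' Expects a tab-delimited file whose header row holds sample ids and whose
#' first column holds peak ids. Raw counts must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @param peaks,meta Optional peak table and sample metadata passed on to
#'   [atac_matrix()].
#' @return An [atac_matrix()] object.
#' @export
read_count_matrix <- function(path, peaks = NULL, meta = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(tab) < 2) abort("count matrix needs a peak-id column and >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate peak id in ", path, ": ", ids[duplicated(ids)][1]))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric count in matrix")
  if (any(m != round(m)) || any(m < 0)) {
    abort("raw counts must be non-negative integers")
  }
  rownames(m) <- ids
  atac_matrix(m, peaks = peaks, meta = meta)
}

#' Write the raw counts of an accessibility matrix to TSV
#'
#' Inverse of [read_count_matrix()]: a round-trip through
#' `read_count_matrix(write_count_matrix(x, path))` preserves raw counts,
#' peak ids and sample ids exactly.
#'
#' @param x An `atac_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "atac_matrix"))
  tab <- tibble::as_tibble(x$counts, rownames = "peak_id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `cell_type`, `state`,
#'   `donor_id`.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_metadata(meta)
}

#' Quantile-normalize an accessibility matrix
#'
#' Forces every sample (column) onto a common empirical distribution: after
#' normalization the sorted value vector of each column is identical, each
#' rank carrying the mean of the rank-k raw values across columns. Ties are
#' resolved by averaging the reference values over the tied ranks (the
#' classic rank-mean algorithm), which keeps every column's total equal to
#' the reference total even in the presence of ties.
#'
#' @param x An `atac_matrix` with at least two samples.
#' @return `x` with the `normalized` slot filled.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "atac_matrix"))
  if (ncol(x$counts) < 2) {
    abort("quantile normalization needs at least 2 samples")
  }
  ref <- rowMeans(apply(x$counts, 2, sort))
  norm <- apply(x$counts, 2, function(col) {
    out <- numeric(length(col))
    out[order(col)] <- ref
    # tied values share the mean of the reference values spanning their run
    stats::ave(out, col, FUN = mean)
  })
  dimnames(norm) <- dimnames(x$counts)
  x$normalized <- norm
  x
}

#' Compute log2 peak intensities
#'
#' Peak intensity is `log2(normalized + 1)`: the log2 of the
#' quantile-normalized read count with a unit pseudocount so that empty
#' peaks map to zero and all intensities are finite.
#'
#' @param x An `atac_matrix` that has been through [quantile_normalize()].
#' @return `x` with the `intensity` slot filled.
#' @export
peak_intensity <- function(x) {
  stopifnot(inherits(x, "atac_matrix"))
  if (is.null(x$normalized)) {
    abort("run quantile_normalize() before peak_intensity()")
  }
  if (any(x$normalized < 0)) abort("negative normalized value")
  x$intensity <- log2(x$normalized + 1)
  x
}

# Intensity slot with a friendly error; most downstream stages start here.
get_intensity <- function(x) {
  stopifnot(inherits(x, "atac_matrix"))
  if (is.null(x$intensity)) {
    abort(
      "intensities absent: run quantile_normalize() then peak_intensity()"
    )
  }
  x$intensity
}

#' Tidy an accessibility matrix into long format
#'
#' @param x An `atac_matrix`.
#' @param ... Unused.
#' @return A long tibble with columns `peak_id`, `sample_id`, `count`, and
#'   `normalized` / `intensity` when computed.
#' @export
tidy.atac_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$counts, rownames = "peak_id") |>
    tidyr::pivot_longer(-"peak_id",
      names_to = "sample_id", values_to = "count"
    )
  if (!is.null(x$normalized)) {
    long$normalized <- as.vector(t(x$normalized))
  }
  if (!is.null(x$intensity)) {
    long$intensity <- as.vector(t(x$intensity))
  }
  long
}

#' One-line summary of an accessibility matrix
#'
#' @param x An `atac_matrix`.
#' @param ... Unused.
#' @return A one-row tibble with peak/sample counts and processing state.
#' @export
glance.atac_matrix <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$counts),
    n_samples = ncol(x$counts),
    normalized = !is.null(x$normalized),
    intensity = !is.null(x$intensity),
    n_cell_types = if (is.null(x$meta)) NA_integer_ else
      dplyr::n_distinct(x$meta$cell_type)
  )
}
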