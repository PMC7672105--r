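#' Read a peak set from a BED file
#'
#' Reads a BED3+ file of peak coordinates into a peak tibble. Coordinates
#' follow the BED convention: 0-based starts, half-open `[start, end)`
#' intervals. When a fourth (name) column is present it is used as the
#' `peak_id`; otherwise ids of the form `"chrom:start-end"` are generated.
#'
#' @param path Path to a tab-delimited BED file with at least three columns
#'   (chrom, start, end).
#' @return A tibble with columns `chrom`, `start`, `end`, `peak_id`, one row
#'   per peak, in file order.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t600", "chr1\t800\t1300"), bed)
#' read_peaks_bed(bed)
read_peaks_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(),
      end = integer(), peak_id = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0(
      "malformed BED line (fewer than 3 columns) at line ",
      which(nf < 3)[1]
    ))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("non-integer coordinate at line ", bad[1]))
  }
  peak_id <- ifelse(
    nf >= 4,
    vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", character(1)),
    paste0(chrom, ":", start, "-", end)
  )
  peaks <- tibble::tibble(
    chrom = chrom, start = start, end = end, peak_id = peak_id
  )
  validate_peaks(peaks)
  peaks
}

#' Write a peak set to a BED file
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`, `peak_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  validate_peaks(peaks)
  readr::write_tsv(
    peaks[, c("chrom", "start", "end", "peak_id")], path,
    col_names = FALSE
  )
  invisible(path)
}

# Shared interval sanity checks; `what` names the offending record type in
# error messages.
validate_intervals <- function(x, what = "interval") {
  if (any(!nzchar(x$chrom))) abort(paste0("empty chrom in ", what, " set"))
  if (any(x$start < 0)) {
    abort(paste0("negative start coordinate in ", what, " set"))
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(paste0(
      what, " with end <= start at line ", bad[1], " (",
      x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]], ")"
    ))
  }
  invisible(x)
}

validate_peaks <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(peaks)))
  validate_intervals(peaks, "peak")
  if (anyDuplicated(peaks$peak_id)) {
    abort(paste0(
      "duplicate peak_id: ",
      peaks$peak_id[duplicated(peaks$peak_id)][1]
    ))
  }
  invisible(peaks)
}

# Peak midpoint used for all distance computations: floor((start + end) / 2).
peak_center <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}
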