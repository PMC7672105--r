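#' Read mapped reads or intervals from a BED6-like file
#'
#' @param path Tab-delimited file with columns chrom, start, end and
#'   optionally name, score, strand.
#' @return A tibble with columns `chrom`, `start`, `end`, and `name`,
#'   `strand` when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  tab <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(), progress = FALSE
  )
  if (ncol(tab) < 3) abort("BED needs >= 3 columns")
  out <- tibble::tibble(
    chrom = as.character(tab[[1]]),
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]])
  )
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  if (ncol(tab) >= 6) out$strand <- as.character(tab[[6]])
  validate_intervals(out, "BED record")
  out
}

#' Derive Tn5 insertion positions from mapped reads
#'
#' Shifts each mapped read so that its first base marks the Tn5 cleavage
#' (insertion) position: plus-strand reads are shifted +4 bp from the read
#' start, minus-strand reads -5 bp from the read's 5' base (the last
#' aligned base, `end - 1` in 0-based coordinates). Shifted positions that
#' fall below zero are dropped (count reported via a message). The result
#' carries a provenance flag so an accidental second shift errors rather
#' than silently moving insertions again.
#'
#' @param reads Tibble with columns `chrom`, `start`, `end`, `strand`.
#' @return A tibble of class `tn5_insertions` with columns `chrom`, `pos`
#'   (plus any `group` column carried through).
#' @export
tn5_shift <- function(reads) {
  if (inherits(reads, "tn5_insertions")) {
    abort("input already carries Tn5-shifted insertions; refusing to shift twice")
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  validate_intervals(reads, "read")
  bad <- setdiff(unique(reads$strand), c("+", "-"))
  if (length(bad) > 0) abort(paste0("invalid strand '", bad[1], "'"))
  pos <- ifelse(
    reads$strand == "+",
    reads$start + 4L,
    reads$end - 1L - 5L
  )
  dropped <- pos < 0
  if (any(dropped)) {
    inform(paste0(
      sum(dropped), " read(s) dropped: shifted position < 0"
    ))
  }
  out <- tibble::tibble(chrom = reads$chrom[!dropped], pos = pos[!dropped])
  if ("group" %in% names(reads)) out$group <- reads$group[!dropped]
  class(out) <- c("tn5_insertions", class(out))
  out
}

#' Equalize insertion depth across sample groups
#'
#' Randomly samples, without replacement, the same number of insertions
#' from every group so that aggregate footprints are comparable across
#' conditions regardless of sequencing depth.
#'
#' @param insertions Tibble with columns `chrom`, `pos`, `group`.
#' @param n Number of insertions to keep per group, or `"min"` (default)
#'   for the smallest group's depth.
#' @param seed Integer seed (required).
#' @return The downsampled insertion tibble (same columns).
#' @export
downsample_insertions <- function(insertions, n = "min", seed) {
  if (missing(seed)) abort("seed is required")
  stopifnot(all(c("chrom", "pos", "group") %in% names(insertions)))
  sizes <- table(insertions$group)
  if (identical(n, "min")) n <- min(sizes)
  n <- as.integer(n)
  if (any(sizes < n)) {
    abort(paste0(
      "group ", names(sizes)[which(sizes < n)[1]], " has only ",
      min(sizes), " insertions; use n = \"min\""
    ))
  }
  cls <- class(insertions)
  withr::with_seed(seed, {
    out <- insertions |>
      dplyr::group_by(.data$group) |>
      dplyr::slice_sample(n = n) |>
      dplyr::ungroup()
  })
  class(out) <- cls
  out
}

#' Aggregate Tn5 insertion footprint around motif sites
#'
#' Averages insertion counts over aligned motif sites: for every site,
#' insertions are binned by their offset from the site center (the
#' midpoint `floor((start + end) / 2)`); minus-strand sites are mirrored so
#' that offsets run in motif orientation. The profile is the per-offset
#' mean insertion count per site over a window of `2 * halfwidth + 1`
#' positions — a dip at the center relative to the flanks is the footprint
#' of a bound factor protecting its motif from transposition.
#'
#' @param insertions Insertion tibble (`chrom`, `pos`, optional `group`).
#'   When a `group` column is present a profile is computed per group.
#' @param motif_sites Tibble with columns `chrom`, `start`, `end` and
#'   optional `strand` (default `+`).
#' @param halfwidth Window half-width in bp (default 50: a 101-position
#'   profile spanning the 100 bp region centered on the motif).
#' @return A tibble of class `footprint_profile` with columns `group`,
#'   `offset` (-halfwidth..halfwidth), `mean_insertions`, and attribute
#'   `n_sites`.
#' @export
aggregate_footprint <- function(insertions, motif_sites, halfwidth = 50) {
  stopifnot(all(c("chrom", "pos") %in% names(insertions)))
  validate_intervals(motif_sites, "motif site")
  if (nrow(motif_sites) == 0) abort("no motif sites")
  motif_len <- unique(motif_sites$end - motif_sites$start)
  if (length(motif_len) > 1) {
    abort("motif sites must all have the same length")
  }
  if (halfwidth < motif_len / 2) {
    abort("halfwidth smaller than half the motif length")
  }
  if (!"strand" %in% names(motif_sites)) motif_sites$strand <- "+"
  if (!"group" %in% names(insertions)) insertions$group <- "all"
  centers <- peak_center(motif_sites)
  offsets <- -halfwidth:halfwidth
  res <- insertions |>
    dplyr::group_split(.data$group) |>
    purrr::map(function(ins) {
      grp <- ins$group[1]
      counts <- numeric(length(offsets))
      for (chr in unique(motif_sites$chrom)) {
        site_idx <- which(motif_sites$chrom == chr)
        p <- sort(ins$pos[ins$chrom == chr])
        if (length(p) == 0) next
        for (s in site_idx) {
          ctr <- centers[s]
          lo <- findInterval(ctr - halfwidth - 1L, p) + 1L
          hi <- findInterval(ctr + halfwidth, p)
          if (hi < lo) next
          off <- p[lo:hi] - ctr
          if (motif_sites$strand[s] == "-") off <- -off
          tab <- table(factor(off, levels = offsets))
          counts <- counts + as.numeric(tab)
        }
      }
      tibble::tibble(
        group = grp, offset = offsets,
        mean_insertions = counts / nrow(motif_sites)
      )
    }) |>
    dplyr::bind_rows()
  structure(
    res,
    class = c("footprint_profile", class(res)),
    n_sites = nrow(motif_sites), halfwidth = halfwidth
  )
}

#' @export
glance.footprint_profile <- function(x, ...) {
  hw <- attr(x, "halfwidth")
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_sites = attr(x, "n_sites"),
      total_mass = sum(.data$mean_insertions),
      center_mean = mean(
        .data$mean_insertions[abs(.data$offset) <= ceiling(hw / 5)]
      ),
      flank_mean = mean(
        .data$mean_insertions[abs(.data$offset) >= floor(hw * 0.7)]
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(protection = 1 - .data$center_mean / .data$flank_mean)
}

#' Footprint profile plot
#'
#' @param object A `footprint_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.footprint_profile <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(
      x = .data$offset, y = .data$mean_insertions, colour = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "offset from motif center (bp)",
      y = "mean insertions per site", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
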