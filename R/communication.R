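#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns `ligand`, `receptor` and optional `source`.
#' @return A tibble with columns `ligand`, `receptor`, `source`.
#' @export
read_lr_pairs <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  as_lr_pairs(tab)
}

#' Coerce a data frame to a ligand-receptor pair table
#'
#' @param pairs Data frame with `ligand`, `receptor` columns.
#' @return A tibble with columns `ligand`, `receptor`, `source`.
#' @export
as_lr_pairs <- function(pairs) {
  stopifnot(all(c("ligand", "receptor") %in% names(pairs)))
  pairs <- tibble::as_tibble(pairs)
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor))) {
    abort("empty gene name in ligand-receptor table")
  }
  dup <- duplicated(pairs[, c("ligand", "receptor")])
  if (any(dup)) pairs <- pairs[!dup, ]
  pairs[, c("ligand", "receptor", "source")]
}

#' Per-gene alteration scores from chromatin accessibility
#'
#' The Alteration Score (AS) of a gene in a cell type measures how its
#' chromatin-predicted expression changes in affected versus normal cells:
#' the log2 ratio of the mean gene-level accessibility (summed peak
#' intensities, averaged over replicate samples of the cell type and
#' state), with a unit pseudocount keeping the score finite at zero
#' accessibility. AS is 0 when affected and normal accessibility are
#' equal.
#'
#' @param gene_acc Gene-level accessibility tibble from
#'   [gene_accessibility()] (`gene_id`, `sample_id`, `accessibility`).
#' @param meta Sample metadata tibble.
#' @param affected_state,normal_state State labels to contrast (defaults
#'   `"affected"` and `"normal"`).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return A tibble with columns `cell_type`, `gene_id`, `as` (NA when a
#'   gene lacks data in either condition).
#' @export
alteration_scores <- function(gene_acc, meta,
                              affected_state = "affected",
                              normal_state = "normal",
                              pseudocount = 1) {
  meta <- validate_metadata(meta)
  joined <- gene_acc |>
    dplyr::inner_join(
      meta[, c("sample_id", "cell_type", "state")],
      by = "sample_id"
    ) |>
    dplyr::filter(.data$state %in% c(affected_state, normal_state))
  joined |>
    dplyr::group_by(.data$cell_type, .data$gene_id) |>
    dplyr::summarise(
      mean_aff = mean(.data$accessibility[.data$state == affected_state]),
      mean_norm = mean(.data$accessibility[.data$state == normal_state]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      as = log2((.data$mean_aff + pseudocount) /
        (.data$mean_norm + pseudocount)),
      as = ifelse(is.nan(.data$as), NA_real_, .data$as)
    ) |>
    dplyr::select("cell_type", "gene_id", "as")
}

#' Strength of Interaction Alteration (SIA)
#'
#' Combines the receptor's and ligand's alteration scores into one
#' interaction-level score:
#' `SIA = 0` when `|AS_receptor| < 1` or `|AS_ligand| < 1` (neither side
#' altered enough), otherwise `SIA = AS_receptor + AS_ligand`. With
#' `concordance_required = TRUE` (default) discordant signs — one side up,
#' the other down — also yield 0, so a non-zero SIA always represents a
#' wholly up- or down-regulated interaction.
#'
#' @param as_receptor,as_ligand Numeric vectors of alteration scores
#'   (recycled to common length).
#' @param concordance_required Zero out sign-discordant pairs (default
#'   TRUE).
#' @return Numeric vector of SIA values (NA propagates).
#' @export
sia <- function(as_receptor, as_ligand, concordance_required = TRUE) {
  n <- max(length(as_receptor), length(as_ligand))
  r <- rep_len(as_receptor, n)
  l <- rep_len(as_ligand, n)
  out <- r + l
  out[abs(r) < 1 | abs(l) < 1] <- 0
  if (concordance_required) out[sign(r) != sign(l)] <- 0
  out[is.na(r) | is.na(l)] <- NA_real_
  out
}

#' Altered receptor-ligand interactions between cell types
#'
#' Evaluates every ordered (receiver, sender) cell-type pair against every
#' known ligand-receptor pair: the SIA combines the receptor's alteration
#' score in the receiver with the ligand's in the sender, and interactions
#' with `|SIA|` strictly greater than `threshold` are retained, direction
#' by sign (positive = up-regulated in the affected state).
#'
#' @param as_table Alteration scores from [alteration_scores()].
#' @param lr_pairs Ligand-receptor table ([as_lr_pairs()]).
#' @param cell_types Cell types to consider (default: all in `as_table`).
#' @param threshold Retention threshold on `|SIA|` (strict `>`; default 7).
#' @param concordance_required Passed to [sia()].
#' @param include_self Evaluate a cell type signalling to itself (default
#'   TRUE).
#' @return A tibble with columns `sender`, `receiver`, `ligand`,
#'   `receptor`, `as_ligand`, `as_receptor`, `sia`, `direction`
#'   (`up` / `down`), retained interactions only.
#' @export
altered_interactions <- function(as_table, lr_pairs, cell_types = NULL,
                                 threshold = 7, concordance_required = TRUE,
                                 include_self = TRUE) {
  lr_pairs <- as_lr_pairs(lr_pairs)
  if (is.null(cell_types)) cell_types <- unique(as_table$cell_type)
  if (nrow(lr_pairs) == 0) {
    return(tibble::tibble(
      sender = character(), receiver = character(),
      ligand = character(), receptor = character(),
      as_ligand = numeric(), as_receptor = numeric(),
      sia = numeric(), direction = character()
    ))
  }
  grid <- tidyr::expand_grid(
    sender = cell_types, receiver = cell_types, lr_pairs
  )
  if (!include_self) grid <- grid[grid$sender != grid$receiver, ]
  as_key <- paste(as_table$cell_type, as_table$gene_id)
  grid$as_ligand <- as_table$as[match(
    paste(grid$sender, grid$ligand), as_key
  )]
  grid$as_receptor <- as_table$as[match(
    paste(grid$receiver, grid$receptor), as_key
  )]
  skipped <- is.na(grid$as_ligand) | is.na(grid$as_receptor)
  if (any(skipped)) {
    inform(paste0(
      sum(skipped),
      " (cell-type pair, ligand-receptor pair) combinations skipped: ",
      "missing alteration score"
    ))
    grid <- grid[!skipped, ]
  }
  grid$sia <- sia(
    grid$as_receptor, grid$as_ligand,
    concordance_required = concordance_required
  )
  kept <- grid[abs(grid$sia) > threshold, ]
  kept$direction <- ifelse(kept$sia > 0, "up", "down")
  kept[, c(
    "sender", "receiver", "ligand", "receptor",
    "as_ligand", "as_receptor", "sia", "direction"
  )]
}

#' Per-cell-type summary of altered interactions
#'
#' Counts, for every cell type, the retained up- and down-regulated
#' interactions in which it participates as sender or receiver (an
#' interaction of a cell type with itself is counted once).
#'
#' @param interactions Tibble from [altered_interactions()].
#' @param cell_types Optional cell types to report (default: those
#'   appearing in `interactions`).
#' @return A tibble with columns `cell_type`, `n_up`, `n_down`, sorted by
#'   `n_up` decreasing.
#' @export
interaction_summary <- function(interactions, cell_types = NULL) {
  if (is.null(cell_types)) {
    cell_types <- sort(unique(c(interactions$sender, interactions$receiver)))
  }
  if (length(cell_types) == 0) {
    return(tibble::tibble(
      cell_type = character(), n_up = integer(), n_down = integer()
    ))
  }
  counts <- purrr::map(cell_types, function(ct) {
    involved <- interactions$sender == ct | interactions$receiver == ct
    tibble::tibble(
      cell_type = ct,
      n_up = sum(involved & interactions$direction == "up"),
      n_down = sum(involved & interactions$direction == "down")
    )
  }) |>
    dplyr::bind_rows()
  dplyr::arrange(counts, dplyr::desc(.data$n_up))
}

#' Bar chart of up/down interaction counts per cell type
#'
#' @param interactions Tibble from [altered_interactions()].
#' @return A ggplot object.
#' @export
plot_interaction_summary <- function(interactions) {
  s <- interaction_summary(interactions) |>
    tidyr::pivot_longer(
      c("n_up", "n_down"),
      names_to = "direction", values_to = "n"
    ) |>
    dplyr::mutate(
      direction = ifelse(.data$direction == "n_up", "up", "down")
    )
  ggplot2::ggplot(
    s,
    ggplot2::aes(
      x = .data$cell_type, y = .data$n, fill = .data$direction
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(up = "firebrick", down = "steelblue")
    ) +
    ggplot2::labs(x = NULL, y = "altered interactions", fill = NULL) +
    ggplot2::theme_minimal()
}
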