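# Expression tables are tibbles with a gene_id first column and one column
# per array; coerce matrix-with-rownames input too.
as_expression <- function(expr) {
  if (is.matrix(expr)) {
    expr <- tibble::as_tibble(expr, rownames = "gene_id")
  }
  stopifnot("gene_id" %in% names(expr))
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene_id in expression")
  if (anyDuplicated(setdiff(names(expr), "gene_id"))) {
    abort("duplicate array id in expression")
  }
  tibble::as_tibble(expr)
}

validate_clinical <- function(clinical) {
  required <- c("array_id", "patient_id", "timepoint", "mrss", "phase")
  missing <- setdiff(required, names(clinical))
  if (length(missing) > 0) {
    abort(paste0("clinical table lacks: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(clinical[, c("patient_id", "timepoint")])) {
    abort("duplicate (patient, timepoint) in clinical table")
  }
  if (any(clinical$mrss < 0)) abort("negative mRSS")
  bad <- setdiff(unique(clinical$phase), c("baseline", "treated"))
  if (length(bad) > 0) {
    abort(paste0("unknown treatment phase '", bad[1], "'"))
  }
  tibble::as_tibble(clinical)
}

#' Derive cell-type signature gene sets from specific peaks
#'
#' The signature genes of a cell type are the deduplicated nearest genes of
#' its specific peaks.
#'
#' @param specific_calls Tibble from [cell_type_specific_peaks()] (rows
#'   with `specific = TRUE` are used; pre-filtered tibbles work too).
#' @param annotation Peak-to-gene annotation from
#'   [annotate_nearest_gene()].
#' @return A tibble with columns `cell_type`, `gene_id`.
#' @export
signature_genes <- function(specific_calls, annotation) {
  calls <- specific_calls
  if ("specific" %in% names(calls)) calls <- calls[calls$specific, ]
  if (nrow(calls) == 0) {
    warn("no specific peaks; empty signature gene sets")
    return(tibble::tibble(cell_type = character(), gene_id = character()))
  }
  calls |>
    dplyr::inner_join(
      annotation[, c("peak_id", "gene_id")],
      by = "peak_id"
    ) |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::distinct(.data$cell_type, .data$gene_id)
}

#' Identify treatment-response genes
#'
#' Per-gene two-sided Welch t-test of treated versus baseline arrays; a
#' gene responds to treatment when `|log2fc| > lfc_thr` and `p < p_thr`.
#' Response genes are removed from signature sets before clinical
#' correlation so that drug effects do not masquerade as disease biology.
#'
#' @param expr Expression table (`gene_id` column plus one column per
#'   array) of normalized values.
#' @param clinical Clinical table with `array_id` and `phase`
#'   (`baseline` / `treated`).
#' @param lfc_thr,p_thr Selection thresholds (defaults 2 and 0.005).
#' @return A tibble with columns `gene_id`, `log2fc`
#'   (treated - baseline), `p` for the selected genes.
#' @export
treatment_response_genes <- function(expr, clinical, lfc_thr = 2,
                                     p_thr = 0.005) {
  expr <- as_expression(expr)
  clinical <- validate_clinical(clinical)
  arrays <- intersect(names(expr), clinical$array_id)
  phase <- clinical$phase[match(arrays, clinical$array_id)]
  base_ids <- arrays[phase == "baseline"]
  trt_ids <- arrays[phase == "treated"]
  if (length(base_ids) < 2 || length(trt_ids) < 2) {
    abort("both treatment phases need >= 2 arrays")
  }
  m <- as.matrix(expr[, arrays])
  rownames(m) <- expr$gene_id
  w <- row_welch_t(m[, trt_ids, drop = FALSE], m[, base_ids, drop = FALSE])
  sel <- abs(w$log2fc) > lfc_thr & w$p < p_thr
  tibble::tibble(
    gene_id = expr$gene_id[sel],
    log2fc = w$log2fc[sel],
    p = w$p[sel]
  )
}

#' Cell-type signature scores per array
#'
#' The signature score of a cell type in an array is the mean normalized
#' expression of its signature genes, after removing excluded genes
#' (typically treatment-response genes) and restricting to genes measured
#' on the array.
#'
#' @param expr Expression table.
#' @param gene_sets Tibble with columns `cell_type`, `gene_id` (from
#'   [signature_genes()]) or a named list of gene-id vectors.
#' @param exclude Character vector of gene ids to drop from every set.
#' @return A tibble with columns `cell_type`, `array_id`, `score`,
#'   `n_genes`.
#' @export
signature_scores <- function(expr, gene_sets, exclude = character()) {
  expr <- as_expression(expr)
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- purrr::imap(
      gene_sets,
      ~ tibble::tibble(cell_type = .y, gene_id = .x)
    ) |> dplyr::bind_rows()
  }
  arrays <- setdiff(names(expr), "gene_id")
  m <- as.matrix(expr[, arrays])
  rownames(m) <- expr$gene_id
  res <- gene_sets |>
    dplyr::distinct(.data$cell_type, .data$gene_id) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_map(function(g, key) {
      genes <- setdiff(g$gene_id, exclude)
      genes <- intersect(genes, rownames(m))
      if (length(genes) == 0) {
        warn(paste0(
          "signature of ", key$cell_type,
          " empty after exclusion; scores are NA"
        ))
        score <- rep(NA_real_, length(arrays))
      } else {
        score <- colMeans(m[genes, , drop = FALSE])
      }
      tibble::tibble(
        cell_type = key$cell_type, array_id = arrays,
        score = unname(score), n_genes = length(genes)
      )
    }) |>
    dplyr::bind_rows()
  res
}

#' Correlate signature scores with the clinical skin score
#'
#' Pearson correlation of each cell type's signature score against the
#' modified Rodnan skin score (mRSS) over paired arrays, with the
#' two-tailed t-statistic p-value on `n - 2` degrees of freedom.
#'
#' @param scores Tibble from [signature_scores()].
#' @param clinical Clinical table with `array_id` and `mrss`.
#' @return A tibble with columns `cell_type`, `r`, `p`, `n`.
#' @export
correlate_mrss <- function(scores, clinical) {
  clinical <- validate_clinical(clinical)
  joined <- dplyr::inner_join(
    scores, clinical[, c("array_id", "mrss")],
    by = "array_id"
  )
  joined |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_map(function(g, key) {
      g <- g[!is.na(g$score), ]
      n <- nrow(g)
      if (n < 3 || sd(g$score) == 0 || sd(g$mrss) == 0) {
        if (n >= 3) {
          warn(paste0(
            "zero variance for ", key$cell_type, "; correlation NA"
          ))
        }
        return(tibble::tibble(
          cell_type = key$cell_type, r = NA_real_, p = NA_real_, n = n
        ))
      }
      ct <- cor.test(g$score, g$mrss, method = "pearson")
      tibble::tibble(
        cell_type = key$cell_type,
        r = unname(ct$estimate), p = ct$p.value, n = n
      )
    }) |>
    dplyr::bind_rows()
}

#' Paired comparison of signature scores at lowest vs highest mRSS
#'
#' For every patient, selects the timepoints of minimal (`Low`) and maximal
#' (`High`) mRSS (ties broken by earliest timepoint), keeps patients whose
#' mRSS span is strictly greater than `min_delta`, and runs a paired
#' two-tailed t-test on `score_High - score_Low` per cell type.
#'
#' @param scores Tibble from [signature_scores()].
#' @param clinical Clinical table.
#' @param min_delta Minimal mRSS span for inclusion (strict `>`; default 5).
#' @return A tibble with columns `cell_type`, `t`, `p`, `n_patients`,
#'   `mean_delta` (mean High - Low score difference).
#' @export
paired_low_high <- function(scores, clinical, min_delta = 5) {
  clinical <- validate_clinical(clinical)
  picks <- clinical |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::summarise(
      low_array = .data$array_id[which.min(.data$mrss)],
      high_array = .data$array_id[which.max(.data$mrss)],
      delta = max(.data$mrss) - min(.data$mrss),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$delta > min_delta)
  if (nrow(picks) < 2) {
    abort("fewer than 2 patients exceed the mRSS span threshold")
  }
  score_of <- function(g, ids) g$score[match(ids, g$array_id)]
  scores |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_map(function(g, key) {
      lo <- score_of(g, picks$low_array)
      hi <- score_of(g, picks$high_array)
      d <- hi - lo
      if (sd(d, na.rm = TRUE) == 0) {
        # degenerate limit: no variance in the differences
        m <- mean(d, na.rm = TRUE)
        warn(paste0(
          "constant paired differences for ", key$cell_type,
          "; limit p-value reported"
        ))
        return(tibble::tibble(
          cell_type = key$cell_type,
          t = if (m == 0) 0 else sign(m) * Inf,
          p = if (m == 0) 1 else 0,
          n_patients = nrow(picks), mean_delta = m
        ))
      }
      tt <- t.test(hi, lo, paired = TRUE)
      tibble::tibble(
        cell_type = key$cell_type,
        t = unname(tt$statistic), p = tt$p.value,
        n_patients = nrow(picks), mean_delta = mean(d, na.rm = TRUE)
      )
    }) |>
    dplyr::bind_rows()
}

#' Scatter plot of signature score versus mRSS
#'
#' @param scores Tibble from [signature_scores()].
#' @param clinical Clinical table.
#' @return A ggplot object, one facet per cell type with a linear fit.
#' @export
plot_signature_mrss <- function(scores, clinical) {
  clinical <- validate_clinical(clinical)
  joined <- dplyr::inner_join(
    scores, clinical[, c("array_id", "mrss")],
    by = "array_id"
  )
  ggplot2::ggplot(
    joined, ggplot2::aes(x = .data$mrss, y = .data$score)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = "mRSS", y = "signature score") +
    ggplot2::theme_minimal()
}
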