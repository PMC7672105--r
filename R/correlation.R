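#' Pearson correlation of samples with hierarchical clustering
#'
#' Computes the sample-by-sample Pearson correlation of log2 intensities
#' over a peak subset (typically distal elements) and orders the samples by
#' average-linkage hierarchical clustering on the `1 - r` distance —
#' the unsupervised view used to check that samples group by cell type
#' rather than donor or batch.
#'
#' @param x An `atac_matrix` with intensities.
#' @param peak_ids Character vector of peak ids to use (default: all).
#' @return An object of class `sample_correlation`: list with `r` (M x M
#'   correlation matrix), `hclust` (the clustering), `order` (leaf order of
#'   sample ids).
#' @export
sample_correlation <- function(x, peak_ids = NULL) {
  intens <- get_intensity(x)
  if (!is.null(peak_ids)) {
    missing <- setdiff(peak_ids, rownames(intens))
    if (length(missing) > 0) {
      abort(paste0("unknown peak id in subset: ", missing[1]))
    }
    intens <- intens[peak_ids, , drop = FALSE]
  }
  if (nrow(intens) < 2) abort("need at least 2 peaks for correlation")
  sds <- apply(intens, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(
      "zero-variance sample(s): ",
      paste(colnames(intens)[sds == 0], collapse = ", "),
      "; their correlations are NA"
    ))
  }
  r <- suppressWarnings(cor(intens, method = "pearson"))
  diag(r) <- 1
  ok <- sds > 0
  hc <- NULL
  ord <- colnames(intens)
  if (sum(ok) >= 2) {
    d <- as.dist(1 - r[ok, ok, drop = FALSE])
    hc <- hclust(d, method = "average")
    ord <- c(colnames(intens)[ok][hc$order], colnames(intens)[!ok])
  }
  structure(
    list(r = r, hclust = hc, order = ord),
    class = "sample_correlation"
  )
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat("<sample_correlation> ", nrow(x$r), " samples\n", sep = "")
  cat("  leaf order: ", paste(x$order, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a sample correlation into long format
#'
#' @param x A `sample_correlation`.
#' @param ... Unused.
#' @return Tibble with columns `sample_a`, `sample_b`, `r`.
#' @export
tidy.sample_correlation <- function(x, ...) {
  tibble::as_tibble(x$r, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r")
}

#' Heatmap of sample correlations in clustered order
#'
#' @param object A `sample_correlation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_correlation <- function(object, ...) {
  long <- tidy(object)
  long$sample_a <- factor(long$sample_a, levels = object$order)
  long$sample_b <- factor(long$sample_b, levels = object$order)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$sample_a, y = .data$sample_b, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick",
      midpoint = 0, limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)
    )
}
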