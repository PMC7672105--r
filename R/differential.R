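# Vectorized two-sided Welch t-test over matrix rows.
# Zero-variance limit convention: se == 0 with equal means -> p = 1;
# se == 0 with unequal means -> p = 0.
row_welch_t <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
    tstat[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0, Inf)
  }
  list(
    log2fc = unname(ma - mb), t = unname(tstat),
    p = unname(p), df = unname(df)
  )
}

#' Differential accessibility between two sample groups
#'
#' Per-peak two-sided Welch t-test on log2 intensities with
#' Benjamini-Hochberg correction. The log2 fold change is the difference of
#' mean intensities (group A minus group B). A peak is significant when
#' `p < p_thr` and `|log2fc| > lfc_thr`; in `fc_only` mode (for conditions
#' with a single replicate, where a test has no power) the fold-change
#' criterion alone applies.
#'
#' @param x An `atac_matrix` with intensities.
#' @param group_a,group_b Character vectors of sample ids.
#' @param p_thr P-value threshold (strict `<`).
#' @param lfc_thr Absolute log2 fold-change threshold (strict `>`).
#' @param mode `"ttest"` (default; needs >= 2 samples per group) or
#'   `"fc_only"`.
#' @return A tibble of class `atac_differential` with columns `peak_id`,
#'   `log2fc`, `p`, `fdr`, `significant`. [glance()] summarises the call
#'   counts.
#' @export
differential_peaks <- function(x, group_a, group_b, p_thr = 0.05,
                               lfc_thr = 1, mode = c("ttest", "fc_only")) {
  mode <- match.arg(mode)
  intens <- get_intensity(x)
  missing <- setdiff(c(group_a, group_b), colnames(intens))
  if (length(missing) > 0) {
    abort(paste0("unknown sample id: ", missing[1]))
  }
  a <- intens[, group_a, drop = FALSE]
  b <- intens[, group_b, drop = FALSE]
  if (mode == "ttest") {
    if (ncol(a) < 2 || ncol(b) < 2) {
      abort(paste0(
        "t-test mode needs >= 2 samples per group; ",
        "use mode = \"fc_only\" for singleton groups"
      ))
    }
    w <- row_welch_t(a, b)
    res <- tibble::tibble(
      peak_id = rownames(intens),
      log2fc = w$log2fc,
      p = w$p,
      fdr = p.adjust(w$p, method = "BH"),
      significant = w$p < p_thr & abs(w$log2fc) > lfc_thr
    )
  } else {
    lfc <- unname(rowMeans(a) - rowMeans(b))
    res <- tibble::tibble(
      peak_id = rownames(intens),
      log2fc = lfc,
      p = NA_real_,
      fdr = NA_real_,
      significant = abs(lfc) > lfc_thr
    )
  }
  structure(
    res,
    class = c("atac_differential", class(res)),
    p_thr = p_thr, lfc_thr = lfc_thr, mode = mode
  )
}

#' @export
glance.atac_differential <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2fc > 0),
    n_down = sum(x$significant & x$log2fc < 0),
    p_thr = attr(x, "p_thr"),
    lfc_thr = attr(x, "lfc_thr"),
    mode = attr(x, "mode")
  )
}

#' Volcano plot of a differential result
#'
#' @param object An `atac_differential`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.atac_differential <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglog10p <- -log10(pmax(df$p, .Machine$double.xmin))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$log2fc, y = .data$neglog10p,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "log2 fold change (intensity)",
      y = "-log10 p", colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

# CV on the linear (normalized count) scale; mean 0 -> +Inf so the filter
# fails rather than divides by zero.
row_cv <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  cv <- rep(Inf, length(mu))
  pos <- mu > 0
  cv[pos] <- s[pos] / mu[pos]
  cv
}

#' Call cell-type-specific peaks (one-vs-rest)
#'
#' For every cell type, compares its samples against all other samples and
#' calls a peak specific when all four criteria hold simultaneously:
#' Welch t-test `p < p_thr`, log2 fold change of mean intensity
#' `> lfc_thr` (focal above rest), coefficient of variation of the
#' normalized counts within the focal cell type (`inCov`) `< in_cov`, and
#' across all remaining samples (`outCov`) `< out_cov`.
#'
#' @param x An `atac_matrix` with intensities and sample metadata.
#' @param p_thr,lfc_thr,in_cov,out_cov Filter thresholds (defaults 0.005,
#'   2, 0.5, 0.5).
#' @return A tibble with one row per (peak, cell type): `peak_id`,
#'   `cell_type`, `log2fc`, `p`, `in_cov`, `out_cov`, `specific`.
#' @export
cell_type_specific_peaks <- function(x, p_thr = 0.005, lfc_thr = 2,
                                     in_cov = 0.5, out_cov = 0.5) {
  intens <- get_intensity(x)
  if (is.null(x$meta)) abort("sample metadata required")
  norm <- x$normalized
  cts <- unique(x$meta$cell_type)
  res <- purrr::map(cts, function(ct) {
    focal <- x$meta$sample_id[x$meta$cell_type == ct]
    rest <- x$meta$sample_id[x$meta$cell_type != ct]
    if (length(focal) < 2 || length(rest) < 2) {
      abort(paste0(
        "cell type ", ct, " needs >= 2 focal and >= 2 other samples"
      ))
    }
    w <- row_welch_t(
      intens[, focal, drop = FALSE],
      intens[, rest, drop = FALSE]
    )
    icv <- row_cv(norm[, focal, drop = FALSE])
    ocv <- row_cv(norm[, rest, drop = FALSE])
    if (any(!is.finite(icv)) || any(!is.finite(ocv))) {
      warn(paste0(
        "zero-mean normalized counts for some peaks in ", ct,
        "; their CV is +Inf and the specificity filter fails"
      ))
    }
    is_specific <- w$p < p_thr & w$log2fc > lfc_thr &
      icv < in_cov & ocv < out_cov
    tibble::tibble(
      peak_id = rownames(intens),
      cell_type = ct,
      log2fc = w$log2fc,
      p = w$p,
      in_cov = icv,
      out_cov = ocv,
      specific = is_specific
    )
  })
  dplyr::bind_rows(res)
}

# Fixed six-state cluster dictionary over {normal, unaffected, affected};
# order doubles as the tie-break (C1 < ... < C6) after subset size.
six_state_patterns <- function() {
  list(
    C1 = "normal",
    C2 = c("normal", "unaffected"),
    C3 = "unaffected",
    C4 = c("unaffected", "affected"),
    C5 = "affected",
    C6 = c("normal", "affected")
  )
}

#' Six-state classification of differential peaks across clinical states
#'
#' Two-stage procedure for one cell type sampled in normal, clinically
#' unaffected and affected skin. Stage 1 gathers candidate peaks as the
#' union of significant peaks over the three pairwise state comparisons
#' (`p < p_thr`, `|log2fc| > lfc_thr`; fold-change-only when a state has a
#' single sample). Stage 2 assigns each candidate the enrichment pattern
#' `S` (one of six: normal-only, normal+unaffected, unaffected-only,
#' unaffected+affected, affected-only, normal+affected) for which every
#' in-`S` group mean exceeds every out-of-`S` group mean by more than
#' `sep`, provided every group's within-group intensity range stays below
#' `range_max`; candidates matching no pattern are `unassigned`. When
#' several patterns qualify, the smallest subset wins, then cluster order.
#'
#' @param x An `atac_matrix` with intensities and metadata.
#' @param cell_type Optional cell type to restrict to (default: use all
#'   samples, assumed to be one cell type).
#' @param p_thr,lfc_thr Stage-1 candidate thresholds (defaults 0.01, 2).
#' @param sep Minimal in-group vs out-group mean gap (default 0.8).
#' @param range_max Maximal within-group intensity range (default 1.5).
#' @return A tibble of class `six_state_classification` with columns
#'   `peak_id`, `cluster` (C1..C6 or `unassigned`) over the candidate
#'   peaks. [glance()] returns per-cluster counts and ratios (count over
#'   total candidates).
#' @export
classify_six_states <- function(x, cell_type = NULL, p_thr = 0.01,
                                lfc_thr = 2, sep = 0.8, range_max = 1.5) {
  intens <- get_intensity(x)
  if (is.null(x$meta)) abort("sample metadata required")
  meta <- x$meta
  if (!is.null(cell_type)) {
    meta <- meta[meta$cell_type == cell_type, ]
    if (nrow(meta) == 0) abort(paste0("no samples of cell type ", cell_type))
  }
  states <- c("normal", "unaffected", "affected")
  groups <- lapply(states, function(s) meta$sample_id[meta$state == s])
  names(groups) <- states
  n_per <- lengths(groups)
  if (any(n_per == 0)) {
    abort(paste0(
      "state(s) missing from samples: ",
      paste(states[n_per == 0], collapse = ", ")
    ))
  }
  # stage 1: union of pairwise significant peaks
  pairs <- utils::combn(states, 2, simplify = FALSE)
  cand <- character(0)
  for (pr in pairs) {
    mode <- if (min(n_per[pr]) >= 2) "ttest" else "fc_only"
    d <- differential_peaks(
      x, groups[[pr[1]]], groups[[pr[2]]],
      p_thr = p_thr, lfc_thr = lfc_thr, mode = mode
    )
    cand <- union(cand, d$peak_id[d$significant])
  }
  patterns <- six_state_patterns()
  if (length(cand) == 0) {
    warn("no candidate differential peaks between clinical states")
    res <- tibble::tibble(peak_id = character(), cluster = character())
  } else {
    gm <- vapply(
      groups,
      function(s) rowMeans(intens[cand, s, drop = FALSE]),
      numeric(length(cand))
    )
    gr <- vapply(
      groups,
      function(s) {
        m <- intens[cand, s, drop = FALSE]
        apply(m, 1, max) - apply(m, 1, min)
      },
      numeric(length(cand))
    )
    if (length(cand) == 1) {
      gm <- matrix(gm, nrow = 1, dimnames = list(cand, states))
      gr <- matrix(gr, nrow = 1, dimnames = list(cand, states))
    }
    # smallest qualifying subset wins, then C1 < ... < C6
    pat_order <- names(patterns)[order(lengths(patterns), seq_along(patterns))]
    cluster <- rep("unassigned", length(cand))
    ranges_ok <- apply(gr < range_max, 1, all)
    for (pat in pat_order) {
      in_s <- patterns[[pat]]
      out_s <- setdiff(states, in_s)
      gap_ok <- apply(
        gm[, in_s, drop = FALSE], 1, min
      ) - apply(gm[, out_s, drop = FALSE], 1, max) > sep
      hit <- cluster == "unassigned" & ranges_ok & gap_ok
      cluster[hit] <- pat
    }
    res <- tibble::tibble(peak_id = cand, cluster = cluster)
  }
  summary <- tibble::tibble(cluster = names(patterns)) |>
    dplyr::left_join(dplyr::count(res, .data$cluster), by = "cluster") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      ratio = if (nrow(res) > 0) .data$n / nrow(res) else 0
    )
  structure(
    res,
    class = c("six_state_classification", class(res)),
    summary = summary,
    n_candidates = nrow(res)
  )
}

#' @export
glance.six_state_classification <- function(x, ...) {
  attr(x, "summary")
}

#' Bar chart of six-state cluster ratios
#'
#' @param object A `six_state_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.six_state_classification <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot2::ggplot(
    s, ggplot2::aes(x = .data$cluster, y = .data$ratio)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "enrichment pattern",
      y = "fraction of differential peaks"
    ) +
    ggplot2::theme_minimal()
}
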