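test_that("BED parsing yields 0-based half-open peaks with generated ids", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(
    c("chr1\t100\t600", "chr1\t800\t1300", "chr2\t0\t50"),
    bed
  )
  peaks <- read_peaks_bed(bed)
  expect_equal(nrow(peaks), 3)
  expect_equal(peaks$peak_id[1], "chr1:100-600")
  expect_equal(peaks$start, c(100L, 800L, 0L))
  expect_equal(peaks$end, c(600L, 1300L, 50L))

  named <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tmyPeak", named)
  expect_equal(read_peaks_bed(named)$peak_id, "myPeak")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600", "chr1\t600\t100"), bad)
  expect_error(read_peaks_bed(bad), "line 2")

  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100", short)
  expect_error(read_peaks_bed(short), "line 1")
})

test_that("count matrix TSV round-trips raw counts and rejects bad input", {
  set.seed(7)
  counts <- matrix(
    rpois(30, 40), 6, 5,
    dimnames = list(sprintf("p%d", 1:6), sprintf("s%d", 1:5))
  )
  x <- atac_matrix(counts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(x, path)
  y <- read_count_matrix(path)
  expect_identical(unname(y$counts), unname(counts * 1.0))
  expect_identical(rownames(y$counts), rownames(counts))
  expect_identical(colnames(y$counts), colnames(counts))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peak\ts1\ts2", "p1\t1\t2", "p1\t3\t4"), dup)
  expect_error(read_count_matrix(dup), "duplicate peak id")

  frac <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peak\ts1\ts2", "p1\t1.5\t2"), frac)
  expect_error(read_count_matrix(frac), "integer")

  expect_error(atac_matrix(counts - 100), "non-negative")
})

test_that("quantile normalization equalizes columns and matches the rank-mean oracle", {
  x <- atac_matrix(matrix(
    c(1L, 3L, 2L, 4L), 2, 2,
    dimnames = list(c("p1", "p2"), c("s1", "s2"))
  ))
  x <- quantile_normalize(x)
  expect_equal(unname(x$normalized), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  same <- matrix(
    rep(c(5L, 9L, 1L), 3), 3, 3,
    dimnames = list(paste0("p", 1:3), paste0("s", 1:3))
  )
  xs <- quantile_normalize(atac_matrix(same))
  expect_equal(xs$normalized, xs$counts)

  set.seed(11)
  m <- matrix(
    sample.int(100000, 250), 50, 5, # distinct values: tie-free
    dimnames = list(sprintf("p%d", 1:50), sprintf("s%d", 1:5))
  )
  xr <- quantile_normalize(atac_matrix(m))
  sorted <- apply(xr$normalized, 2, sort)
  for (j in 2:5) expect_identical(sorted[, j], sorted[, 1])
  expect_equal(unname(xr$normalized), unname(qn_oracle(m)))
  # independent cross-check against limma on tie-free data
  expect_equal(
    unname(xr$normalized),
    unname(limma::normalizeQuantiles(m, ties = TRUE))
  )

  # with ties the sorted vectors need not coincide exactly, but every
  # column sum still equals the reference sum
  mt <- matrix(
    rpois(250, 20), 50, 5,
    dimnames = dimnames(m)
  )
  xm <- quantile_normalize(atac_matrix(mt))
  expect_equal(unname(xm$normalized), unname(qn_oracle(mt)))
  expect_equal(
    unname(colSums(xm$normalized)), rep(mean(colSums(mt)), 5)
  )

  # heavy ties: small integer support
  tied <- matrix(
    sample(0:3, 120, replace = TRUE), 30, 4,
    dimnames = list(sprintf("p%d", 1:30), sprintf("s%d", 1:4))
  )
  xt <- quantile_normalize(atac_matrix(tied))
  expect_equal(unname(xt$normalized), unname(qn_oracle(tied)))

  one_col <- matrix(1:3, 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
  expect_error(quantile_normalize(atac_matrix(one_col)), "2 samples")
})

test_that("quantile normalization conserves the per-column sum at the mean of column sums", {
  set.seed(3)
  m <- matrix(
    sample(1000:9999, 200), 40, 5, # distinct values: no ties
    dimnames = list(sprintf("p%d", 1:40), sprintf("s%d", 1:5))
  )
  x <- quantile_normalize(atac_matrix(m))
  expect_equal(
    unname(colSums(x$normalized)),
    rep(mean(colSums(m)), 5)
  )
})

test_that("intensity is log2(normalized + 1) and monotone", {
  x <- make_matrix(matrix(0, 2, 2))
  x$normalized <- cbind(c(3, 0), c(1, 7))
  x$intensity <- NULL
  x <- peak_intensity(x)
  expect_equal(x$intensity[1, 1], 2)
  expect_equal(x$intensity[2, 1], 0)
  expect_equal(x$intensity[1, 2], 1)
  expect_true(all(is.finite(x$intensity)))

  y <- atac_matrix(matrix(
    1:4, 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))
  ))
  expect_error(peak_intensity(y), "quantile_normalize")
})

test_that("nearest-gene annotation matches brute force with deterministic ties", {
  peaks <- tibble::tibble(
    chrom = "chr1", start = 400L, end = 600L, peak_id = "pk"
  )
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", tss = c(400L, 5000L),
    strand = "+"
  )
  ann <- annotate_nearest_gene(peaks, genes)
  expect_equal(ann$gene_id, "gA")
  expect_equal(ann$distance, 100)

  # equidistant: lexicographically smallest gene id wins
  genes2 <- tibble::tibble(
    gene_id = c("geneB", "geneA"), chrom = "chr1", tss = c(400L, 600L),
    strand = "+"
  )
  ann2 <- annotate_nearest_gene(peaks, genes2)
  expect_equal(ann2$gene_id, "geneA")

  # peak on an unannotated chromosome
  chrx <- tibble::tibble(
    chrom = "chrX", start = 0L, end = 10L, peak_id = "px"
  )
  annx <- annotate_nearest_gene(chrx, genes)
  expect_true(is.na(annx$gene_id))

  set.seed(5)
  for (rep in 1:5) {
    rp <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
      start = sample.int(10000, 20)
    )
    rp$end <- rp$start + sample(50:500, 20, replace = TRUE)
    rp$peak_id <- sprintf("p%02d", 1:20)
    rg <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:10),
      chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
      tss = sample.int(11000, 10), strand = "+"
    )
    expect_equal(
      annotate_nearest_gene(rp, rg),
      nearest_gene_oracle(rp, rg)
    )
  }
})

test_that("distal classification uses a strict 1 kb boundary", {
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 0L, 0L),
    end = c(2L, 2L, 2L), # centers at 1
    peak_id = c("near", "far", "edge")
  )
  # craft TSS distances of 999, 1001, 1000 from the centers
  genes <- tibble::tibble(
    gene_id = "g", chrom = "chr1", tss = 1000L, strand = "+"
  )
  mk <- function(center) {
    tibble::tibble(
      chrom = "chr1", start = center - 1L, end = center + 1L,
      peak_id = paste0("c", center)
    )
  }
  expect_equal(classify_distal(mk(1L), genes)$class, "proximal") # |d| = 999
  expect_equal(classify_distal(mk(2001L), genes)$class, "distal") # |d| = 1001
  expect_equal(classify_distal(mk(2000L), genes)$class, "proximal") # |d| = 1000
  # min_dist = 0: any nonzero distance is distal
  expect_equal(classify_distal(mk(1L), genes, min_dist = 0)$class, "distal")
  expect_equal(classify_distal(mk(1000L), genes, min_dist = 0)$class, "proximal")
})

test_that("gene accessibility sums exactly the peaks imputed to each gene", {
  x <- make_matrix(rbind(
    pk1 = c(2, 1),
    pk2 = c(3, 4),
    pk3 = c(5, 6)
  ))
  ann <- tibble::tibble(
    peak_id = c("pk1", "pk2", "pk3"),
    gene_id = c("gA", "gA", "gB"),
    distance = c(0, 10, -5)
  )
  ga <- gene_accessibility(x, ann)
  expect_equal(
    ga$accessibility[ga$gene_id == "gA" & ga$sample_id == "s01"], 5
  )
  expect_equal(
    ga$accessibility[ga$gene_id == "gB" & ga$sample_id == "s02"], 6
  )
  # permuting peaks leaves sums unchanged
  ga2 <- gene_accessibility(x, ann[c(3, 1, 2), ])
  expect_equal(
    dplyr::arrange(ga, gene_id, sample_id),
    dplyr::arrange(ga2, gene_id, sample_id)
  )
  # a gene with no peaks is absent
  expect_setequal(unique(ga$gene_id), c("gA", "gB"))
})

test_that("sample correlation recovers planted groups and flags degenerate samples", {
  set.seed(21)
  base_a <- rnorm(40, 5)
  base_b <- rnorm(40, 5)
  intens <- cbind(
    a1 = base_a + rnorm(40, sd = 0.05),
    a2 = base_a + rnorm(40, sd = 0.05),
    b1 = base_b + rnorm(40, sd = 0.05),
    b2 = base_b + rnorm(40, sd = 0.05)
  )
  x <- make_matrix(intens)
  sc <- sample_correlation(x)
  expect_equal(unname(diag(sc$r)), rep(1, 4))
  expect_true(sc$r["a1", "a2"] > sc$r["a1", "b1"])
  ord <- sc$order
  groups <- substr(ord, 1, 1)
  expect_true(identical(groups, c("a", "a", "b", "b")) ||
    identical(groups, c("b", "b", "a", "a")))

  # duplicated and negated samples
  y <- make_matrix(cbind(s1 = base_a, s2 = base_a, s3 = -base_a))
  sy <- sample_correlation(y)
  expect_equal(sy$r["s1", "s2"], 1)
  expect_equal(sy$r["s1", "s3"], -1)

  z <- make_matrix(cbind(s1 = base_a, s2 = rep(2, 40)))
  expect_warning(sz <- sample_correlation(z), "zero-variance")
  expect_true(is.na(sz$r["s1", "s2"]))
})
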