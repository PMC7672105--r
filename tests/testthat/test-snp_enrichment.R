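make_catalog <- function(trait, n, p = 1e-4, start = 0L, step = 10L) {
  tibble::tibble(
    trait = trait, chrom = "chrS",
    pos = start + step * (seq_len(n) - 1L),
    assoc_p = rep_len(p, n)
  )
}

test_that("catalog filtering applies strict thresholds and the 20-SNP floor", {
  cat <- dplyr::bind_rows(
    make_catalog("small", 19, p = 1e-9),
    make_catalog("big", 25, p = 1e-4, start = 10000L)
  )
  # a trait with 19 SNPs is dropped at any threshold
  f <- filter_catalog(cat, 0.05)
  expect_setequal(unique(f$trait), "big")
  f2 <- filter_catalog(cat, 1e-8)
  expect_equal(nrow(f2), 0) # big's SNPs fail 1e-8; small has < 20

  # threshold 1 retains every SNP with p < 1
  expect_equal(nrow(filter_catalog(cat, 1, min_snps = 1)), 44)

  # per-threshold counts match hand enumeration on a 3-trait catalog
  cat3 <- dplyr::bind_rows(
    make_catalog("t1", 30, p = 1e-2),
    make_catalog("t2", 30, p = 1e-6, start = 40000L),
    make_catalog("t3", 30, p = 1e-9, start = 80000L)
  )
  for (thr in c(0.05, 1e-3, 1e-5, 1e-8)) {
    expected <- sum(cat3$assoc_p < thr &
      cat3$trait %in% names(which(
        table(cat3$trait[cat3$assoc_p < thr]) >= 20
      )))
    expect_equal(nrow(filter_catalog(cat3, thr)), expected)
  }
  expect_warning(filter_catalog(cat3[0, ], 0.05), "empty")
})

test_that("SNP-peak overlap respects half-open boundaries and matches brute force", {
  peaks <- tibble::tibble(
    chrom = "chrS", start = 100L, end = 200L, peak_id = "pk"
  )
  # 1-based position 101 -> 0-based 100: inside [100, 200)
  inside <- tibble::tibble(
    trait = "t", chrom = "chrS", pos = 100L, assoc_p = 0.01
  )
  expect_equal(nrow(overlap_traits_peaks(inside, peaks)), 1)
  # 1-based position 100 -> 0-based 99: outside
  outside <- dplyr::mutate(inside, pos = 99L)
  expect_equal(nrow(overlap_traits_peaks(outside, peaks)), 0)
  # end is exclusive
  at_end <- dplyr::mutate(inside, pos = 200L)
  expect_equal(nrow(overlap_traits_peaks(at_end, peaks)), 0)

  set.seed(31)
  for (rep in 1:3) {
    rpk <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
      start = sample.int(5000, 50)
    )
    rpk$end <- rpk$start + sample(20:400, 50, replace = TRUE) # overlapping
    rpk$peak_id <- sprintf("p%02d", 1:50)
    rcat <- tibble::tibble(
      trait = sample(c("tA", "tB"), 100, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
      pos = sample.int(6000, 100), assoc_p = 0.01
    )
    got <- overlap_traits_peaks(rcat, rpk)
    expect_setequal(
      paste(got$trait, got$peak_id),
      paste(
        overlap_oracle(rcat, rpk)$trait,
        overlap_oracle(rcat, rpk)$peak_id
      )
    )
  }
})

# small matrix with structured counts for deviation tests
dev_fixture <- function(seed = 41, n = 60, m = 6) {
  set.seed(seed)
  counts <- matrix(
    rpois(n * m, lambda = rep(sample(10:200, n), m)), n, m,
    dimnames = list(sprintf("p%02d", seq_len(n)), sprintf("s%d", seq_len(m)))
  )
  atac_matrix(counts)
}

test_that("deviation of the all-peaks set is zero and scaling-invariant", {
  x <- dev_fixture()
  membership <- tidyr::expand_grid(
    trait = "everything", peak_id = rownames(x$counts)
  )
  dev <- deviation_scores(membership, x, n_background = 5, seed = 1)
  expect_equal(dev$deviation, rep(0, ncol(x$counts)))

  # multiplying one sample's counts by a constant leaves deviations alone
  part <- tidyr::expand_grid(
    trait = "t", peak_id = rownames(x$counts)[1:20]
  )
  d1 <- deviation_scores(part, x, n_background = 5, seed = 2)
  y <- x
  y$counts[, 3] <- y$counts[, 3] * 7L
  d2 <- deviation_scores(part, y, n_background = 5, seed = 2)
  expect_equal(d1$deviation[d1$sample_id == "s3"],
    d2$deviation[d2$sample_id == "s3"],
    tolerance = 1e-2
  )
})

test_that("deviation scores are reproducible under a fixed seed", {
  x <- dev_fixture()
  membership <- tidyr::expand_grid(
    trait = "t", peak_id = rownames(x$counts)[seq(1, 59, by = 3)]
  )
  d1 <- deviation_scores(membership, x, seed = 77)
  d2 <- deviation_scores(membership, x, seed = 77)
  expect_identical(d1, d2)
  d3 <- deviation_scores(membership, x, seed = 78)
  expect_false(identical(d1$z, d3$z))
})

test_that("uniform random trait sets have near-zero mean raw deviation", {
  x <- dev_fixture(seed = 51, n = 100, m = 8)
  set.seed(52)
  devs <- replicate(100, {
    ids <- sample(rownames(x$counts), 25)
    membership <- tidyr::expand_grid(trait = "null", peak_id = ids)
    mean(deviation_scores(membership, x,
      n_background = 2, seed = 1
    )$deviation)
  })
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * se + 1e-3)
})

test_that("per-cell-type averaging is a plain mean over samples", {
  dev <- tibble::tibble(
    trait = "t",
    sample_id = c("s1", "s2", "s3"),
    deviation = c(0.1, 0.3, -0.2),
    z = c(1, 3, -2)
  )
  meta <- make_meta(c("s1", "s2", "s3"), c("A", "A", "B"))
  enr <- enrichment_by_cell_type(dev, meta)
  expect_equal(enr$mean_deviation[enr$cell_type == "A"], 0.2)
  expect_equal(enr$mean_deviation[enr$cell_type == "B"], -0.2)
  expect_equal(enr$mean_z[enr$cell_type == "B"], -2) # single sample
  # permuting sample rows changes nothing
  enr2 <- enrichment_by_cell_type(dev[c(3, 1, 2), ], meta)
  expect_equal(enr, enr2)
})

test_that("planted SNP enrichment points at the target cell type", {
  cfg <- sim_config(
    n_peaks = 600, cell_types = c("A", "B", "C", "DC"), states = "normal",
    replicates = 2, n_specific = 30, cluster_counts = 0,
    n_lr_up = 0, n_lr_down = 0, snps_per_trait = 150,
    target_cell_type = "DC", seed = 13
  )
  sim <- simulate_accessibility(cfg)
  catalog <- simulate_snp_catalog(sim, cfg)
  x <- sim$matrix
  sweep <- snp_enrichment_sweep(
    catalog, x, sim$peaks,
    thresholds = c(0.05, 1e-5), seed = 5
  )
  top <- sweep |>
    dplyr::filter(trait == "trait_target") |>
    dplyr::group_by(threshold) |>
    dplyr::slice_max(mean_deviation, n = 1)
  expect_equal(unique(top$cell_type), "DC")
})
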