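test_that("identical groups give zero fold change and no calls", {
  set.seed(1)
  base <- matrix(rnorm(20, 6), 10, 2)
  intens <- cbind(base, base)
  colnames(intens) <- c("a1", "a2", "b1", "b2")
  x <- make_matrix(intens)
  d <- differential_peaks(x, c("a1", "a2"), c("b1", "b2"),
    p_thr = 0.05, lfc_thr = 1
  )
  expect_equal(d$log2fc, rep(0, 10))
  expect_equal(d$p, rep(1, 10)) # zero-variance equal means convention
  expect_equal(sum(d$significant), 0)
})

test_that("per-peak Welch test agrees with stats::t.test", {
  set.seed(2)
  intens <- matrix(
    rnorm(60, 5), 10, 6,
    dimnames = list(sprintf("p%d", 1:10), sprintf("s%d", 1:6))
  )
  intens[1, 1:3] <- rnorm(3, 8, 0.1) # planted peak: 8 vs 2
  intens[1, 4:6] <- rnorm(3, 2, 0.1)
  x <- make_matrix(intens)
  d <- differential_peaks(x, paste0("s", 1:3), paste0("s", 4:6),
    p_thr = 0.005, lfc_thr = 2
  )
  for (i in 1:10) {
    tt <- t.test(intens[i, 1:3], intens[i, 4:6])
    expect_equal(d$p[i], tt$p.value)
    expect_equal(d$log2fc[i], unname(diff(rev(tt$estimate))))
  }
  expect_true(d$significant[1])
  expect_equal(sum(d$significant), 1)
})

test_that("BH adjustment matches the step-up oracle", {
  # hand case: (0.01, 0.02, 0.03, 0.04) with m = 4 -> all 0.04
  expect_equal(
    p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
    rep(0.04, 4)
  )
  set.seed(3)
  for (n in c(10, 100, 5000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
})

test_that("swapping group labels negates log2fc and preserves p", {
  set.seed(4)
  intens <- matrix(
    rnorm(40, 5), 10, 4,
    dimnames = list(sprintf("p%d", 1:10), sprintf("s%d", 1:4))
  )
  x <- make_matrix(intens)
  d1 <- differential_peaks(x, c("s1", "s2"), c("s3", "s4"))
  d2 <- differential_peaks(x, c("s3", "s4"), c("s1", "s2"))
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p)
})

test_that("singleton groups need fc_only mode", {
  intens <- matrix(
    c(8, 8, 2, 5), 2, 2,
    dimnames = list(c("p1", "p2"), c("s1", "s2"))
  )
  x <- make_matrix(intens)
  expect_error(
    differential_peaks(x, "s1", "s2", mode = "ttest"),
    "fc_only"
  )
  d <- differential_peaks(x, "s1", "s2", mode = "fc_only", lfc_thr = 2)
  expect_equal(d$log2fc, c(6, 3))
  expect_true(all(is.na(d$p)))
  expect_equal(d$significant, c(TRUE, TRUE))
})

test_that("specificity calls require all four filters simultaneously", {
  # 2 cell types x 3 reps; peak pk01 is A-specific with tight focal CV,
  # pk02 passes p/lfc but has a noisy focal group (inCov fails)
  meta <- make_meta(
    sprintf("s%02d", 1:6), rep(c("A", "B"), each = 3)
  )
  intens <- rbind(
    pk01 = c(8.0, 8.1, 7.9, 2.0, 2.1, 1.9),
    pk02 = c(9.9, 5.0, 8.1, 2.0, 2.1, 1.9),
    pk03 = c(5, 5, 5, 5, 5, 5)
  )
  colnames(intens) <- meta$sample_id
  norm <- rbind(
    pk01 = c(100, 101, 99, 4, 5, 3),
    pk02 = c(900, 30, 260, 4, 5, 3),
    pk03 = c(31, 31, 31, 31, 31, 31)
  )
  colnames(norm) <- meta$sample_id
  x <- make_matrix(intens, meta = meta, normalized = norm)
  calls <- cell_type_specific_peaks(x)
  a <- calls[calls$cell_type == "A", ]
  expect_true(a$specific[a$peak_id == "pk01"])
  expect_false(a$specific[a$peak_id == "pk02"]) # inCov = sd/mean > 0.5
  expect_gt(a$in_cov[a$peak_id == "pk02"], 0.5)
  expect_false(any(calls$specific[calls$peak_id == "pk03"]))
  # constant focal group: inCov exactly 0
  expect_equal(a$in_cov[a$peak_id == "pk03"], 0)
})

test_that("planted cell-type-specific peaks are recovered on simulated data", {
  cfg <- sim_config(
    n_peaks = 900, cell_types = c("A", "B", "C"), states = "normal",
    replicates = 3, n_specific = 30, cluster_counts = 0,
    n_lr_up = 0, n_lr_down = 0, n_traits = 0, seed = 7
  )
  sim <- simulate_accessibility(cfg)
  x <- peak_intensity(quantile_normalize(sim$matrix))
  calls <- suppressWarnings(cell_type_specific_peaks(x))
  hit <- calls[calls$specific, ]
  truth <- sim$truth$specific
  key <- function(d) paste(d$peak_id, d$cell_type)
  tp <- sum(key(hit) %in% key(truth))
  expect_gte(tp / nrow(truth), 0.9)
  expect_gte(tp / nrow(hit), 0.9)
  # one-vs-rest calls are mutually exclusive across cell types
  expect_equal(anyDuplicated(hit$peak_id), 0)
})

test_that("six-state rules assign patterns by gap and range", {
  meta <- make_meta(
    sprintf("s%02d", 1:6), "DC",
    state = rep(c("normal", "unaffected", "affected"), each = 2)
  )
  intens <- rbind(
    pk01 = c(8.0, 8.1, 8.0, 7.9, 2.0, 2.1), # C2: normal+unaffected
    pk02 = c(5.0, 5.1, 5.5, 5.4, 5.9, 5.8), # gaps < 0.8: unassigned
    pk03 = c(2.0, 2.1, 1.9, 2.0, 8.0, 8.1), # C5: affected only
    pk04 = c(5, 5, 5, 5, 5, 5)
  )
  colnames(intens) <- meta$sample_id
  x <- make_matrix(intens, meta = meta)
  res <- classify_six_states(x, p_thr = 0.05)
  lab <- setNames(res$cluster, res$peak_id)
  expect_equal(unname(lab["pk01"]), "C2")
  expect_equal(unname(lab["pk03"]), "C5")
  expect_false("pk04" %in% res$peak_id) # never a stage-1 candidate
  if ("pk02" %in% res$peak_id) {
    expect_equal(unname(lab["pk02"]), "unassigned")
  }
  s <- glance(res)
  expect_equal(sum(s$n), sum(res$cluster != "unassigned"))
  expect_equal(s$ratio, s$n / nrow(res))
})

test_that("six-state labels are invariant to sample order and intensity shifts", {
  cfg <- sim_config(
    n_peaks = 400, cell_types = "DC", states = c(
      "normal", "unaffected", "affected"
    ),
    replicates = 3, n_specific = 0, cluster_counts = 20,
    noise_sd = 0.1, n_lr_up = 0, n_lr_down = 0, seed = 9
  )
  sim <- simulate_accessibility(cfg)
  x <- peak_intensity(quantile_normalize(sim$matrix))
  res <- classify_six_states(x)

  # permute samples
  perm <- sample(ncol(x$counts))
  xp <- x
  xp$counts <- x$counts[, perm]
  xp$normalized <- x$normalized[, perm]
  xp$intensity <- x$intensity[, perm]
  xp$meta <- x$meta[perm, ]
  resp <- classify_six_states(xp)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(res), peak_id),
    dplyr::arrange(tibble::as_tibble(resp), peak_id)
  )

  # add a constant to every intensity
  xs <- x
  xs$intensity <- x$intensity + 3
  ress <- classify_six_states(xs)
  expect_equal(tibble::as_tibble(res), tibble::as_tibble(ress))
})
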