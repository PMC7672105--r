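#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults that
#' emulate a multi-donor, multi-cell-type skin chromatin study: eight
#' sorted cell populations, three clinical states (normal donors plus
#' clinically unaffected and affected patient skin), negative-binomial
#' read counts around per-peak baselines, planted cell-type-specific
#' peaks, planted six-state differential peaks, trait-SNP enrichment,
#' expression arrays coupled to a clinical fibrosis score, footprint
#' protection, and altered ligand-receptor pairs.
#'
#' Peaks are laid out in blocks of three along one synthetic chromosome
#' with a gene TSS at the center of each block's middle peak, so every
#' planted peak maps deterministically to a known gene.
#'
#' @param n_peaks Total merged peaks (default 5000).
#' @param cell_types Cell-type labels (default the eight skin
#'   populations: CD4, CD8, DC, LC, EC, Mac, Fib, KC).
#' @param states Clinical states (default normal / unaffected / affected).
#' @param replicates Samples per (cell type, state) (default 2, i.e. 48
#'   samples under the defaults).
#' @param n_specific Planted specific peaks per cell type (default 100).
#' @param specific_effect Planted specificity offset in log2 intensity
#'   units (default 4).
#' @param cluster_counts Planted peaks per six-state pattern in the focal
#'   cell type (default 100).
#' @param cluster_gap Log2 intensity gap between in- and out-pattern
#'   states (default 3).
#' @param cluster_cell_type Cell type carrying the six-state peaks
#'   (default `"DC"`).
#' @param noise_sd Log2-scale normal noise on planted intensities
#'   (default 0.2).
#' @param nb_size Negative-binomial size (inverse dispersion) of raw
#'   counts (default 100).
#' @param baseline_log2 Range of per-peak baseline log2 counts (default
#'   c(4, 7)).
#' @param peak_width,peak_spacing Peak geometry in bp (defaults 500 and
#'   2000).
#' @param n_traits Traits in the SNP catalog (default 5; one is the
#'   enrichment target).
#' @param snps_per_trait SNPs per trait (default 300).
#' @param snp_odds Odds of a target-trait SNP landing inside a
#'   target-cell-type-specific peak versus a background position
#'   (default 20).
#' @param target_cell_type Cell type targeted by the SNP enrichment and
#'   the clinical-score coupling (default `"DC"`).
#' @param n_lr_pairs Total ligand-receptor pairs emitted (default 30).
#' @param n_lr_up,n_lr_down Planted up-/down-regulated pairs (defaults 3
#'   and 3).
#' @param lr_low,lr_high Log2 count levels of ligand-receptor gene peaks
#'   in their silent and active condition (defaults -6, i.e. essentially
#'   unread chromatin, and 13).
#' @param n_patients,n_arrays Patients and expression arrays (defaults 30
#'   and 105).
#' @param mrss_rho Planted correlation between the target cell type's
#'   signature score and mRSS (default 0.4).
#' @param n_response_genes Planted treatment-response genes (default 20).
#' @param response_effect Expression shift of response genes in treated
#'   arrays (default 5).
#' @param expr_noise_sd Per-gene expression noise (default 0.3).
#' @param n_motif_sites,motif_length Motif site count and width for the
#'   footprint stage (defaults 200 and 10).
#' @param insertion_rate Tn5 insertions per bp per group outside motifs
#'   (default 2).
#' @param footprint_protection Multiplier on the insertion rate inside
#'   motifs for protected groups (default 0.2).
#' @param flank_factor Multiplier on the rate in the flanking window
#'   (default 1).
#' @param protected_groups Sample groups whose motifs are protected
#'   (default `"normal"`).
#' @param seed Mandatory integer seed; every generator is a pure function
#'   of (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_peaks = 5000,
                       cell_types = c(
                         "CD4", "CD8", "DC", "LC", "EC", "Mac", "Fib", "KC"
                       ),
                       states = c("normal", "unaffected", "affected"),
                       replicates = 2,
                       n_specific = 100,
                       specific_effect = 4,
                       cluster_counts = 100,
                       cluster_gap = 3,
                       cluster_cell_type = "DC",
                       noise_sd = 0.2,
                       nb_size = 100,
                       baseline_log2 = c(4, 7),
                       peak_width = 500,
                       peak_spacing = 2000,
                       n_traits = 5,
                       snps_per_trait = 300,
                       snp_odds = 20,
                       target_cell_type = "DC",
                       n_lr_pairs = 30,
                       n_lr_up = 3,
                       n_lr_down = 3,
                       lr_low = -6,
                       lr_high = 13,
                       n_patients = 30,
                       n_arrays = 105,
                       mrss_rho = 0.4,
                       n_response_genes = 20,
                       response_effect = 5,
                       expr_noise_sd = 0.3,
                       n_motif_sites = 200,
                       motif_length = 10,
                       insertion_rate = 2,
                       footprint_protection = 0.2,
                       flank_factor = 1,
                       protected_groups = "normal",
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- as.list(environment())
  cfg$n_blocks <- n_peaks %/% 3L
  planted <- length(cell_types) * n_specific +
    6L * cluster_counts * (cluster_counts > 0) +
    2L * (n_lr_up + n_lr_down)
  if (planted > cfg$n_blocks) {
    abort(paste0(
      "config plants ", planted, " peak blocks but only ", cfg$n_blocks,
      " are available (n_peaks %/% 3); increase n_peaks"
    ))
  }
  if (abs(mrss_rho) >= 1) abort("mrss_rho must lie in (-1, 1)")
  counts <- c(
    n_peaks, replicates, n_specific, cluster_counts, n_traits,
    snps_per_trait, n_lr_pairs, n_lr_up, n_lr_down, n_patients, n_arrays,
    n_motif_sites, n_response_genes
  )
  if (any(counts < 0)) abort("counts in the config must be >= 0")
  if (!cluster_cell_type %in% cell_types && cluster_counts > 0) {
    abort("cluster_cell_type must be one of cell_types")
  }
  cfg$genome_length <- n_peaks * peak_spacing + 10000L
  structure(cfg, class = "sim_config")
}

# Deterministic block layout: which 3-peak blocks carry which planted
# feature. Returns a tibble(block, feature, label).
sim_block_plan <- function(cfg) {
  n_ct <- length(cfg$cell_types)
  blocks <- seq_len(cfg$n_blocks)
  plan <- tibble::tibble(
    block = blocks, feature = "background", label = NA_character_
  )
  cursor <- 1L
  take <- function(k) {
    out <- cursor:(cursor + k - 1L)
    cursor <<- cursor + k
    out
  }
  for (ct in cfg$cell_types) {
    if (cfg$n_specific > 0) {
      idx <- take(cfg$n_specific)
      plan$feature[idx] <- "specific"
      plan$label[idx] <- ct
    }
  }
  if (cfg$cluster_counts > 0) {
    for (cl in names(six_state_patterns())) {
      idx <- take(cfg$cluster_counts)
      plan$feature[idx] <- "cluster"
      plan$label[idx] <- cl
    }
  }
  n_lr_genes <- 2L * (cfg$n_lr_up + cfg$n_lr_down)
  if (n_lr_genes > 0) {
    idx <- take(n_lr_genes)
    plan$feature[idx] <- "lr"
    plan$label[idx] <- paste0("lr_gene_", seq_len(n_lr_genes))
  }
  plan
}

# Planned ligand/receptor cell-type pairings: up pairs are sent by the
# target cell type (its communications are the ones the study flags as
# up-regulated); down pairs are sent by the last cell type.
sim_lr_plan <- function(cfg) {
  if (cfg$n_lr_up + cfg$n_lr_down == 0) {
    return(tibble::tibble(
      ligand = character(), receptor = character(),
      sender = character(), receiver = character(), direction = character()
    ))
  }
  others <- setdiff(cfg$cell_types, cfg$target_cell_type)
  down_sender <- others[length(others)]
  gene_idx <- 0L
  mk <- function(n, sender_ct, dir) {
    if (n == 0) {
      return(NULL)
    }
    receivers <- rep_len(setdiff(cfg$cell_types, sender_ct), n)
    purrr::map(seq_len(n), function(i) {
      lig <- paste0("lr_gene_", gene_idx + 2L * i - 1L)
      rec <- paste0("lr_gene_", gene_idx + 2L * i)
      tibble::tibble(
        ligand = lig, receptor = rec, sender = sender_ct,
        receiver = receivers[i], direction = dir
      )
    }) |> dplyr::bind_rows()
  }
  up <- mk(cfg$n_lr_up, cfg$target_cell_type, "up")
  gene_idx <- 2L * cfg$n_lr_up
  down <- mk(cfg$n_lr_down, down_sender, "down")
  dplyr::bind_rows(up, down)
}

#' Simulate a multi-cell-type accessibility study
#'
#' Generates the peak set, gene models, sample metadata and raw count
#' matrix with planted cell-type-specific peaks, six-state differential
#' peaks in the focal cell type, and altered ligand-receptor gene blocks.
#' Raw counts are negative-binomial draws around per-peak log2 baselines;
#' planted effects are offsets on the log2 scale with normal noise of sd
#' `noise_sd`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `matrix` (an [atac_matrix()]), `peaks`,
#'   `meta`, `genes` (gene models), `annotation` (peak-to-gene map) and
#'   `truth` (ground-truth list: `specific`, `clusters`, `lr`,
#'   `signature_genes`, `block_gene`).
#' @export
simulate_accessibility <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_peaks
  peaks <- tibble::tibble(
    chrom = "chrS",
    start = as.integer((seq_len(n) - 1L) * cfg$peak_spacing),
    end = as.integer((seq_len(n) - 1L) * cfg$peak_spacing + cfg$peak_width),
    peak_id = sprintf("peak_%05d", seq_len(n))
  )
  # one gene per 3-peak block, TSS at the center of the middle peak
  blocks <- cfg$n_blocks
  anchor_idx <- (seq_len(blocks) - 1L) * 3L + 2L
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%04d", seq_len(blocks)),
    chrom = "chrS",
    tss = peak_center(peaks[anchor_idx, ]),
    strand = "+"
  )
  plan <- sim_block_plan(cfg)
  lr_plan <- sim_lr_plan(cfg)

  samples <- tidyr::expand_grid(
    cell_type = cfg$cell_types, state = cfg$states,
    rep = seq_len(cfg$replicates)
  )
  meta <- tibble::tibble(
    sample_id = sprintf(
      "%s_%s_r%d", samples$cell_type, samples$state, samples$rep
    ),
    cell_type = samples$cell_type,
    state = samples$state,
    donor_id = sprintf("donor_%s_%d", samples$state, samples$rep)
  )
  m <- nrow(meta)

  withr::with_seed(cfg$seed, {
    mu <- runif(n, cfg$baseline_log2[1], cfg$baseline_log2[2])
    # per-peak per-sample log2 target intensity
    log2_mu <- matrix(mu, n, m)
    for (b in which(plan$feature == "specific")) {
      pk <- anchor_idx[b]
      ct <- plan$label[b]
      log2_mu[pk, meta$cell_type == ct] <-
        log2_mu[pk, meta$cell_type == ct] + cfg$specific_effect
    }
    for (b in which(plan$feature == "cluster")) {
      pk <- anchor_idx[b]
      in_states <- six_state_patterns()[[plan$label[b]]]
      sel <- meta$cell_type == cfg$cluster_cell_type &
        meta$state %in% in_states
      log2_mu[pk, sel] <- log2_mu[pk, sel] + cfg$cluster_gap
    }
    if (nrow(lr_plan) > 0) {
      lr_blocks <- which(plan$feature == "lr")
      block_of_gene <- setNames(lr_blocks, plan$label[lr_blocks])
      set_gene_level <- function(gene, ct_active, up) {
        b <- block_of_gene[[gene]]
        pk <- ((b - 1L) * 3L + 1L):((b - 1L) * 3L + 3L)
        # silent everywhere by default
        log2_mu[pk, ] <<- cfg$lr_low
        active <- meta$cell_type == ct_active
        if (up) {
          # low in normal/unaffected, high in affected
          log2_mu[pk, active & meta$state == "affected"] <<- cfg$lr_high
        } else {
          # high everywhere in the sender but collapses in affected
          log2_mu[pk, active] <<- cfg$lr_high
          log2_mu[pk, active & meta$state == "affected"] <<- cfg$lr_low
        }
      }
      for (i in seq_len(nrow(lr_plan))) {
        up <- lr_plan$direction[i] == "up"
        set_gene_level(lr_plan$ligand[i], lr_plan$sender[i], up)
        set_gene_level(lr_plan$receptor[i], lr_plan$receiver[i], up)
      }
    }
    log2_mu <- log2_mu + matrix(rnorm(n * m, sd = cfg$noise_sd), n, m)
    counts <- matrix(
      rnbinom(n * m, size = cfg$nb_size, mu = 2^log2_mu), n, m,
      dimnames = list(peaks$peak_id, meta$sample_id)
    )
  })

  mat <- atac_matrix(counts, peaks = peaks, meta = meta)
  annotation <- annotate_nearest_gene(peaks, genes)
  block_gene <- genes$gene_id # block b -> gene

  # translate the plan's placeholder ligand/receptor labels into the gene
  # ids of the blocks they occupy
  if (nrow(lr_plan) > 0) {
    lr_blocks <- which(plan$feature == "lr")
    label_gene <- setNames(block_gene[lr_blocks], plan$label[lr_blocks])
    lr_plan$ligand <- unname(label_gene[lr_plan$ligand])
    lr_plan$receptor <- unname(label_gene[lr_plan$receptor])
  }

  specific_truth <- plan |>
    dplyr::filter(.data$feature == "specific") |>
    dplyr::transmute(
      peak_id = peaks$peak_id[anchor_idx[.data$block]],
      cell_type = .data$label,
      gene_id = block_gene[.data$block]
    )
  cluster_truth <- plan |>
    dplyr::filter(.data$feature == "cluster") |>
    dplyr::transmute(
      peak_id = peaks$peak_id[anchor_idx[.data$block]],
      cluster = .data$label
    )
  truth <- list(
    specific = specific_truth,
    clusters = cluster_truth,
    cluster_cell_type = cfg$cluster_cell_type,
    lr = lr_plan,
    signature_genes = specific_truth[, c("cell_type", "gene_id")],
    target_cell_type = cfg$target_cell_type,
    block_gene = block_gene
  )
  list(
    matrix = mat, peaks = peaks, meta = meta, genes = genes,
    annotation = annotation, truth = truth
  )
}

#' Simulate a trait-SNP association catalog
#'
#' One target trait places its SNPs preferentially inside the target cell
#' type's planted specific peaks (probability `snp_odds / (snp_odds + 1)`
#' per SNP, the rest uniform over the genome); the remaining traits place
#' all SNPs uniformly. Association p-values are drawn log-uniformly over
#' ten orders of magnitude so threshold sweeps change the retained counts.
#'
#' @param sim Output of [simulate_accessibility()].
#' @param cfg The same [sim_config()].
#' @return A catalog tibble (`trait`, `chrom`, `pos` 0-based, `assoc_p`)
#'   with attribute `target_trait`.
#' @export
simulate_snp_catalog <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  target_peaks <- sim$truth$specific |>
    dplyr::filter(.data$cell_type == cfg$target_cell_type)
  if (nrow(target_peaks) == 0) {
    abort("no specific peaks planted for the target cell type")
  }
  tp <- sim$peaks[match(target_peaks$peak_id, sim$peaks$peak_id), ]
  traits <- c("trait_target", sprintf("trait_null_%02d", seq_len(
    max(cfg$n_traits - 1L, 0L)
  )))
  withr::with_seed(cfg$seed + 101L, {
    cat_rows <- purrr::map(traits, function(tr) {
      k <- cfg$snps_per_trait
      if (tr == "trait_target" && cfg$snp_odds > 0) {
        inside <- runif(k) < cfg$snp_odds / (cfg$snp_odds + 1)
        pk <- sample(nrow(tp), sum(inside), replace = TRUE)
        pos_in <- tp$start[pk] + floor(
          runif(sum(inside)) * (tp$end[pk] - tp$start[pk])
        )
        pos_out <- floor(runif(k - sum(inside)) * cfg$genome_length)
        pos <- c(pos_in, pos_out)
      } else {
        pos <- floor(runif(k) * cfg$genome_length)
      }
      tibble::tibble(
        trait = tr, chrom = "chrS", pos = as.integer(pos),
        assoc_p = 10^(-runif(k, 0, 10))
      )
    })
  })
  out <- dplyr::bind_rows(cat_rows)
  attr(out, "target_trait") <- "trait_target"
  out
}

#' Simulate expression arrays and clinical scores
#'
#' Emits a normalized expression matrix over the study's genes and a
#' clinical table of mRSS trajectories under treatment: each patient's
#' score declines from its baseline, the target cell type's signature
#' genes are coupled to the standardized mRSS at correlation `mrss_rho`,
#' planted treatment-response genes are shifted by `response_effect` in
#' treated (12/24-month) arrays, and all other genes are independent
#' noise. A handful of the response genes are drawn from the target
#' signature, so removing them matters.
#'
#' @param sim Output of [simulate_accessibility()].
#' @param cfg The same [sim_config()].
#' @return A list with `expr` (tibble, `gene_id` + one column per array),
#'   `clinical` (tibble: `array_id`, `patient_id`, `timepoint`, `mrss`,
#'   `phase`) and `response_genes` (character).
#' @export
simulate_expression_clinical <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim$genes$gene_id
  sig <- sim$truth$signature_genes
  target_genes <- sig$gene_id[sig$cell_type == cfg$target_cell_type]
  n_extra <- cfg$n_arrays - 3L * cfg$n_patients
  if (n_extra < 0 || n_extra > cfg$n_patients) {
    abort("n_arrays must lie in [3 * n_patients, 4 * n_patients]")
  }
  withr::with_seed(cfg$seed + 202L, {
    # visit layout: everyone at 0/12/24 months, some patients add a
    # 6-month visit so the array count matches the design
    extra <- sample(cfg$n_patients, n_extra)
    clin <- purrr::map(seq_len(cfg$n_patients), function(p) {
      tps <- c(0L, 12L, 24L)
      if (p %in% extra) tps <- c(0L, 6L, 12L, 24L)
      base <- runif(1, 15, 40)
      # noisy decline under treatment; rate varies across patients so
      # only part of the cohort spans a large mRSS range
      rate <- runif(1, 0.008, 0.035)
      mrss <- pmax(base * (1 - rate * tps) + rnorm(length(tps), sd = 2), 0)
      tibble::tibble(
        patient_id = sprintf("pt_%02d", p), timepoint = tps,
        mrss = round(mrss, 1),
        phase = ifelse(tps == 0L, "baseline", "treated")
      )
    }) |> dplyr::bind_rows()
    clin$array_id <- sprintf("array_%03d", seq_len(nrow(clin)))
    clin <- clin[, c("array_id", "patient_id", "timepoint", "mrss", "phase")]

    n_arr <- nrow(clin)
    z <- as.numeric(scale(clin$mrss))
    rho <- cfg$mrss_rho
    # residual score variation is mostly patient-level (cell-composition
    # differences between people), which cancels in within-patient paired
    # contrasts while leaving the overall score-mRSS correlation at rho
    patient_share <- 0.7
    u_patient <- rnorm(cfg$n_patients)
    resid <- sqrt(patient_share) *
      u_patient[match(clin$patient_id, sprintf("pt_%02d", seq_len(cfg$n_patients)))] +
      sqrt(1 - patient_share) * rnorm(n_arr)
    target_score <- rho * z + sqrt(1 - rho^2) * resid

    gene_base <- rnorm(length(genes), mean = 7, sd = 1)
    expr_m <- matrix(
      rnorm(length(genes) * n_arr, sd = cfg$expr_noise_sd),
      length(genes), n_arr,
      dimnames = list(genes, clin$array_id)
    ) + gene_base
    is_target <- genes %in% target_genes
    expr_m[is_target, ] <- expr_m[is_target, ] +
      matrix(target_score, sum(is_target), n_arr, byrow = TRUE)

    # response genes: a few from the target signature, the rest from
    # genes carrying no signature
    free_genes <- setdiff(genes, sig$gene_id)
    n_from_sig <- min(5L, cfg$n_response_genes, length(target_genes))
    resp <- c(
      sample(target_genes, n_from_sig),
      sample(free_genes, cfg$n_response_genes - n_from_sig)
    )
    treated <- clin$phase == "treated"
    expr_m[resp, treated] <- expr_m[resp, treated] + cfg$response_effect
  })
  list(
    expr = tibble::as_tibble(expr_m, rownames = "gene_id"),
    clinical = clin,
    response_genes = resp
  )
}

#' Simulate motif sites for the footprint stage
#'
#' @param cfg A [sim_config()].
#' @return A tibble of motif sites (`chrom`, `start`, `end`, `motif_id`,
#'   `strand`), evenly spaced with alternating strand.
#' @export
simulate_motif_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spacing <- max(1000L, cfg$genome_length %/% (cfg$n_motif_sites + 1L))
  start <- spacing * seq_len(cfg$n_motif_sites)
  tibble::tibble(
    chrom = "chrS",
    start = start,
    end = start + cfg$motif_length,
    motif_id = "motif_X",
    strand = rep_len(c("+", "-"), cfg$n_motif_sites)
  )
}

#' Simulate Tn5 insertion tracks with footprint protection
#'
#' Draws Poisson insertions per base within a window around every motif
#' site for each sample group. Inside the motif the rate is multiplied by
#' `footprint_protection` for protected groups (a bound factor shields its
#' motif from transposition); the flanking window rate is multiplied by
#' `flank_factor`.
#'
#' @param motif_sites Tibble from [simulate_motif_sites()].
#' @param cfg A [sim_config()].
#' @param groups Group labels (default the config's states).
#' @param window_halfwidth Half-width of the simulated window (default
#'   100 bp).
#' @return A tibble of class `tn5_insertions` (`chrom`, `pos`, `group`).
#' @export
simulate_insertions <- function(motif_sites, cfg,
                                groups = NULL, window_halfwidth = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(groups)) groups <- cfg$states
  centers <- peak_center(motif_sites)
  half_motif <- (motif_sites$end - motif_sites$start) / 2
  offs <- -window_halfwidth:window_halfwidth
  withr::with_seed(cfg$seed + 303L, {
    res <- purrr::map(groups, function(g) {
      protected <- g %in% cfg$protected_groups
      rows <- purrr::map(seq_len(nrow(motif_sites)), function(s) {
        pos <- centers[s] + offs
        in_motif <- pos >= motif_sites$start[s] & pos < motif_sites$end[s]
        rate <- rep(cfg$insertion_rate * cfg$flank_factor, length(pos))
        if (protected) {
          rate[in_motif] <- cfg$insertion_rate * cfg$footprint_protection
        } else {
          rate[in_motif] <- cfg$insertion_rate
        }
        k <- rpois(length(pos), rate)
        tibble::tibble(
          chrom = motif_sites$chrom[s],
          pos = rep(pos, k)
        )
      })
      out <- dplyr::bind_rows(rows)
      out$group <- g
      out
    })
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("tn5_insertions", class(out))
  out
}

#' Simulate motif hit locations
#'
#' One planted motif concentrates its hits inside the target cell type's
#' specific peaks; background motifs hit peaks uniformly. Hit intervals
#' are `motif_length` wide and placed at the peak center.
#'
#' @param sim Output of [simulate_accessibility()].
#' @param cfg The same [sim_config()].
#' @param n_background_motifs Uniform background motifs (default 4).
#' @param target_rate Fraction of target-specific peaks hit by the planted
#'   motif (default 0.8).
#' @param background_rate Fraction of all peaks hit by each background
#'   motif, and by the planted motif outside its target set (default 0.1).
#' @return A tibble with columns `chrom`, `start`, `end`, `motif_id`, and
#'   attribute `target_motif`.
#' @export
simulate_motif_hits <- function(sim, cfg, n_background_motifs = 4,
                                target_rate = 0.8, background_rate = 0.1) {
  stopifnot(inherits(cfg, "sim_config"))
  peaks <- sim$peaks
  centers <- peak_center(peaks)
  target_idx <- match(
    sim$truth$specific$peak_id[
      sim$truth$specific$cell_type == cfg$target_cell_type
    ],
    peaks$peak_id
  )
  hit_rows <- function(idx, motif) {
    tibble::tibble(
      chrom = peaks$chrom[idx],
      start = centers[idx],
      end = centers[idx] + cfg$motif_length,
      motif_id = motif
    )
  }
  withr::with_seed(cfg$seed + 505L, {
    res <- list(hit_rows(
      c(
        target_idx[runif(length(target_idx)) < target_rate],
        which(runif(nrow(peaks)) < background_rate)
      ),
      "motif_target"
    ))
    for (b in seq_len(n_background_motifs)) {
      res[[b + 1L]] <- hit_rows(
        which(runif(nrow(peaks)) < background_rate),
        sprintf("motif_bg_%02d", b)
      )
    }
  })
  out <- dplyr::bind_rows(res) |> dplyr::distinct()
  attr(out, "target_motif") <- "motif_target"
  out
}

#' Simulate a ligand-receptor pair table
#'
#' Emits the planted altered pairs from the accessibility ground truth
#' plus decoy pairs among unplanted genes (whose accessibility does not
#' change, so their interactions are never retained).
#'
#' @param sim Output of [simulate_accessibility()].
#' @param cfg The same [sim_config()].
#' @return A tibble with columns `ligand`, `receptor`, `source`.
#' @export
simulate_lr_pairs <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  planted <- sim$truth$lr
  n_decoy <- max(cfg$n_lr_pairs - nrow(planted), 0L)
  free_genes <- setdiff(sim$genes$gene_id, c(
    planted$ligand, planted$receptor, sim$truth$signature_genes$gene_id
  ))
  withr::with_seed(cfg$seed + 404L, {
    decoy_genes <- sample(free_genes, 2L * n_decoy)
  })
  decoys <- tibble::tibble(
    ligand = decoy_genes[seq_len(n_decoy) * 2L - 1L],
    receptor = decoy_genes[seq_len(n_decoy) * 2L],
    source = "decoy"
  )
  planted_tbl <- tibble::tibble(
    ligand = planted$ligand, receptor = planted$receptor,
    source = "planted"
  )
  as_lr_pairs(dplyr::bind_rows(planted_tbl, decoys))
}

#' Simulate a full study
#'
#' Runs every generator under one config and seed: accessibility matrix,
#' SNP catalog, expression plus clinical tables, motif sites, insertion
#' tracks and ligand-receptor pairs, with a single ground-truth record.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `matrix`, `peaks`, `meta`, `genes`,
#'   `annotation`, `catalog`, `expr`, `clinical`, `response_genes`,
#'   `motif_sites`, `insertions`, `lr_pairs`, `truth`.
#' @export
simulate_study <- function(cfg) {
  sim <- simulate_accessibility(cfg)
  catalog <- simulate_snp_catalog(sim, cfg)
  ec <- simulate_expression_clinical(sim, cfg)
  motif_sites <- simulate_motif_sites(cfg)
  insertions <- simulate_insertions(motif_sites, cfg)
  lr_pairs <- simulate_lr_pairs(sim, cfg)
  motif_hits <- simulate_motif_hits(sim, cfg)
  sim$truth$response_genes <- ec$response_genes
  sim$truth$target_trait <- attr(catalog, "target_trait")
  sim$truth$target_motif <- attr(motif_hits, "target_motif")
  list(
    matrix = sim$matrix, peaks = sim$peaks, meta = sim$meta,
    genes = sim$genes, annotation = sim$annotation,
    catalog = catalog, expr = ec$expr, clinical = ec$clinical,
    response_genes = ec$response_genes,
    motif_sites = motif_sites, insertions = insertions,
    lr_pairs = lr_pairs, motif_hits = motif_hits, truth = sim$truth
  )
}

#' Write a simulated study to disk as plain-text files
#'
#' Emits every input file the pipeline readers consume: peaks BED, counts
#' TSV, metadata TSV, gene models TSV, SNP catalog TSV (1-based
#' positions), expression and clinical TSVs, motif-site BED, insertion
#' BED3 and ligand-receptor TSV, plus the ground truth as JSON when
#' jsonlite is available.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_peaks_bed(study$peaks, p("peaks.bed"))
  write_count_matrix(study$matrix, p("counts.tsv"))
  readr::write_tsv(study$meta, p("metadata.tsv"))
  readr::write_tsv(study$genes, p("genes.tsv"))
  catalog_1based <- dplyr::mutate(study$catalog, pos = .data$pos + 1L)
  readr::write_tsv(catalog_1based, p("snp_catalog.tsv"))
  readr::write_tsv(study$expr, p("expression.tsv"))
  readr::write_tsv(study$clinical, p("clinical.tsv"))
  readr::write_tsv(
    study$motif_sites[, c("chrom", "start", "end", "motif_id")],
    p("motif_sites.bed"),
    col_names = FALSE
  )
  ins <- dplyr::mutate(
    tibble::as_tibble(study$insertions),
    end = .data$pos + 1L
  )
  readr::write_tsv(
    ins[, c("chrom", "pos", "end", "group")], p("insertions.bed"),
    col_names = FALSE
  )
  readr::write_tsv(study$lr_pairs, p("lr_pairs.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      study$truth, p("ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
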