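# Synthetic cohorts, interactomes, regulons and Hi-C maps with recorded
# planted ground truth. The defaults define the desk-scale study conditions:
# five age groups of 20 individuals spanning 1-96 years, 2000 genes with 50
# planted DE genes per transition (|log2FC| >= 1), a toy genome of four
# 12.5-20 Mb chromosomes binned at 250 kb, and condition-specific trans
# contact blocks anchored over the loci of genes planted down (young-specific
# blocks) or up (old-specific blocks) with age.

#' Simulation specification
#'
#' @param n_per_group Individuals per true age group (default 20).
#' @param group_breaks Age cut points defining the five true groups
#'   (defaults to 1-15, 16-26, 27-60, 61-85, 86-96 years).
#' @param n_genes Total genes (default 2000).
#' @param chrom_sizes Named chromosome sizes in bp.
#' @param resolution Hi-C bin width in bp.
#' @param dispersion NB dispersion alpha (constant across genes, default
#'   0.05).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 mean counts.
#' @param libsize_range Per-sample library-size multiplier range.
#' @param length_coupling Correlation-scale coupling in [0, 1] between a
#'   gene's planted age effect and its log transcript length.
#' @param n_trend Genes with a linear age trend.
#' @param trend_slope_range Absolute slope range (log2 units per year).
#' @param n_de_per_transition Planted DE genes per transition (default 50).
#' @param de_lfc_range Absolute planted log2 fold-change range (default
#'   c(1, 2); the minimum is the generator's stated minimum magnitude).
#' @param n_ppi_extra Non-DE background genes included as PPI nodes.
#' @param ppi_degree Mean background PPI degree.
#' @param score_range PPI confidence score range (default c(150, 1000)).
#' @param n_bridge_per_network Planted bridge TFs per transition-pair
#'   network (default 4).
#' @param n_decoy_tfs Decoy TFs with matched regulon sizes but no DE
#'   enrichment (default 40).
#' @param regulon_size_range Regulon size range for decoys and planted TFs.
#' @param bridge_cover_fraction Fraction of the matching target-DE set
#'   covered by each planted bridge TF's regulon (default 0.6).
#' @param self_target_fraction Fraction of TFs targeting themselves
#'   (default 0.2).
#' @param cis_decay_exponent Cis background decay exponent gamma (default 1).
#' @param cis_scale,trans_mean Background contact levels.
#' @param block_shift_range Additive mean shift of planted trans blocks.
#' @param block_size_range Planted block side length in bins.
#' @param n_shared_blocks Shared (condition-independent) trans blocks.
#' @param replicate_noise_sd Per-replicate additive noise sd.
#' @param seed Master seed.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(n_per_group = 20L,
                     group_breaks = c(1, 16, 27, 61, 86, 97),
                     n_genes = 2000L,
                     chrom_sizes = c(chr1 = 16e6, chr2 = 15.5e6,
                                     chr3 = 14.5e6, chr4 = 14e6),
                     resolution = 250000L,
                     dispersion = 0.05,
                     baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                     libsize_range = c(0.7, 1.3),
                     length_coupling = 0.3,
                     n_trend = 50L, trend_slope_range = c(0.01, 0.03),
                     n_de_per_transition = 50L, de_lfc_range = c(1, 2),
                     n_ppi_extra = 400L, ppi_degree = 6,
                     score_range = c(150, 1000),
                     n_bridge_per_network = 4L, n_decoy_tfs = 40L,
                     regulon_size_range = c(150, 350),
                     bridge_cover_fraction = 0.6,
                     self_target_fraction = 0.2,
                     cis_decay_exponent = 1,
                     cis_scale = 50, trans_mean = 5,
                     block_shift_range = c(3, 6),
                     block_size_range = c(4, 8),
                     n_shared_blocks = 4L,
                     replicate_noise_sd = 1,
                     seed = 1L) {
  spec <- as.list(environment())
  if (spec$dispersion < 0 || spec$replicate_noise_sd < 0)
    stop("variances must be non-negative")
  if (spec$score_range[1] >= spec$score_range[2])
    stop("score_min must be below score_max")
  if (any(spec$block_shift_range <= 0)) stop("block mean shifts must be positive")
  if (spec$length_coupling < 0 || spec$length_coupling > 1)
    stop("length_coupling must lie in [0, 1]")
  if (spec$n_per_group < 2) stop("need >= 2 samples per true group")
  class(spec) <- "sim_spec"
  spec
}

#' Simulate the cohort counts and gene catalog
#'
#' Counts are NB(mean = libsize_s * 2^(b_g + effect_g(age_s)), dispersion
#' alpha). Trend genes carry a linear log2 slope in age (monotone expected
#' log-mean); transition-t DE genes step by their planted log2 fold change
#' between true groups t and t+1. Planted age effects are positively coupled
#' to log transcript length with the configured coefficient, and genes with
#' strong overall down (up) effects are preferentially placed inside the
#' down (up) anchor regions later used to position condition-specific Hi-C
#' blocks.
#'
#' @param spec A `sim_spec`.
#' @return List: `cohort` (a `cohort_counts`), `catalog` (a `gene_catalog`),
#'   `truth` (planted ground truth).
#' @export
simulate_cohort_counts <- function(spec) {
  set.seed(spec$seed)
  n_groups <- length(spec$group_breaks) - 1
  ages <- unlist(lapply(seq_len(n_groups), function(g)
    round(runif(spec$n_per_group, spec$group_breaks[g],
                spec$group_breaks[g + 1] - 1))))
  true_group <- rep(seq_len(n_groups), each = spec$n_per_group)
  samples <- sprintf("S%03d", seq_along(ages))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))

  # planted effects
  slope <- setNames(rep(0, spec$n_genes), genes)
  pool <- genes
  trend_genes <- sample(pool, spec$n_trend)
  pool <- setdiff(pool, trend_genes)
  sgn <- sample(c(-1, 1), spec$n_trend, replace = TRUE)
  slope[trend_genes] <- sgn * runif(spec$n_trend, spec$trend_slope_range[1],
                                    spec$trend_slope_range[2])
  transition_de <- list()
  lfc <- matrix(0, spec$n_genes, n_groups - 1,
                dimnames = list(genes, as.character(seq_len(n_groups - 1))))
  for (t in seq_len(n_groups - 1)) {
    de <- sample(pool, spec$n_de_per_transition)
    pool <- setdiff(pool, de)
    s <- sample(c(-1, 1), length(de), replace = TRUE)
    mag <- runif(length(de), spec$de_lfc_range[1], spec$de_lfc_range[2])
    lfc[de, t] <- s * mag
    transition_de[[as.character(t)]] <- data.frame(gene = de, log2fc = s * mag)
  }

  mean_age <- mean(ages)
  effect <- outer(slope, ages - mean_age)                 # trend part
  for (t in seq_len(n_groups - 1))
    effect <- effect + outer(lfc[, t], as.numeric(true_group > t))
  base <- rnorm(spec$n_genes, spec$baseline_log2_mean, spec$baseline_log2_sd)
  libmult <- runif(length(ages), spec$libsize_range[1], spec$libsize_range[2])
  mu <- sweep(2^(base + effect), 2, libmult, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / max(spec$dispersion, 1e-12)),
                   nrow = spec$n_genes,
                   dimnames = list(genes, samples))
  if (spec$dispersion == 0)
    counts <- matrix(rpois(length(mu), mu), nrow = spec$n_genes,
                     dimnames = list(genes, samples))

  # overall age effect (group 1 -> last group) drives length coupling and
  # Hi-C anchoring
  overall <- slope * (max(spec$group_breaks) - min(spec$group_breaks)) +
    rowSums(lfc)
  z_eff <- if (sd(overall) > 0) (overall - mean(overall)) / sd(overall) else overall
  c0 <- spec$length_coupling
  loglen <- log(2000) + 0.6 * (c0 * z_eff + sqrt(1 - c0^2) * rnorm(spec$n_genes))
  tlen <- pmax(200L, as.integer(round(exp(loglen))))

  # genomic placement with anchor regions for strong up/down genes
  chroms <- names(spec$chrom_sizes)
  n_bins <- ceiling(spec$chrom_sizes / spec$resolution)
  anchor <- list(
    down = list(chrom_a = chroms[1], bins_a = 10:15,
                chrom_b = chroms[2], bins_b = 20:25),
    up = list(chrom_a = chroms[3], bins_a = 12:17,
              chrom_b = chroms[4], bins_b = 8:13))
  chrom <- sample(chroms, spec$n_genes, replace = TRUE,
                  prob = spec$chrom_sizes / sum(spec$chrom_sizes))
  start <- floor(runif(spec$n_genes) * (spec$chrom_sizes[chrom] - tlen))
  place_in <- function(idx, side) {
    if (length(idx) < 2) return(invisible(NULL))
    half <- split(idx, rep(1:2, length.out = length(idx)))
    for (h in 1:2) {
      ch <- if (h == 1) side$chrom_a else side$chrom_b
      bn <- if (h == 1) side$bins_a else side$bins_b
      ii <- half[[h]]
      chrom[ii] <<- ch
      start[ii] <<- (sample(bn, length(ii), replace = TRUE) +
                       runif(length(ii), 0.05, 0.8)) * spec$resolution
    }
  }
  down_idx <- which(overall < -0.5)
  up_idx <- which(overall > 0.5)
  place_in(down_idx[seq_len(ceiling(0.6 * length(down_idx)))], anchor$down)
  place_in(up_idx[seq_len(ceiling(0.6 * length(up_idx)))], anchor$up)
  catalog <- gene_catalog(data.frame(
    gene = genes, chrom = chrom, start = as.integer(start),
    end = as.integer(start) + tlen,
    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
    transcript_length = tlen))

  truth <- list(
    trend_genes = data.frame(gene = trend_genes, slope = slope[trend_genes]),
    transition_de = transition_de,
    overall_effect = setNames(overall, genes),
    group_boundaries = spec$group_breaks,
    true_group = setNames(true_group, samples),
    anchors = anchor)
  list(cohort = cohort_counts(counts, setNames(ages, samples)),
       catalog = catalog, truth = truth)
}

#' Simulate the interactome and regulons
#'
#' Builds an undirected scored PPI over the DE genes, planted bridge TFs,
#' decoy TFs and background genes, plus TF -> target regulons. Each planted
#' bridge TF of network k receives maximum-score edges to several source DE
#' genes of transition k (cheap paths of length 1) and a regulon covering
#' the configured fraction of transition k+1's target DE genes; decoy TFs
#' get size-matched random regulons. The stated fraction of TFs target
#' themselves.
#'
#' @param spec A `sim_spec`.
#' @param sim Output of [simulate_cohort_counts()] (truth is updated).
#' @return List: `ppi` (data frame), `regulons` (data frame), `truth`.
#' @export
simulate_interactome <- function(spec, sim) {
  set.seed(spec$seed + 1L)
  truth <- sim$truth
  genes <- rownames(sim$cohort$counts)
  n_networks <- length(truth$transition_de) - 1   # networks N1..N(T-1)
  # TFs are cohort genes: drawn from well-expressed genes without planted
  # effects, so they survive the downstream activity filter
  effect_genes <- c(truth$trend_genes$gene,
                    unlist(lapply(truth$transition_de, `[[`, "gene")))
  mean_cnt <- rowMeans(sim$cohort$counts)
  candidates <- setdiff(genes[mean_cnt > median(mean_cnt)], effect_genes)
  n_tfs <- n_networks * spec$n_bridge_per_network + spec$n_decoy_tfs
  if (length(candidates) < n_tfs)
    stop("too few well-expressed non-effect genes to host the requested TFs")
  tfs <- sample(candidates, n_tfs)
  bridge <- split(tfs[seq_len(n_networks * spec$n_bridge_per_network)],
                  rep(seq_len(n_networks), each = spec$n_bridge_per_network))
  decoys <- tfs[-seq_len(n_networks * spec$n_bridge_per_network)]

  de_genes <- unique(unlist(lapply(truth$transition_de, `[[`, "gene")))
  backbone <- unique(c(de_genes, sample(setdiff(genes, de_genes),
                                        min(spec$n_ppi_extra,
                                            length(genes) - length(de_genes)))))
  nodes <- c(backbone, tfs)

  smin <- spec$score_range[1]; smax <- spec$score_range[2]
  n_bg_edges <- round(spec$ppi_degree * length(nodes) / 2)
  a <- sample(nodes, n_bg_edges, replace = TRUE)
  b <- sample(nodes, n_bg_edges, replace = TRUE)
  keep <- a != b
  ppi <- data.frame(protein_a = pmin(a[keep], b[keep]),
                    protein_b = pmax(a[keep], b[keep]),
                    score = round(runif(sum(keep), smin, smax)))
  # planted cheap paths: each bridge TF of network k touches source DE genes
  # of transition k at maximum score
  planted_edges <- NULL
  for (k in seq_len(n_networks)) {
    src <- truth$transition_de[[k]]$gene
    for (tf in bridge[[k]]) {
      touch <- sample(src, min(5L, length(src)))
      planted_edges <- rbind(planted_edges,
        data.frame(protein_a = pmin(tf, touch), protein_b = pmax(tf, touch),
                   score = smax))
    }
  }
  ppi <- rbind(ppi, planted_edges)
  ppi <- ppi[!duplicated(ppi[, c("protein_a", "protein_b")]), ]

  # regulons
  reg_size <- function(n) round(runif(n, spec$regulon_size_range[1],
                                      spec$regulon_size_range[2]))
  regulons <- NULL
  planted_bridge <- list()
  for (k in seq_len(n_networks)) {
    tgt <- truth$transition_de[[k + 1]]$gene
    for (tf in bridge[[k]]) {
      covered <- sample(tgt, ceiling(spec$bridge_cover_fraction * length(tgt)))
      extra <- sample(setdiff(genes, c(covered, tf)),
                      max(0, reg_size(1) - length(covered)))
      regulons <- rbind(regulons, data.frame(tf = tf, target = c(covered, extra)))
      planted_bridge[[tf]] <- list(network = k, covered_targets = covered)
    }
  }
  for (tf in decoys)
    regulons <- rbind(regulons, data.frame(
      tf = tf, target = sample(setdiff(genes, tf),
                               min(reg_size(1), length(genes) - 1))))
  self <- sample(tfs, round(spec$self_target_fraction * length(tfs)))
  if (length(self))
    regulons <- rbind(regulons, data.frame(tf = self, target = self))
  regulons <- unique(regulons)

  truth$planted_bridge_tfs <- planted_bridge
  truth$decoy_tfs <- decoys
  truth$tf_universe <- tfs
  list(ppi = ppi, regulons = regulons, truth = truth)
}

# expand condition mean matrices for one chromosome pair
hic_condition_mean <- function(spec, chrom_a, chrom_b, n_a, n_b, blocks) {
  if (chrom_a == chrom_b) {
    d <- abs(outer(seq_len(n_a), seq_len(n_a), "-"))
    M <- spec$cis_scale * (1 + d)^(-spec$cis_decay_exponent)
  } else {
    M <- matrix(spec$trans_mean, n_a, n_b)
  }
  if (!is.null(blocks) && nrow(blocks)) {
    for (r in seq_len(nrow(blocks))) {
      ri <- (blocks$r0[r] + 1):blocks$r1[r]
      ci <- (blocks$c0[r] + 1):blocks$c1[r]
      M[ri, ci] <- M[ri, ci] + blocks$shift[r]
      if (chrom_a == chrom_b) M[ci, ri] <- M[ci, ri] + blocks$shift[r]
    }
  }
  M
}

#' Simulate the Hi-C maps of both conditions
#'
#' Cis background mean is proportional to (1 + |i - j|)^(-gamma); trans
#' background is a low constant. Planted contiguous blocks add a mean shift:
#' young-specific blocks sit over the down-gene anchor regions, old-specific
#' blocks over the up-gene anchors, and `n_shared_blocks` shared trans
#' blocks are placed at random positions. Replicates add independent
#' Gaussian noise (sd `replicate_noise_sd`) around the condition mean,
#' truncated at zero.
#'
#' @param spec A `sim_spec`.
#' @param sim Output with `truth` containing the anchors (truth is updated
#'   with `planted_blocks`).
#' @param blacklist Optional BED data frame; planting a block over a
#'   blacklisted bin is an error.
#' @param n_planted_specific Condition-specific blocks per anchor pair
#'   (default 1; 0 disables condition-specific planting).
#' @return List: `samples` (list of 4 `hic_sample`s:
#'   young/old x rep1/rep2), `truth`.
#' @export
simulate_hic <- function(spec, sim, blacklist = NULL, n_planted_specific = 1L) {
  set.seed(spec$seed + 2L)
  truth <- sim$truth
  chroms <- names(spec$chrom_sizes)
  n_bins <- setNames(as.integer(ceiling(spec$chrom_sizes / spec$resolution)), chroms)
  bins <- data.frame(chrom = chroms, n_bins = unname(n_bins))

  mk_block <- function(chrom_a, chrom_b, bins_a, bins_b, condition) {
    data.frame(chrom_a = chrom_a, chrom_b = chrom_b,
               r0 = min(bins_a), r1 = max(bins_a) + 1L,
               c0 = min(bins_b), c1 = max(bins_b) + 1L,
               shift = runif(1, spec$block_shift_range[1],
                             spec$block_shift_range[2]),
               condition = condition)
  }
  blocks <- NULL
  if (n_planted_specific > 0) {
    an <- truth$anchors
    for (i in seq_len(n_planted_specific)) {
      blocks <- rbind(blocks,
        mk_block(an$down$chrom_a, an$down$chrom_b, an$down$bins_a,
                 an$down$bins_b, "young"),
        mk_block(an$up$chrom_a, an$up$chrom_b, an$up$bins_a,
                 an$up$bins_b, "old"))
    }
  }
  # shared TAD-like cis domains tiling each diagonal: identical in both
  # conditions, so intrachromosomal LAS coverage is condition-stable
  domains <- NULL
  for (ch in chroms) {
    pos <- 0L
    while (pos < n_bins[ch]) {
      w <- min(sample(8:12, 1), n_bins[ch] - pos)
      if (w >= 4)
        domains <- rbind(domains, mk_block(ch, ch, pos:(pos + w - 1),
                                           pos:(pos + w - 1), "shared"))
      pos <- pos + w
    }
  }
  blocks <- rbind(blocks, domains)
  pairs <- t(combn(chroms, 2))
  for (i in seq_len(spec$n_shared_blocks)) {
    pr <- pairs[sample(nrow(pairs), 1), ]
    w <- sample(spec$block_size_range[1]:spec$block_size_range[2], 2, replace = TRUE)
    r0 <- sample(0:(n_bins[pr[1]] - w[1]), 1)
    c0 <- sample(0:(n_bins[pr[2]] - w[2]), 1)
    blocks <- rbind(blocks, mk_block(pr[1], pr[2], r0:(r0 + w[1] - 1),
                                     c0:(c0 + w[2] - 1), "shared"))
  }
  if (!is.null(blacklist) && !is.null(blocks)) {
    for (r in seq_len(nrow(blocks))) {
      mask_a <- bins_overlapping(blacklist[blacklist$chrom == blocks$chrom_a[r], ],
                                 n_bins[blocks$chrom_a[r]], spec$resolution)
      mask_b <- bins_overlapping(blacklist[blacklist$chrom == blocks$chrom_b[r], ],
                                 n_bins[blocks$chrom_b[r]], spec$resolution)
      if (any(mask_a[(blocks$r0[r] + 1):blocks$r1[r]]) ||
          any(mask_b[(blocks$c0[r] + 1):blocks$c1[r]]))
        stop("planted block overlaps a blacklisted region")
    }
  }

  all_pairs <- rbind(cbind(chroms, chroms), pairs)
  samples <- list()
  for (cond in c("young", "old")) {
    means <- list()
    for (p in seq_len(nrow(all_pairs))) {
      ca <- all_pairs[p, 1]; cb <- all_pairs[p, 2]
      bl <- if (is.null(blocks)) NULL
            else blocks[blocks$chrom_a == ca & blocks$chrom_b == cb &
                          blocks$condition %in% c(cond, "shared"), , drop = FALSE]
      means[[pair_key(ca, cb)]] <- hic_condition_mean(spec, ca, cb,
                                                      n_bins[ca], n_bins[cb], bl)
    }
    for (rep_id in 1:2) {
      maps <- list()
      for (key in names(means)) {
        chr <- strsplit(key, "|", fixed = TRUE)[[1]]
        M <- means[[key]]
        if (spec$replicate_noise_sd > 0) {
          E <- matrix(rnorm(length(M), 0, spec$replicate_noise_sd),
                      nrow(M), ncol(M))
          if (chr[1] == chr[2]) E <- (E + t(E)) / 2
          M <- pmax(M + E, 0)
        }
        maps[[key]] <- contact_map(chr[1], chr[2], M, spec$resolution,
                                   condition = cond, replicate = rep_id)
      }
      samples[[sprintf("%s_rep%d", cond, rep_id)]] <-
        hic_sample(maps, bins, spec$resolution, cond, rep_id)
    }
  }
  truth$planted_blocks <- blocks
  list(samples = samples, truth = truth)
}

#' Write the planted ground truth as JSON
#' @param truth Ground-truth list from the simulators.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
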