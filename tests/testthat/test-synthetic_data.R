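test_that("the count generator honours NB moments, determinism and effect planting", {
  # Poisson limit: dispersion -> 0 gives variance/mean -> 1
  spec0 <- sim_spec(n_per_group = 100L, n_genes = 5L, dispersion = 0,
                    n_trend = 0L, n_de_per_transition = 0L,
                    libsize_range = c(1, 1), seed = 2)
  sim0 <- simulate_cohort_counts(spec0)
  vm <- apply(sim0$cohort$counts, 1, var) / rowMeans(sim0$cohort$counts)
  expect_true(all(abs(vm - 1) < 0.35))
  # identical seed twice -> identical count matrix
  s1 <- simulate_cohort_counts(sim_spec(seed = 5))
  s2 <- simulate_cohort_counts(sim_spec(seed = 5))
  expect_identical(s1$cohort$counts, s2$cohort$counts)
  # fewer than 2 samples per group is rejected
  expect_error(sim_spec(n_per_group = 1L), ">= 2")
  # planted DE magnitudes respect the stated minimum
  expect_true(all(abs(unlist(lapply(s1$truth$transition_de, `[[`, "log2fc"))) >= 1))
  # trend genes have monotone expected log-mean in age: positive-slope genes
  # correlate positively with age
  tg <- s1$truth$trend_genes
  vst <- vst_transform(s1$cohort)
  cors <- sapply(seq_len(nrow(tg)), function(i)
    cor(vst$mat[tg$gene[i], ], s1$cohort$ages))
  expect_gt(mean(sign(cors) == sign(tg$slope)), 0.9)
})

test_that("length coupling drives (or removes) the slope-length correlation", {
  spec0 <- sim_spec(length_coupling = 0, seed = 13)
  sim0 <- simulate_cohort_counts(spec0)
  r0 <- cor(sim0$truth$overall_effect,
            log(sim0$catalog$transcript_length[match(names(sim0$truth$overall_effect),
                                                     sim0$catalog$gene)]))
  expect_lt(abs(r0), 0.1)
  spec1 <- sim_spec(length_coupling = 0.6, seed = 13)
  sim1 <- simulate_cohort_counts(spec1)
  r1 <- cor(sim1$truth$overall_effect,
            log(sim1$catalog$transcript_length[match(names(sim1$truth$overall_effect),
                                                     sim1$catalog$gene)]))
  expect_gt(r1, 0.3)
})

test_that("planted bridge TFs are enriched by construction and decoys are null-calibrated", {
  w <- small_world()
  M <- nrow(w$cohort$counts)
  targets <- split(w$regulons$target, w$regulons$tf)
  n_tf <- length(w$truth$tf_universe)
  for (tf in names(w$truth$planted_bridge_tfs)) {
    k <- w$truth$planted_bridge_tfs[[tf]]$network
    de <- w$truth$transition_de[[as.character(k + 1)]]$gene
    enr <- tf_target_enrichment(targets[tf], de, M)
    expect_lt(enr$p, 0.05 / n_tf)
  }
  # decoy enrichment p-values are uniform under the null across replicates
  # (mid-p variant removes the discreteness of the hypergeometric support)
  ps <- c()
  for (seed in 1:5) {
    spec <- sim_spec(seed = 100 + seed)
    sim <- simulate_cohort_counts(spec)
    sim2 <- simulate_interactome(spec, sim)
    tg <- split(sim2$regulons$target, sim2$regulons$tf)
    for (tf in sim2$truth$decoy_tfs) {
      de <- sim2$truth$transition_de[["2"]]$gene
      N <- length(unique(tg[[tf]]))
      k <- length(intersect(tg[[tf]], de))
      M2 <- nrow(sim$cohort$counts)
      p_ge <- phyper(k - 1, length(de), M2 - length(de), N, lower.tail = FALSE)
      p_gt <- phyper(k, length(de), M2 - length(de), N, lower.tail = FALSE)
      ps <- c(ps, (p_ge + p_gt) / 2)
    }
  }
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("self-target planting matches the requested fraction", {
  w <- small_world()
  tfs <- w$truth$tf_universe
  self <- sum(vapply(tfs, function(t)
    any(w$regulons$tf == t & w$regulons$target == t), logical(1)))
  expected <- round(w$spec$self_target_fraction * length(tfs))
  expect_identical(self, as.integer(expected))
})

test_that("the Hi-C generator obeys replicate noise, decay, masks and symmetry", {
  # replicate noise sd 0 -> identical replicates
  spec <- sim_spec(replicate_noise_sd = 0, seed = 9)
  sim <- simulate_cohort_counts(spec)
  sim2 <- simulate_interactome(spec, sim)
  hic <- simulate_hic(spec, list(truth = sim2$truth))
  expect_identical(hic$samples$young_rep1$maps[["chr1|chr2"]]$mat,
                   hic$samples$young_rep2$maps[["chr1|chr2"]]$mat)
  # cis maps symmetric
  cis <- hic$samples$young_rep1$maps[["chr1|chr1"]]$mat
  expect_equal(cis, t(cis))
  # planted gamma = 1 gives a log-log decay slope of -1 +- 0.1 (raw mean)
  prof <- distance_decay_profile(hic$samples$young_rep1$maps[["chr1|chr1"]])
  keep <- prof$separation > 12 & !is.na(prof$mean_contact)  # off TAD-domain diagonal
  fit <- lm(log(mean_contact) ~ log(1 + separation), data = prof[keep, ])
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  # a blacklist overlapping a planted block is an error
  anchors <- sim2$truth$anchors
  bl <- data.frame(chrom = anchors$down$chrom_a,
                   start = min(anchors$down$bins_a) * spec$resolution,
                   end = (min(anchors$down$bins_a) + 1) * spec$resolution)
  expect_error(simulate_hic(spec, list(truth = sim2$truth), blacklist = bl),
               "blacklisted")
  # every planted object is recoverable from outputs: block intervals lie in
  # bounds and truth records all conditions
  blocks <- hic$truth$planted_blocks
  nb <- setNames(ceiling(spec$chrom_sizes / spec$resolution),
                 names(spec$chrom_sizes))
  expect_true(all(blocks$r1 <= nb[blocks$chrom_a]))
  expect_true(all(blocks$c1 <= nb[blocks$chrom_b]))
  expect_setequal(unique(blocks$condition), c("young", "old", "shared"))
})

test_that("with no planted specific blocks the reconciled LAS stage stays null", {
  # zero condition-specific and zero shared trans blocks: replicate
  # reconciliation must reject pure-noise submatrices
  hits <- 0
  for (seed in 1:10) {
    spec <- sim_spec(seed = 300 + seed, n_shared_blocks = 0L,
                     n_per_group = 2L, n_genes = 100L, n_trend = 5L,
                     n_de_per_transition = 5L, n_bridge_per_network = 1L,
                     n_decoy_tfs = 3L, n_ppi_extra = 20L,
                     regulon_size_range = c(5, 15))
    sim <- simulate_cohort_counts(spec)
    sim2 <- simulate_interactome(spec, sim)
    hic <- simulate_hic(spec, list(truth = sim2$truth),
                        n_planted_specific = 0L)
    proc <- lapply(hic$samples[c("young_rep1", "young_rep2")], function(s)
      log_zscore(balance_hic(mask_excluded_regions(s))))
    key <- "chr1|chr2"
    l1 <- las_decompose(proc$young_rep1$maps[[key]], 20, 5, 8, seed = 1,
                        max_len = 16)
    l2 <- las_decompose(proc$young_rep2$maps[[key]], 20, 5, 8, seed = 2,
                        max_len = 16)
    rec <- reconcile_replicates(l1, l2, proc$young_rep1$maps[[key]],
                                proc$young_rep2$maps[[key]], 20)
    if (nrow(rec$kept) > 0) hits <- hits + 1
  }
  expect_lte(hits, 1)   # null in at least 9 of 10 seeds
})
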