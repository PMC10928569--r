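toy_hic <- function(n = 24, seed = 1, sd = 0.5) {
  set.seed(seed)
  m <- 40 * (1 + abs(outer(1:n, 1:n, "-")))^-1
  e <- matrix(rnorm(n * n, 0, sd), n, n); e <- (e + t(e)) / 2
  cis <- contact_map("chrA", "chrA", pmax(m + e, 0), 1e5, "young", 1L)
  mk_tr <- function(a, b, na, nb)
    contact_map(a, b, pmax(matrix(5 + rnorm(na * nb), na, nb), 0), 1e5,
                "young", 1L)
  hic_sample(list("chrA|chrA" = cis,
                  "chrA|chrB" = mk_tr("chrA", "chrB", n, 20L),
                  "chrA|chrC" = mk_tr("chrA", "chrC", n, 16L),
                  "chrB|chrC" = mk_tr("chrB", "chrC", 20L, 16L)),
             bins = data.frame(chrom = c("chrA", "chrB", "chrC"),
                               n_bins = c(n, 20L, 16L)),
             resolution = 1e5, condition = "young", replicate = 1L)
}

test_that("masking follows the any-overlap rule and the pericentromeric flank arithmetic", {
  s <- toy_hic()
  # a centromere of one 100 kb bin with a 400 kb flank masks 4 bins each side
  cen <- data.frame(chrom = "chrA", start = 10e5, end = 11e5)
  ms <- mask_excluded_regions(s, centromeres = cen, flank_bp = 4e5)
  mask <- attr(ms, "bin_mask")$chrA
  expect_identical(which(mask), 7:15)   # bin 11 +- 4
  expect_true(all(is.na(ms$maps[["chrA|chrA"]]$mat[7:15, ])))
  expect_true(all(is.na(ms$maps[["chrA|chrB"]]$mat[7:15, ])))
  # 2 Mb flank at 250 kb resolution masks 8 bins on each side
  s2 <- hic_sample(list("c1|c1" = contact_map("c1", "c1",
                                              matrix(1, 40, 40), 250000)),
                   data.frame(chrom = "c1", n_bins = 40L), 250000, "x", 1L)
  cen2 <- data.frame(chrom = "c1", start = 20 * 250000, end = 21 * 250000)
  m2 <- attr(mask_excluded_regions(s2, centromeres = cen2), "bin_mask")$c1
  expect_identical(sum(m2), 1L + 16L)
  # empty blacklist leaves the map unchanged
  s3 <- mask_excluded_regions(s)
  expect_equal(s3$maps[["chrA|chrA"]]$mat, s$maps[["chrA|chrA"]]$mat)
  # a bin half-overlapping a blacklist interval is masked
  bl <- data.frame(chrom = "chrA", start = 5e4, end = 1.2e5)
  s4 <- mask_excluded_regions(s, blacklist = bl)
  expect_identical(which(attr(s4, "bin_mask")$chrA), 1:2)
  # idempotence
  s5 <- mask_excluded_regions(s4, blacklist = bl)
  expect_equal(s5$maps[["chrA|chrA"]]$mat, s4$maps[["chrA|chrA"]]$mat)
})

test_that("iterative proportional fitting reaches a doubly stochastic matrix", {
  # constant positive matrix is a fixed point up to scale
  cm <- matrix(2, 10, 10)
  b <- sinkhorn_balance(cm)
  expect_equal(unname(rowSums(b)), rep(1, 10), tolerance = 1e-9)
  expect_true(max(abs(b - 0.1)) < 1e-9)
  # random positive matrix balances to within 1e-6
  set.seed(12)
  r <- matrix(runif(2500, 0.1, 5), 50, 50)
  br <- sinkhorn_balance(r)
  expect_lt(max(abs(rowSums(br) - 1)), 1e-6)
  expect_lt(max(abs(colSums(br) - 1)), 1e-6)
  # an all-zero row is auto-masked with a warning
  rz <- r; rz[7, ] <- 0; rz[, 7] <- 0
  expect_warning(bz <- sinkhorn_balance(rz), "auto-masking")
  expect_true(all(is.na(bz[7, ])))
  # cis balancing preserves symmetry
  s <- balance_hic(mask_excluded_regions(toy_hic()), mode = "intra")
  cis <- s$maps[["chrA|chrA"]]$mat
  expect_equal(cis, t(cis))
})

test_that("log/z-scoring zeroes trans moments and keeps cis and trans moments separate", {
  s <- log_zscore(balance_hic(mask_excluded_regions(toy_hic())))
  trans <- unlist(lapply(s$maps[c("chrA|chrB", "chrA|chrC", "chrB|chrC")],
                         function(m) m$mat[is.finite(m$mat)]))
  expect_equal(mean(trans), 0, tolerance = 1e-9)
  expect_equal(sd(trans), 1, tolerance = 1e-6)
  cis <- s$maps[["chrA|chrA"]]$mat
  expect_equal(mean(cis[is.finite(cis)]), 0, tolerance = 1e-9)
  # an identical raw value gets different z in cis and trans (separate moments)
  expect_false(isTRUE(all.equal(sd(cis[is.finite(cis)]) * 0 + mean(cis[is.finite(cis)]),
                                mean(trans[is.finite(trans)]) + 1)))
  # log(0 + 1) = 0 before z-scoring
  z <- contact_map("a", "a", matrix(0, 4, 4), 1)
  s0 <- hic_sample(list("a|a" = z), data.frame(chrom = "a", n_bins = 4L), 1, "x", 1L)
  expect_error(log_zscore(s0), "zero standard deviation")
})

test_that("distance decay recovers the planted exponent and degenerates sensibly", {
  n <- 60
  m <- 100 * (1 + abs(outer(1:n, 1:n, "-")))^-1
  map <- contact_map("c", "c", m, 1e5)
  prof <- distance_decay_profile(map)
  fit <- lm(log(mean_contact) ~ log(1 + separation),
            data = prof[prof$separation > 0, ])
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  # constant matrix -> flat profile
  pc <- distance_decay_profile(contact_map("c", "c", matrix(3, 10, 10), 1e5))
  expect_true(all(pc$mean_contact == 3))
  # fully masked separations are reported missing
  mm <- m; mm[abs(outer(1:n, 1:n, "-")) == 2] <- NA
  pm <- distance_decay_profile(contact_map("c", "c", mm, 1e5))
  expect_true(is.na(pm$mean_contact[pm$separation == 2]))
})

test_that("insulation is zero on constant maps and dips at planted boundaries", {
  cm <- contact_map("c", "c", matrix(4, 30, 30), 1e5)
  ins <- insulation_profile(cm, 3)
  expect_true(all(abs(ins[!is.na(ins)]) < 1e-12))
  # two-block structure: minimum at the boundary
  n <- 40
  blocky <- matrix(1, n, n)
  blocky[1:20, 1:20] <- 6; blocky[21:40, 21:40] <- 6
  set.seed(3)
  e <- matrix(rnorm(n * n, 0, 0.2), n, n); blocky <- pmax(blocky + (e + t(e)) / 2, 0)
  insb <- insulation_profile(contact_map("c", "c", blocky, 1e5), 5)
  expect_equal(which.min(insb), 21, tolerance = 1)
  expect_error(insulation_profile(cm, 20), "window")
})

test_that("submatrix scores follow the Gaussian-tail formula and are monotone in the mean", {
  M <- matrix(0, 8, 6)
  sc <- score_submatrix(M, 2:4, 3:5)
  expect_equal(sc$score, -log((8 - 3 + 1) * (6 - 3 + 1) * 0.5))
  # single-cell endpoint
  one <- matrix(1.7, 1, 1)
  expect_equal(score_submatrix(one, 1, 1)$score, -log(pnorm(-1.7)))
  # strictly increasing in tau at fixed shape
  scores <- sapply(c(0, 0.5, 1, 2), function(tau)
    score_submatrix(matrix(tau, 8, 6), 2:4, 3:5)$score)
  expect_true(all(diff(scores) > 0))
  # masked entries leave tau and the effective count
  Mm <- matrix(2, 8, 6); Mm[2, 3] <- NA
  scm <- score_submatrix(Mm, 2:4, 3:5)
  expect_identical(scm$k_eff, 8L)
  expect_error(score_submatrix(matrix(NA_real_, 2, 2), 1:2, 1:2), "unmasked")
  # subset variant uses binomial multiplicities
  sub <- score_submatrix(matrix(1, 8, 6), 2:4, 3:5, variant = "subset")
  expect_equal(sub$score,
               -(lchoose(8, 3) + lchoose(6, 3) + pnorm(-1 * 3, log.p = TRUE)))
})

test_that("LAS decomposition matches the exhaustive oracle and residual scores never increase", {
  set.seed(41)
  for (i in 1:10) {
    M <- matrix(rnorm(120), 12, 10)
    d <- las_decompose(M, score_threshold = -20, max_submatrices = 6, seed = i)
    expect_equal(d$score[1], brute_force_las(M), tolerance = 1e-9)
    expect_true(all(diff(d$score) <= 1e-9))
  }
  # an all-zeros matrix yields nothing above a positive threshold
  z <- matrix(0, 15, 15)
  expect_identical(nrow(las_decompose(z, score_threshold = 1)), 0L)
  # recorded tau is recomputable from the original matrix
  set.seed(5)
  Mp <- matrix(rnorm(400), 20, 20); Mp[4:9, 11:16] <- Mp[4:9, 11:16] + 3
  dp <- las_decompose(Mp, score_threshold = 10, max_submatrices = 3, seed = 1)
  expect_equal(dp$tau[1],
               mean(Mp[(dp$r0[1] + 1):dp$r1[1], (dp$c0[1] + 1):dp$c1[1]]),
               tolerance = 1e-9)
})

test_that("replicate reconciliation keeps blocks that rescore in both replicates", {
  set.seed(19)
  base <- matrix(rnorm(900), 30, 30)
  blk <- matrix(0, 30, 30); blk[5:10, 20:25] <- 2.5
  m1 <- contact_map("a", "b", matrix(0, 30, 30), 1); m1$mat <- base + blk
  m2 <- contact_map("a", "b", matrix(0, 30, 30), 1)
  m2$mat <- matrix(rnorm(900), 30, 30) + blk
  l1 <- las_decompose(m1, score_threshold = 8, max_submatrices = 5, seed = 1)
  l2 <- las_decompose(m2, score_threshold = 8, max_submatrices = 5, seed = 2)
  rec <- reconcile_replicates(l1, l2, m1, m2, score_threshold = 8)
  expect_gt(nrow(rec$kept), 0)
  planted_px <- paste("a", rep(4:9, 6), "b", rep(19:24, each = 6), sep = ":")
  expect_gte(mean(planted_px %in% rec$pixels), 0.9)
  # identical replicates keep everything with correlation 1
  rec2 <- reconcile_replicates(l1, l1, m1, m1, score_threshold = 8)
  expect_identical(nrow(rec2$kept), 2L * nrow(l1))
  if (nrow(l1) >= 2) expect_equal(rec2$correlation, 1)
  # a block above threshold in one replicate only is dropped
  noise2 <- contact_map("a", "b", matrix(0, 30, 30), 1)
  set.seed(77); noise2$mat <- matrix(rnorm(900), 30, 30)
  l2n <- las_decompose(noise2, score_threshold = 8, max_submatrices = 5, seed = 3)
  rec3 <- reconcile_replicates(l1, l2n, m1, noise2, score_threshold = 8)
  expect_identical(nrow(rec3$kept), 0L)
  expect_error(reconcile_replicates(l1, l2, m1, toy_hic()$maps[[2]]), "shape")
})

test_that("difference maps label pixels and compute specificity", {
  y <- c("c1:1:c2:5", "c1:2:c2:5", "c1:1:c1:3")
  o <- c("c1:2:c2:5", "c2:4:c2:6")
  d <- build_difference_map(y, o)
  expect_identical(unname(d$labels["c1:1:c2:5"]), "young_only")
  expect_identical(unname(d$labels["c1:2:c2:5"]), "shared")
  expect_identical(unname(d$labels["c2:4:c2:6"]), "old_only")
  # disjoint sets -> specificity 1; identical sets -> 0
  expect_equal(build_difference_map("a:1:b:1", "a:2:b:2")$summary$specificity[3], 1)
  expect_equal(build_difference_map(y, y)$summary$specificity[3], 0)
  # 10 + 5 specific out of 100 -> 0.15
  ys <- paste0("a:", 1:95, ":b:1")   # 85 shared + 10 young-only
  os <- paste0("a:", c(11:95, 96:100), ":b:1")
  expect_equal(build_difference_map(ys, os)$summary$specificity[3], 0.15)
})
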