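# Shared fixture builders; everything is generated in code at test time.

toy_counts <- function(n_genes = 10, n_samples = 6, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  cohort_counts(m, setNames(seq(5, 90, length.out = n_samples),
                            colnames(m)))
}

toy_catalog <- function(genes, seed = 1) {
  set.seed(seed)
  n <- length(genes)
  start <- sample(0:1e6, n)
  len <- sample(500:3000, n, replace = TRUE)
  gene_catalog(data.frame(gene = genes, chrom = "chr1", start = start,
                          end = start + len, strand = "+",
                          transcript_length = len))
}

toy_ppi <- function() {
  transform_edge_costs(data.frame(
    protein_a = c("a", "b", "c", "a"),
    protein_b = c("b", "c", "d", "c"),
    score = c(1000, 575, 150, 800)))
}

# small random prized instance for PCST checks
random_pcst_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:12, 1)
  m <- min(sample((n - 1):(n + 2), 1), n * (n - 1) / 2)
  all_pairs <- t(combn(n, 2))
  pick <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
  list(nodes = data.frame(id = paste0("v", seq_len(n)),
                          gene = paste0("v", seq_len(n)),
                          prize = ifelse(runif(n) < 0.5,
                                         round(runif(n, 0.5, 5), 2), 0),
                          kind = "ppi"),
       edges = data.frame(a = paste0("v", pick[, 1]),
                          b = paste0("v", pick[, 2]),
                          cost = round(runif(m, 0.1, 3), 2), kind = "ppi"))
}

# independent PCST oracle: enumerate all edge subsets forming forests;
# untouched nodes take the cheaper of exclusion (beta * prize) or a
# singleton tree (omega)
brute_force_pcst <- function(nodes, edges, beta, omega) {
  n <- nrow(nodes); m <- nrow(edges)
  idx <- setNames(seq_len(n), nodes$id)
  best <- sum(pmin(beta * nodes$prize, omega))
  for (code in seq_len(2^m - 1)) {
    sel <- as.logical(bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L))
    ea <- idx[edges$a[sel]]; eb <- idx[edges$b[sel]]
    parent <- seq_len(n); ok <- TRUE
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (k in seq_along(ea)) {
      ra <- find(ea[k]); rb <- find(eb[k])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    touched <- unique(c(ea, eb))
    ntrees <- length(touched) - sum(sel)
    obj <- sum(edges$cost[sel]) + omega * ntrees +
      sum(pmin(beta * nodes$prize[-touched], omega))
    if (obj < best) best <- obj
  }
  best
}

# independent LAS oracle: plain loops over every contiguous interval pair
brute_force_las <- function(M) {
  m <- nrow(M); n <- ncol(M); best <- -Inf
  for (r0 in 1:m) for (r1 in r0:m) for (c0 in 1:n) for (c1 in c0:n) {
    v <- M[r0:r1, c0:c1]
    tau <- mean(v); kl <- length(v)
    s <- -(log(m - (r1 - r0 + 1) + 1) + log(n - (c1 - c0 + 1) + 1) +
             pnorm(-tau * sqrt(kl), log.p = TRUE))
    if (s > best) best <- s
  }
  best
}

# one small synthetic world reused across integration-level tests
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sim_spec(seed = 7)
      sim <- simulate_cohort_counts(spec)
      sim2 <- simulate_interactome(spec, sim)
      hic <- simulate_hic(spec, list(truth = sim2$truth))
      cache <<- list(spec = spec, cohort = sim$cohort, catalog = sim$catalog,
                     ppi = sim2$ppi, regulons = sim2$regulons,
                     hic = hic$samples, truth = hic$truth)
    }
    cache
  }
})

# processed Hi-C + difference map for the small world (cached)
small_world_hic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world()
      proc <- lapply(w$hic, function(s)
        log_zscore(balance_hic(mask_excluded_regions(s))))
      las <- lapply(proc, function(s)
        lapply(s$maps, function(m)
          las_decompose(m, 20, 20, 8, seed = 3, max_len = 16)))
      pixels <- list()
      for (cond in c("young", "old")) {
        r1 <- paste0(cond, "_rep1"); r2 <- paste0(cond, "_rep2")
        px <- character(0)
        for (key in names(proc[[r1]]$maps)) {
          rec <- reconcile_replicates(las[[r1]][[key]], las[[r2]][[key]],
                                      proc[[r1]]$maps[[key]],
                                      proc[[r2]]$maps[[key]], 20)
          px <- c(px, rec$pixels)
        }
        pixels[[cond]] <- unique(px)
      }
      diff <- build_difference_map(pixels$young, pixels$old)
      locus_map <- map_genes_to_loci(w$catalog, w$spec$resolution,
                                     proc[[1]]$bins,
                                     attr(proc[[1]], "bin_mask"))
      cache <<- list(proc = proc, las = las, pixels = pixels, diff = diff,
                     locus_map = locus_map)
    }
    cache
  }
})
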