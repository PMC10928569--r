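# Bridge-TF set comparisons and TF-level null-model statistics.

#' Partition bridge TFs by network membership
#'
#' Classifies every bridge TF found in the three solved networks by its exact
#' membership pattern (S1-specific, S2-specific, S3-specific, pairwise
#' combinations, or shared by all three).
#'
#' @param s1,s2,s3 Role-classified `steiner_network`s.
#' @return Long data frame `tf, in_s1, in_s2, in_s3, pattern` (UpSet-ready).
#' @export
partition_bridge_tfs <- function(s1, s2, s3) {
  sets <- list(S1 = bridge_tfs(s1), S2 = bridge_tfs(s2), S3 = bridge_tfs(s3))
  tfs <- sort(unique(unlist(sets)))
  m <- vapply(sets, function(s) tfs %in% s, logical(length(tfs)))
  if (is.null(dim(m)))
    m <- matrix(m, nrow = length(tfs), dimnames = list(NULL, names(sets)))
  pattern <- apply(m, 1, function(row) {
    inn <- names(sets)[row]
    if (length(inn) == 3) "shared"
    else if (length(inn) == 1) paste0(inn, "-specific")
    else paste(inn, collapse = "+")
  })
  data.frame(tf = tfs, in_s1 = m[, "S1"], in_s2 = m[, "S2"], in_s3 = m[, "S3"],
             pattern = if (length(tfs)) pattern else character(0),
             stringsAsFactors = FALSE)
}

#' Regulatory network among a TF set
#'
#' Edges are regulon pairs with both endpoints inside the TF set (self-loops
#' included). Density = edges / nodes; the self-target fraction is the
#' fraction of TFs in the set with a self-loop.
#'
#' @param tf_set Character vector of TFs.
#' @param regulons Data frame `tf, target`.
#' @return List: `edges` (data frame), `density`, `self_target_fraction`.
#' @export
tf_regulatory_network <- function(tf_set, regulons) {
  if (!length(tf_set)) stop("tf_set must be non-empty")
  tf_set <- unique(tf_set)
  e <- regulons[regulons$tf %in% tf_set & regulons$target %in% tf_set, ,
                drop = FALSE]
  list(edges = e,
       density = nrow(e) / length(tf_set),
       self_target_fraction = mean(tf_set %in% e$tf[e$tf == e$target]))
}

#' Permutation test for regulatory-network density
#'
#' Draws `n_perm` random TF sets of the observed size (without replacement)
#' from the pool, builds each regulatory network, and reports
#' p = (number of permuted densities >= observed) / n_perm.
#'
#' @param observed_set Character vector of TFs whose density is tested.
#' @param pool Character vector to draw the null sets from.
#' @param regulons Data frame `tf, target`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `p`, `p_label` ("< 1/n_perm" when zero), `observed_density`,
#'   `null_densities`.
#' @export
density_permutation_test <- function(observed_set, pool, regulons,
                                     n_perm = 1000L, seed = 1L) {
  size <- length(unique(observed_set))
  pool <- unique(pool)
  if (length(pool) < size) stop("pool smaller than the observed set")
  obs <- tf_regulatory_network(observed_set, regulons)$density
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    tf_regulatory_network(sample(pool, size), regulons)$density, numeric(1))
  p <- sum(null >= obs) / n_perm
  list(p = p,
       p_label = if (p == 0) sprintf("< %g", 1 / n_perm) else format(p),
       observed_density = obs, null_densities = null)
}

# Upper-tail hypergeometric P[X >= k] for overlap k of a size-N draw with n
# successes in a universe of M.
hyper_tail <- function(k, M, n, N) {
  if (N > M || n > M) stop("N and n must not exceed the universe M")
  stats::phyper(k - 1, m = n, n = M - n, k = N, lower.tail = FALSE)
}

#' Co-target network among bridge TFs
#'
#' For each TF pair, the probability of observing at least the seen number of
#' shared DE targets under a hypergeometric null over the DE-target universe;
#' an edge is admitted when p is below `p_threshold` and the Jaccard
#' proportion |intersection| / |union| strictly exceeds
#' `proportion_threshold`.
#'
#' @param target_sets Named list: per TF, its DE-target gene set.
#' @param universe DE-target universe (character vector).
#' @param p_threshold Hypergeometric cutoff (default 1e-15).
#' @param proportion_threshold Jaccard cutoff (default 0.5, strict).
#' @return Data frame `tf1, tf2, k, proportion, p, kept` (all tested pairs),
#'   with node weights (`n_targets`) as an attribute.
#' @export
cotarget_network <- function(target_sets, universe, p_threshold = 1e-15,
                             proportion_threshold = 0.5) {
  target_sets <- lapply(target_sets, function(s) intersect(unique(s), universe))
  tfs <- names(target_sets)
  M <- length(unique(universe))
  out <- NULL
  if (length(tfs) >= 2) {
    pairs <- combn(tfs, 2)
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      t1 <- target_sets[[pairs[1, i]]]; t2 <- target_sets[[pairs[2, i]]]
      k <- length(intersect(t1, t2))
      uni <- length(union(t1, t2))
      prop <- if (uni) k / uni else 0
      p <- hyper_tail(k, M, length(t1), length(t2))
      data.frame(tf1 = pairs[1, i], tf2 = pairs[2, i], k = k,
                 proportion = prop, p = p,
                 kept = p < p_threshold & prop > proportion_threshold)
    }))
  }
  if (is.null(out))
    out <- data.frame(tf1 = character(), tf2 = character(), k = integer(),
                      proportion = numeric(), p = numeric(), kept = logical())
  attr(out, "n_targets") <- vapply(target_sets, length, integer(1))
  out
}

#' Hypergeometric enrichment of target-DE genes per bridge TF
#'
#' For each TF: out of M universe genes, n are target-DE; the TF targets N
#' genes genome-wide, k of them DE. Raw p = P[X >= k] under
#' Hypergeom(M, n, N); Bonferroni correction over the network's bridge TFs;
#' significant at adjusted p < 0.05. The optional sensitivity interval
#' recomputes p over N' in [ceil(0.9 N), floor(1.1 N)] and reports the
#' 2.5-97.5% span.
#'
#' @param tf_targets Named list: per bridge TF, its genome-wide target set.
#' @param de_set Target-DE gene set.
#' @param M Universe size (number of genes in the tested expression
#'   universe).
#' @param interval Compute the p-range over perturbed N (default FALSE).
#' @return Data frame `tf, M, n, N, k, p, p_adj, significant` (+ `p_lo,
#'   p_hi`).
#' @export
tf_target_enrichment <- function(tf_targets, de_set, M, interval = FALSE) {
  de_set <- unique(de_set)
  n <- length(de_set)
  if (n > M) stop("n exceeds the universe M")
  rows <- lapply(names(tf_targets), function(tf) {
    tg <- unique(tf_targets[[tf]])
    N <- length(tg)
    if (N > M) stop("TF target count exceeds the universe M")
    k <- length(intersect(tg, de_set))
    p <- hyper_tail(k, M, n, N)
    row <- data.frame(tf = tf, M = M, n = n, N = N, k = k, p = p)
    if (interval) {
      grid <- seq(ceiling(0.9 * N), floor(1.1 * N))
      grid <- grid[grid >= k & grid <= M - (n - k)]
      ps <- vapply(grid, function(NN) hyper_tail(k, M, n, NN), numeric(1))
      qs <- quantile(ps, c(0.025, 0.975), names = FALSE)
      row$p_lo <- qs[1]; row$p_hi <- qs[2]
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adj < 0.05
  out
}
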