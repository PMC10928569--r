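# Hi-C preprocessing, contiguous large-average-submatrix (LAS) decomposition,
# replicate reconciliation, and binarized intermingling difference maps.

# ---- masking ----------------------------------------------------------------

bins_overlapping <- function(intervals, n_bins, resolution) {
  masked <- rep(FALSE, n_bins)
  if (is.null(intervals) || !nrow(intervals)) return(masked)
  for (r in seq_len(nrow(intervals))) {
    b0 <- max(0L, floor(intervals$start[r] / resolution))
    b1 <- min(n_bins - 1L, floor((intervals$end[r] - 1L) / resolution))
    if (b1 >= b0) masked[(b0 + 1L):(b1 + 1L)] <- TRUE   # any-overlap rule
  }
  masked
}

#' Mask excluded regions in a Hi-C sample
#'
#' Bins overlapping a blacklist interval, or a centromere extended by
#' `flank_bp` in both directions, are masked in both rows and columns of
#' every map (entries set to NA). Masking is idempotent.
#'
#' @param sample A `hic_sample`.
#' @param blacklist BED-convention data frame `chrom, start, end` (or NULL).
#' @param centromeres Same format (or NULL).
#' @param flank_bp Pericentromeric flank in bp (default 2e6).
#' @return The masked `hic_sample`; per-chromosome masks stored in
#'   `attr(, "bin_mask")`.
#' @export
mask_excluded_regions <- function(sample, blacklist = NULL, centromeres = NULL,
                                  flank_bp = 2e6) {
  res <- sample$resolution
  masks <- list()
  for (i in seq_len(nrow(sample$bins))) {
    chrom <- sample$bins$chrom[i]; nb <- sample$bins$n_bins[i]
    m <- rep(FALSE, nb)
    if (!is.null(blacklist))
      m <- m | bins_overlapping(blacklist[blacklist$chrom == chrom, , drop = FALSE],
                                nb, res)
    if (!is.null(centromeres)) {
      cen <- centromeres[centromeres$chrom == chrom, , drop = FALSE]
      if (nrow(cen)) {
        cen$start <- pmax(0, cen$start - flank_bp)
        cen$end <- cen$end + flank_bp
        m <- m | bins_overlapping(cen, nb, res)
      }
    }
    masks[[chrom]] <- m
  }
  for (key in names(sample$maps)) {
    map <- sample$maps[[key]]
    mr <- masks[[map$chrom_a]]; mc <- masks[[map$chrom_b]]
    map$mat[mr, ] <- NA_real_
    map$mat[, mc] <- NA_real_
    map$mask_row <- mr; map$mask_col <- mc
    sample$maps[[key]] <- map
  }
  attr(sample, "bin_mask") <- masks
  sample
}

# ---- balancing --------------------------------------------------------------

#' Iterative proportional fitting to a doubly stochastic matrix
#'
#' Alternates row and column rescaling on the unmasked (finite) entries until
#' every unmasked row and column sum is within relative `tol` of 1. All-zero
#' rows or columns are auto-masked (set to NA) with a warning.
#'
#' @param mat Numeric matrix; NA entries are excluded.
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return The balanced matrix.
#' @export
sinkhorn_balance <- function(mat, tol = 1e-6, max_iter = 5000L) {
  rs <- rowSums(mat, na.rm = TRUE)
  cs <- colSums(mat, na.rm = TRUE)
  dead_r <- rs == 0 & !apply(mat, 1, function(x) all(is.na(x)))
  dead_c <- cs == 0 & !apply(mat, 2, function(x) all(is.na(x)))
  if (any(dead_r) || any(dead_c)) {
    warning(sprintf("auto-masking %d zero-sum rows and %d zero-sum columns",
                    sum(dead_r), sum(dead_c)))
    mat[dead_r, ] <- NA_real_
    mat[, dead_c] <- NA_real_
  }
  live_r <- !apply(mat, 1, function(x) all(is.na(x)))
  live_c <- !apply(mat, 2, function(x) all(is.na(x)))
  for (it in seq_len(max_iter)) {
    rs <- rowSums(mat, na.rm = TRUE)
    mat[live_r, ] <- mat[live_r, , drop = FALSE] / rs[live_r]
    cs <- colSums(mat, na.rm = TRUE)
    mat[, live_c] <- sweep(mat[, live_c, drop = FALSE], 2, cs[live_c], "/")
    rs <- rowSums(mat, na.rm = TRUE); cs <- colSums(mat, na.rm = TRUE)
    dev <- max(abs(rs[live_r] - 1), abs(cs[live_c] - 1), 0)
    if (dev < tol) return(mat)
  }
  stop(sprintf("matrix balancing did not converge: residual %.3g after %d iterations",
               dev, max_iter))
}

genome_bin_offsets <- function(bins) {
  off <- c(0L, cumsum(bins$n_bins))
  setNames(off[-length(off)], bins$chrom)
}

#' Balance all contact maps of a Hi-C sample
#'
#' Intra mode balances each cis map separately; inter mode assembles the
#' genome-wide matrix with all cis blocks removed and balances the trans part
#' into a doubly stochastic matrix, then writes the scaled values back into
#' the per-pair maps.
#'
#' @param sample A masked `hic_sample`.
#' @param mode "intra", "inter", or "both" (default).
#' @param tol Convergence tolerance.
#' @return The `hic_sample` with balanced maps (`state = "balanced"`).
#' @export
balance_hic <- function(sample, mode = c("both", "intra", "inter"), tol = 1e-6) {
  mode <- match.arg(mode)
  if (mode %in% c("both", "intra")) {
    for (key in names(sample$maps)) {
      map <- sample$maps[[key]]
      if (!is_cis(map)) next
      b <- sinkhorn_balance(map$mat, tol = tol)
      map$mat <- (b + t(b)) / 2    # restore exact symmetry
      map$state <- "balanced"
      sample$maps[[key]] <- map
    }
  }
  if (mode %in% c("both", "inter")) {
    off <- genome_bin_offsets(sample$bins)
    total <- sum(sample$bins$n_bins)
    G <- matrix(NA_real_, total, total)
    for (key in names(sample$maps)) {
      map <- sample$maps[[key]]
      if (is_cis(map)) next
      ia <- off[map$chrom_a] + seq_len(nrow(map$mat))
      ib <- off[map$chrom_b] + seq_len(ncol(map$mat))
      G[ia, ib] <- map$mat
      G[ib, ia] <- t(map$mat)
    }
    if (any(is.finite(G))) {
      B <- sinkhorn_balance(G, tol = tol)
      B <- (B + t(B)) / 2
      for (key in names(sample$maps)) {
        map <- sample$maps[[key]]
        if (is_cis(map)) next
        ia <- off[map$chrom_a] + seq_len(nrow(map$mat))
        ib <- off[map$chrom_b] + seq_len(ncol(map$mat))
        map$mat <- B[ia, ib]
        map$state <- "balanced"
        sample$maps[[key]] <- map
      }
    }
  }
  sample
}

# ---- log / z-score ----------------------------------------------------------

#' Log-transform and z-score a balanced Hi-C sample
#'
#' Applies log(x + 1) elementwise, then z-scores cis maps with the mean and
#' sd pooled over all unmasked intrachromosomal entries and trans maps with
#' the moments pooled over all unmasked interchromosomal entries.
#'
#' @param sample A balanced `hic_sample`.
#' @return The sample with `state = "zscored"` maps.
#' @export
log_zscore <- function(sample) {
  for (key in names(sample$maps))
    sample$maps[[key]]$mat <- log1p(sample$maps[[key]]$mat)
  pool <- function(cis) {
    unlist(lapply(sample$maps, function(m)
      if (is_cis(m) == cis) m$mat[is.finite(m$mat)] else NULL))
  }
  for (cis in c(TRUE, FALSE)) {
    vals <- pool(cis)
    if (!length(vals)) next
    mu <- mean(vals); s <- sd(vals)
    if (!is.finite(s) || s == 0) stop("zero standard deviation in z-scoring")
    for (key in names(sample$maps)) {
      if (is_cis(sample$maps[[key]]) != cis) next
      sample$maps[[key]]$mat <- (sample$maps[[key]]$mat - mu) / s
      sample$maps[[key]]$state <- "zscored"
    }
  }
  sample
}

# ---- cis profiles -----------------------------------------------------------

#' Distance-decay profile of a cis map
#'
#' Mean unmasked contact value at each bin separation, with a log2-binned
#' separation column for plotting.
#'
#' @param map A cis `contact_map`.
#' @return Data frame `separation, mean_contact, n, log_bin`; separations
#'   with no unmasked entries are reported as NA.
#' @export
distance_decay_profile <- function(map) {
  if (!is_cis(map)) stop("distance decay is defined for cis maps")
  n <- nrow(map$mat)
  out <- data.frame(separation = 0:(n - 1), mean_contact = NA_real_, n = 0L)
  for (s in 0:(n - 1)) {
    v <- map$mat[cbind(seq_len(n - s), seq_len(n - s) + s)]
    v <- v[is.finite(v)]
    out$n[s + 1] <- length(v)
    if (length(v)) out$mean_contact[s + 1] <- mean(v)
  }
  out$log_bin <- ifelse(out$separation > 0, floor(log2(out$separation)), -1)
  out
}

#' Insulation score profile of a cis map
#'
#' score_i = log2(mean of the unmasked w x w square upstream x downstream of
#' bin i / chromosome-wide mean of such squares). Bins within `window` of an
#' edge, or whose square is fully masked, are NA.
#'
#' @param map A cis `contact_map`.
#' @param window Window size in bins (>= 1).
#' @return Numeric vector of per-bin scores.
#' @export
insulation_profile <- function(map, window) {
  if (!is_cis(map)) stop("insulation is defined for cis maps")
  n <- nrow(map$mat)
  if (window < 1) stop("window must be >= 1")
  if (2 * window >= n) stop("window larger than the chromosome")
  means <- rep(NA_real_, n)
  for (i in (window + 1):(n - window)) {
    sq <- map$mat[(i - window):(i - 1), (i + 1):(i + window), drop = FALSE]
    v <- sq[is.finite(sq)]
    if (length(v)) means[i] <- mean(v)
  }
  gm <- mean(means, na.rm = TRUE)
  if (!is.finite(gm) || gm <= 0) return(rep(NA_real_, n))
  log2(means / gm)
}

# ---- LAS scoring and decomposition -----------------------------------------

las_score_value <- function(tau, k_eff, k, l, m, n, variant = "contiguous") {
  mult <- if (variant == "contiguous") log(m - k + 1) + log(n - l + 1)
          else lchoose(m, k) + lchoose(n, l)
  -(mult + pnorm(-tau * sqrt(k_eff), log.p = TRUE))
}

#' Score one contiguous submatrix under the Gaussian LAS null
#'
#' S = -log[(m - k + 1)(n - l + 1) * Phi(-tau * sqrt(k_eff))] for the default
#' contiguous variant, where tau is the mean of the unmasked entries of the
#' k x l block and k_eff their count; the subset variant replaces the
#' interval multiplicities with binomial coefficients. The Gaussian tail is
#' evaluated in log space.
#'
#' @param mat Z-scored numeric matrix (NA = masked).
#' @param rows,cols Integer index vectors (contiguous).
#' @param variant "contiguous" (default) or "subset".
#' @return List `score, tau, k_eff`.
#' @export
score_submatrix <- function(mat, rows, cols, variant = "contiguous") {
  block <- mat[rows, cols, drop = FALSE]
  v <- block[is.finite(block)]
  if (!length(v)) stop("submatrix has no unmasked entries")
  tau <- mean(v)
  list(score = las_score_value(tau, length(v), length(rows), length(cols),
                               nrow(mat), ncol(mat), variant),
       tau = tau, k_eff = length(v))
}

# All contiguous interval pairs, scored via 2D prefix sums; exact maximum.
las_exhaustive_best <- function(M, variant, max_len = Inf) {
  m <- nrow(M); n <- ncol(M)
  Z <- M; Z[!is.finite(Z)] <- 0
  C <- matrix(as.numeric(is.finite(M)), m, n)
  P <- matrix(0, m + 1, n + 1); Q <- matrix(0, m + 1, n + 1)
  P[-1, -1] <- t(apply(apply(Z, 2, cumsum), 1, cumsum))
  Q[-1, -1] <- t(apply(apply(C, 2, cumsum), 1, cumsum))
  rp <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE) # r0 <= r1
  cp <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  rp <- rp[rp[, 2] - rp[, 1] < max_len, , drop = FALSE]
  cp <- cp[cp[, 2] - cp[, 1] < max_len, , drop = FALSE]
  best <- list(score = -Inf)
  # block over row-interval chunks to bound memory
  chunk <- max(1L, floor(4e6 / nrow(cp)))
  for (s in seq(1, nrow(rp), by = chunk)) {
    idx <- s:min(nrow(rp), s + chunk - 1)
    r0 <- rp[idx, 1]; r1 <- rp[idx, 2]
    SumR <- P[r1 + 1, , drop = FALSE] - P[r0, , drop = FALSE]
    CntR <- Q[r1 + 1, , drop = FALSE] - Q[r0, , drop = FALSE]
    c0 <- cp[, 1]; c1 <- cp[, 2]
    S <- SumR[, c1 + 1, drop = FALSE] - SumR[, c0, drop = FALSE]
    K <- CntR[, c1 + 1, drop = FALSE] - CntR[, c0, drop = FALSE]
    kk <- matrix(r1 - r0 + 1, nrow = length(idx), ncol = nrow(cp))
    ll <- matrix(c1 - c0 + 1, nrow = length(idx), ncol = nrow(cp), byrow = TRUE)
    tau <- S / K
    sc <- las_score_value(tau, K, kk, ll, m, n, variant)
    sc[K == 0] <- -Inf
    w <- which.max(sc)
    if (length(w) && sc[w] > best$score) {
      wi <- ((w - 1) %% length(idx)) + 1
      wj <- ((w - 1) %/% length(idx)) + 1
      best <- list(score = sc[w], rows = rp[idx[wi], 1]:rp[idx[wi], 2],
                   cols = cp[wj, 1]:cp[wj, 2], tau = tau[w])
    }
  }
  best
}

# Given fixed columns, the best row interval (and vice versa by transpose).
best_interval_1d <- function(sums, cnts, fixed_len, m, n,
                             other_is_rows, variant, max_len = Inf) {
  L <- length(sums)
  ps <- c(0, cumsum(sums)); pc <- c(0, cumsum(cnts))
  pairs <- which(upper.tri(matrix(0, L, L), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] < max_len, , drop = FALSE]
  a <- pairs[, 1]; b <- pairs[, 2]
  S <- ps[b + 1] - ps[a]; K <- pc[b + 1] - pc[a]
  len <- b - a + 1
  tau <- S / K
  sc <- if (other_is_rows)
    las_score_value(tau, K, len, fixed_len, m, n, variant)
  else
    las_score_value(tau, K, fixed_len, len, m, n, variant)
  sc[K == 0] <- -Inf
  w <- which.max(sc)
  list(interval = a[w]:b[w], score = sc[w])
}

las_iterative_best <- function(M, n_restarts, variant, max_len = Inf,
                               max_sweeps = 30L) {
  m <- nrow(M); n <- ncol(M)
  finite_idx <- which(is.finite(M))
  if (!length(finite_idx)) return(list(score = -Inf))
  Z <- M; Z[!is.finite(Z)] <- 0
  Cn <- matrix(as.numeric(is.finite(M)), m, n)
  # starts: the top high-mean square windows at several scales (located via
  # prefix sums), the top single cells, and random cells
  P <- matrix(0, m + 1, n + 1)
  P[-1, -1] <- t(apply(apply(Z, 2, cumsum), 1, cumsum))
  starts <- list()
  for (w in c(4L, 8L, 16L)) {
    if (w > min(m, n) || w > max_len) next
    wm <- P[(w + 1):(m + 1), (w + 1):(n + 1)] - P[1:(m - w + 1), (w + 1):(n + 1)] -
      P[(w + 1):(m + 1), 1:(n - w + 1)] + P[1:(m - w + 1), 1:(n - w + 1)]
    top_w <- arrayInd(order(wm, decreasing = TRUE)[1:2], dim(wm))
    for (i in 1:nrow(top_w))
      starts[[length(starts) + 1]] <- list(rows = top_w[i, 1]:(top_w[i, 1] + w - 1),
                                           cols = top_w[i, 2]:(top_w[i, 2] + w - 1))
  }
  n_top <- ceiling(n_restarts / 2)
  top <- finite_idx[order(M[finite_idx], decreasing = TRUE)[seq_len(min(n_top, length(finite_idx)))]]
  rnd <- sample(finite_idx, min(n_restarts, length(finite_idx)))
  cells <- arrayInd(unique(c(top, rnd)), dim(M))
  for (i in seq_len(nrow(cells)))
    starts[[length(starts) + 1]] <- list(rows = cells[i, 1], cols = cells[i, 2])
  best <- list(score = -Inf)
  for (s in seq_along(starts)) {
    rows <- starts[[s]]$rows; cols <- starts[[s]]$cols
    prev <- -Inf
    for (sweep in seq_len(max_sweeps)) {
      rs <- rowSums(Z[, cols, drop = FALSE]); rc <- rowSums(Cn[, cols, drop = FALSE])
      br <- best_interval_1d(rs, rc, length(cols), m, n, TRUE, variant, max_len)
      rows <- br$interval
      cs <- colSums(Z[rows, , drop = FALSE]); cc <- colSums(Cn[rows, , drop = FALSE])
      bc <- best_interval_1d(cs, cc, length(rows), m, n, FALSE, variant, max_len)
      cols <- bc$interval
      if (bc$score <= prev + 1e-12) break
      prev <- bc$score
    }
    sc <- score_submatrix(M, rows, cols, variant)
    if (sc$score > best$score)
      best <- list(score = sc$score, rows = rows, cols = cols, tau = sc$tau)
  }
  best
}

#' LAS decomposition of one z-scored map
#'
#' Repeatedly finds the highest-scoring contiguous submatrix, accepts it when
#' its score reaches `score_threshold`, subtracts its mean from its entries
#' (residualization), and continues until the best score drops below the
#' threshold or `max_submatrices` are found. Matrices with at most 2048
#' cells are searched exhaustively over all contiguous interval pairs;
#' larger ones use alternating row/column interval sweeps from seeded starts
#' (the top cells plus random cells).
#'
#' @param map A z-scored `contact_map` (or plain matrix).
#' @param score_threshold Acceptance threshold (default 0).
#' @param max_submatrices Cap on accepted submatrices (default 50).
#' @param n_restarts Seeded starts per round for the iterative search.
#' @param seed Integer seed for the random starts.
#' @param variant "contiguous" or "subset" scoring.
#' @param max_len Optional cap on the row/column interval length in bins
#'   (default unlimited); caps the search space on large chromosomes.
#' @return Data frame `r0, r1, c0, c1` (0-based half-open bin intervals in
#'   original coordinates), `tau, score`, sorted by descending score.
#' @export
las_decompose <- function(map, score_threshold = 0, max_submatrices = 50L,
                          n_restarts = 8L, seed = 1L, variant = "contiguous",
                          max_len = Inf) {
  M <- if (inherits(map, "contact_map")) map$mat else as.matrix(map)
  set.seed(seed)
  out <- NULL
  for (iter in seq_len(max_submatrices)) {
    best <- if (length(M) <= 2048) las_exhaustive_best(M, variant, max_len)
            else las_iterative_best(M, n_restarts, variant, max_len)
    if (!is.finite(best$score) || best$score < score_threshold) break
    out <- rbind(out, data.frame(r0 = min(best$rows) - 1L, r1 = max(best$rows),
                                 c0 = min(best$cols) - 1L, c1 = max(best$cols),
                                 tau = best$tau, score = best$score))
    blk <- M[best$rows, best$cols, drop = FALSE]
    blk[is.finite(blk)] <- blk[is.finite(blk)] - best$tau
    M[best$rows, best$cols] <- blk
  }
  if (is.null(out))
    out <- data.frame(r0 = integer(), r1 = integer(), c0 = integer(),
                      c1 = integer(), tau = numeric(), score = numeric())
  out[order(-out$score), , drop = FALSE]
}

submatrix_pixels <- function(subs, chrom_a, chrom_b) {
  if (!nrow(subs)) return(character(0))
  unlist(lapply(seq_len(nrow(subs)), function(r) {
    gi <- (subs$r0[r] + 1):subs$r1[r]
    gj <- (subs$c0[r] + 1):subs$c1[r]
    px <- expand.grid(i = gi - 1L, j = gj - 1L)
    if (chrom_a == chrom_b) {
      ii <- pmin(px$i, px$j); jj <- pmax(px$i, px$j)
      unique(paste(chrom_a, ii, chrom_b, jj, sep = ":"))
    } else paste(chrom_a, px$i, chrom_b, px$j, sep = ":")
  }))
}

#' Reconcile LAS submatrices across replicates
#'
#' Each submatrix detected in either replicate is rescored in the other
#' replicate's z-scored map; submatrices at or above the threshold in both
#' are kept. Also returns the Pearson correlation (with the non-correlation
#' test p) between the paired scores over the union of detected submatrices.
#'
#' @param las1,las2 Decompositions from [las_decompose()] for the two
#'   replicates of one map.
#' @param map1,map2 The corresponding z-scored `contact_map`s (same shape).
#' @param score_threshold Threshold applied in both replicates.
#' @return List: `kept` (submatrix table with scores in both replicates),
#'   `pixels` (character pixel keys of the union of kept submatrices),
#'   `correlation`, `cor_p`.
#' @export
reconcile_replicates <- function(las1, las2, map1, map2, score_threshold = 0) {
  if (!all(dim(map1$mat) == dim(map2$mat)))
    stop("replicate maps have different shapes")
  rescore <- function(subs, mat) {
    if (!nrow(subs)) return(numeric(0))
    vapply(seq_len(nrow(subs)), function(r)
      score_submatrix(mat, (subs$r0[r] + 1):subs$r1[r],
                      (subs$c0[r] + 1):subs$c1[r])$score, numeric(1))
  }
  las1$origin <- rep(1L, nrow(las1)); las2$origin <- rep(2L, nrow(las2))
  all_subs <- rbind(las1, las2)
  if (!nrow(all_subs))
    return(list(kept = all_subs, pixels = character(0),
                correlation = NA_real_, cor_p = NA_real_))
  s1 <- rescore(all_subs, map1$mat)
  s2 <- rescore(all_subs, map2$mat)
  all_subs$score_rep1 <- s1; all_subs$score_rep2 <- s2
  keep <- s1 >= score_threshold & s2 >= score_threshold
  kept <- all_subs[keep, , drop = FALSE]
  ct <- if (nrow(all_subs) >= 3 && sd(s1) > 0 && sd(s2) > 0)
    cor.test(s1, s2) else NULL
  list(kept = kept,
       pixels = unique(submatrix_pixels(kept, map1$chrom_a, map1$chrom_b)),
       correlation = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       cor_p = if (is.null(ct)) NA_real_ else ct$p.value)
}

#' Difference map between two conditions' intermingling pixels
#'
#' Labels every pixel in the union of the two binarized maps as young_only,
#' old_only or shared, and summarizes counts, fractions and specificity
#' ((young_only + old_only) / total) separately for intra- and
#' interchromosomal pixels.
#'
#' @param young_pixels,old_pixels Character pixel keys
#'   ("chromA:i:chromB:j") from [reconcile_replicates()].
#' @return List: `labels` (named character vector pixel -> label),
#'   `summary` (per intra/inter class: counts and specificity).
#' @export
build_difference_map <- function(young_pixels, old_pixels) {
  young_pixels <- unique(young_pixels); old_pixels <- unique(old_pixels)
  all_px <- union(young_pixels, old_pixels)
  labels <- setNames(rep("shared", length(all_px)), all_px)
  labels[setdiff(young_pixels, old_pixels)] <- "young_only"
  labels[setdiff(old_pixels, young_pixels)] <- "old_only"
  parts <- strsplit(all_px, ":", fixed = TRUE)
  intra <- vapply(parts, function(p) p[1] == p[3], logical(1))
  summarize <- function(lab) {
    tot <- length(lab)
    data.frame(total = tot,
               young_only = sum(lab == "young_only"),
               old_only = sum(lab == "old_only"),
               shared = sum(lab == "shared"),
               specificity = if (tot) sum(lab != "shared") / tot else NA_real_)
  }
  summary <- rbind(cbind(class = "intra", summarize(labels[intra])),
                   cbind(class = "inter", summarize(labels[!intra])),
                   cbind(class = "all", summarize(labels)))
  list(labels = labels, summary = summary)
}
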