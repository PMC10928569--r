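# Per-transition differential expression with subsampling robustness,
# state signatures, and the transcript-length imbalance test.

# Vectorized NB GLM Wald test across genes for a two-group design with
# size-factor offsets. Dispersion per gene by method of moments with a floor;
# coefficients by IRLS with closed-form 2x2 solves, all genes simultaneously.
nb_wald <- function(counts, group, size_factors,
                    dispersion_floor = 1e-4, max_iter = 25L) {
  y <- counts
  x <- as.numeric(group)              # 0/1 indicator
  s <- size_factors
  q <- sweep(y, 2, s, "/")            # normalized counts

  idxA <- which(x == 0); idxB <- which(x == 1)
  mA <- rowMeans(q[, idxA, drop = FALSE]); mB <- rowMeans(q[, idxB, drop = FALSE])
  vA <- apply(q[, idxA, drop = FALSE], 1, var)
  vB <- apply(q[, idxB, drop = FALSE], 1, var)
  invsA <- mean(1 / s[idxA]); invsB <- mean(1 / s[idxB])
  # Var(K/s) = mu/s + alpha mu^2  =>  moment estimate per group, pooled by df
  aA <- (vA - mA * invsA) / pmax(mA, 1e-12)^2
  aB <- (vB - mB * invsB) / pmax(mB, 1e-12)^2
  wA <- length(idxA) - 1; wB <- length(idxB) - 1
  alpha <- pmin(pmax((wA * aA + wB * aB) / (wA + wB), dispersion_floor), 50)

  tested <- rowSums(y) > 0
  eps <- 1e-8
  b0 <- log(pmax(mA, eps))
  b1 <- log(pmax(mB, eps)) - b0
  off <- matrix(log(s), nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  xm <- matrix(x, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xm
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta + off)
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    wz <- w * z
    Sw <- rowSums(w); Swx <- rowSums(w * xm)
    Swz <- rowSums(wz); Swxz <- rowSums(wz * xm)
    det <- Sw * Swx - Swx^2
    det[det < 1e-12] <- NA
    nb1 <- (Sw * Swxz - Swx * Swz) / det
    nb0 <- (Swx * Swz - Swx * Swxz) / det
    ok <- is.finite(nb0) & is.finite(nb1)
    delta <- max(abs(nb0[ok] - b0[ok]), abs(nb1[ok] - b1[ok]), 0)
    b0[ok] <- nb0[ok]; b1[ok] <- nb1[ok]
    b0 <- pmin(pmax(b0, -30), 30); b1 <- pmin(pmax(b1, -60), 60)
    if (delta < 1e-8) break
  }
  eta <- pmin(pmax(b0 + b1 * xm, -30), 30)
  mu <- exp(eta + off)
  w <- mu / (1 + alpha * mu)
  Sw <- rowSums(w); Swx <- rowSums(w * xm)
  det <- Sw * Swx - Swx^2
  se <- sqrt(Sw / pmax(det, 1e-12))
  zstat <- b1 / se
  p <- 2 * pnorm(-abs(zstat))
  p[!tested] <- NA_real_
  data.frame(gene = rownames(y),
             log2fc = b1 / log(2),
             dispersion = alpha,
             stat = zstat,
             p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Negative-binomial Wald differential test between two sample groups
#'
#' Per gene: NB GLM with log link and size-factor offsets, per-gene moment
#' dispersion (floor 1e-4), Wald test on the group coefficient, BH adjustment
#' over tested genes. Genes with all-zero counts in both groups are excluded
#' (reported with NA p).
#'
#' @param cohort A `cohort_counts`.
#' @param samples_a,samples_b Sample ids of the two groups (>= 2 each).
#' @param size_factors Optional precomputed factors for the full cohort.
#' @return A `de_result` data frame: `gene, log2fc, p, padj, direction,
#'   tested`.
#' @export
differential_test <- function(cohort, samples_a, samples_b,
                              size_factors = NULL) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs >= 2 samples")
  sel <- c(samples_a, samples_b)
  counts <- cohort$counts[, sel, drop = FALSE]
  sf <- if (is.null(size_factors))
    compute_size_factors(cohort_counts(counts, cohort$ages[sel]))
  else size_factors[sel]
  group <- c(rep(0L, length(samples_a)), rep(1L, length(samples_b)))
  res <- nb_wald(counts, group, sf)
  res$padj <- NA_real_
  tested <- !is.na(res$p)
  res$padj[tested] <- p.adjust(res$p[tested], method = "BH")
  res$direction <- ifelse(res$log2fc >= 0, "up", "down")
  res$tested <- tested
  class(res) <- c("de_result", "data.frame")
  res
}

group_samples <- function(cohort, groups) {
  labels <- if (inherits(groups, "age_groups")) groups$labels else groups
  labels <- labels[colnames(cohort$counts)]
  split(names(labels), labels)
}

#' Robust per-transition differential-expression selection
#'
#' Three conjunctive filters reproduce the study's selection scheme:
#' (i) a transition-specific p-value threshold solved by quantile to keep
#' approximately `n_primary` genes with the smallest adjusted p on the full
#' data; (ii) a robustness frequency -- the fraction of `n_subsamples`
#' subsampling rounds (each drawing `ceiling(fraction * n)` samples per group
#' without replacement) in which the gene has adjusted p below
#' `subsample_fdr` -- at least `robustness_threshold`; (iii) an absolute
#' log2-fold-change threshold solved by quantile to keep approximately
#' `n_final` genes. The subsampling dampens the effect of outlier
#' individuals.
#'
#' @param cohort A `cohort_counts`.
#' @param groups An `age_groups` or named label vector.
#' @param transition Integer t: compares group t against group t + 1.
#' @param config A `pipeline_config` (its `de_config` is used).
#' @param seed Integer seed for the subsampling.
#' @return A `de_result` with extra columns `robustness`, `selected`.
#' @export
robust_de_selection <- function(cohort, groups, transition,
                                config = pipeline_config(), seed = 1L) {
  de_cfg <- config$de_config
  gs <- group_samples(cohort, groups)
  a <- gs[[as.character(transition)]]
  b <- gs[[as.character(transition + 1)]]
  if (is.null(a) || is.null(b))
    stop("transition must join two adjacent existing groups")
  n_sub_a <- ceiling(de_cfg$subsample_fraction * length(a))
  n_sub_b <- ceiling(de_cfg$subsample_fraction * length(b))
  if (n_sub_a < 2 || n_sub_b < 2)
    stop("subsample smaller than 2 samples per group")

  full <- differential_test(cohort, a, b)
  padj <- full$padj
  thr_p <- sort(padj)[min(de_cfg$n_primary, sum(!is.na(padj)))]
  pass_p <- !is.na(padj) & padj <= thr_p

  hits <- numeric(nrow(full))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (i in seq_len(de_cfg$n_subsamples)) {
    sa <- sample(a, n_sub_a); sb <- sample(b, n_sub_b)
    sub <- differential_test(cohort, sa, sb)
    hit <- !is.na(sub$padj) & sub$padj < de_cfg$subsample_fdr
    hits <- hits + hit
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  freq <- hits / de_cfg$n_subsamples
  pass_r <- freq >= de_cfg$robustness_threshold

  surv <- pass_p & pass_r
  alfc <- abs(full$log2fc)
  thr_lfc <- if (sum(surv) > de_cfg$n_final)
    sort(alfc[surv], decreasing = TRUE)[de_cfg$n_final] else 0
  pass_l <- alfc >= thr_lfc

  full$robustness <- freq
  full$selected <- surv & pass_l
  attr(full, "thresholds") <- list(p = thr_p, robustness = de_cfg$robustness_threshold,
                                   lfc = thr_lfc)
  full
}

#' State signature genes (one group versus all others)
#'
#' Tests the focal age group against all remaining samples and returns the
#' `n_genes` genes with the smallest adjusted p, split by direction
#' (up-in-focal versus down-in-focal).
#'
#' @param cohort A `cohort_counts`.
#' @param groups An `age_groups` or named label vector.
#' @param focal_group Group label.
#' @param n_genes Signature size (default 170).
#' @return A `de_result` restricted to the signature, with `direction`
#'   relative to the focal group.
#' @export
state_signature_genes <- function(cohort, groups, focal_group, n_genes = 170L) {
  gs <- group_samples(cohort, groups)
  focal <- gs[[as.character(focal_group)]]
  if (is.null(focal) || !length(focal)) stop("focal group is empty")
  rest <- setdiff(colnames(cohort$counts), focal)
  res <- differential_test(cohort, rest, focal)   # positive lfc = up in focal
  res <- res[!is.na(res$padj), ]
  if (n_genes == 0) return(res[0, ])
  if (n_genes > nrow(res)) {
    warning("n_genes exceeds tested genes; capped at ", nrow(res))
    n_genes <- nrow(res)
  }
  res[order(res$padj, res$p)[seq_len(n_genes)], ]
}

#' Transcript-length imbalance of DE genes
#'
#' One-sided Welch t tests on log transcript length: (a) genes downregulated
#' with age have shorter transcripts than non-DE genes, (b) upregulated genes
#' have longer transcripts.
#'
#' @param de A `de_result` for the youngest-versus-oldest comparison with a
#'   `selected` (or significance) flag; direction is read from `log2fc`.
#' @param catalog A `gene_catalog` providing transcript lengths.
#' @param selected Optional logical vector overriding `de$selected`.
#' @return Data frame with one row per comparison: `comparison, t, df, p`.
#' @export
length_imbalance_test <- function(de, catalog, selected = NULL) {
  if (is.null(selected)) selected <- de$selected
  if (is.null(selected)) stop("no selection flag available")
  lens <- setNames(log(catalog$transcript_length), catalog$gene)
  ll <- lens[de$gene]
  down <- ll[selected & de$log2fc < 0]
  up <- ll[selected & de$log2fc > 0]
  nonde <- ll[!selected]
  if (length(down) < 2 || length(up) < 2 || length(nonde) < 2)
    stop("each compared gene set needs >= 2 genes")
  welch <- function(x, y, alternative) {
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
      return(data.frame(t = 0, df = NA_real_, p = 0.5))  # symmetric null
    ht <- t.test(x, y, alternative = alternative, var.equal = FALSE)
    data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value)
  }
  rbind(cbind(comparison = "down_shorter_than_nonDE", welch(down, nonde, "less")),
        cbind(comparison = "up_longer_than_nonDE", welch(up, nonde, "greater")))
}
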