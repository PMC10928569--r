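# Normalization, activity calling, age-gene selection and age-group
# definition for the transcriptomic arm.

#' Median-of-ratios size factors
#'
#' Library-size correction factors: the reference is the per-gene geometric
#' mean over samples (genes containing any zero are excluded from the
#' reference), and each sample's factor is the median over reference genes of
#' count / reference.
#'
#' @param cohort A `cohort_counts`.
#' @return Positive numeric vector, one factor per sample.
#' @export
compute_size_factors <- function(cohort) {
  counts <- cohort$counts
  ref_ok <- rowSums(counts == 0) == 0
  if (!any(ref_ok))
    stop("no gene has nonzero counts in all samples; supply a pseudo-reference")
  logc <- log(counts[ref_ok, , drop = FALSE])
  ref <- rowMeans(logc)                      # log geometric mean
  factors <- apply(logc, 2, function(col) exp(median(col - ref)))
  if (any(!is.finite(factors) | factors <= 0)) stop("non-positive size factor")
  setNames(factors, colnames(counts))
}

#' FPKM normalization
#'
#' fpkm = count / (transcript_length/1e3) / (library_size/1e6), with library
#' size the raw column sum.
#'
#' @param cohort A `cohort_counts`.
#' @param catalog A `gene_catalog` covering all counted genes.
#' @return List with `mat` (gene x sample FPKM), `transform = "fpkm"`.
#' @export
compute_fpkm <- function(cohort, catalog) {
  counts <- cohort$counts
  lens <- setNames(catalog$transcript_length, catalog$gene)[rownames(counts)]
  if (anyNA(lens)) stop("catalog missing transcript length for some counted genes")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size")
  mat <- counts / (lens / 1e3)
  mat <- sweep(mat, 2, libsize / 1e6, "/")
  list(mat = mat, transform = "fpkm", size_factors = NULL)
}

#' Variance-stabilizing transform (shifted log)
#'
#' vst = log2(count / size_factor + 1). Monotone in counts per cell; on
#' negative-binomial data the across-sample sd of the transformed values
#' varies far less with the mean than the raw-count sd does.
#'
#' @param cohort A `cohort_counts`.
#' @param factors Size factors from [compute_size_factors()].
#' @return List with `mat`, `transform = "vst"`, `size_factors`.
#' @export
vst_transform <- function(cohort, factors = compute_size_factors(cohort)) {
  norm <- sweep(cohort$counts, 2, factors, "/")
  list(mat = log2(norm + 1), transform = "vst", size_factors = factors)
}

#' Call genes active per age group
#'
#' A gene is active in a group when its mean FPKM over the group's samples is
#' at or above the threshold; genes with a mean below the threshold are
#' inactive there.
#'
#' @param fpkm Output of [compute_fpkm()].
#' @param groups An `age_groups` object (see [define_age_groups()]) or a
#'   named group label vector.
#' @param threshold Activity cutoff on the FPKM scale (default 0.8).
#' @return Logical gene x group matrix.
#' @export
call_active_genes <- function(fpkm, groups, threshold = 0.8) {
  if (threshold <= 0) stop("threshold must be strictly positive")
  labels <- if (inherits(groups, "age_groups")) groups$labels else groups
  labels <- labels[colnames(fpkm$mat)]
  if (anyNA(labels)) stop("group labels must cover every sample")
  lv <- sort(unique(labels))
  act <- sapply(lv, function(g) {
    idx <- which(labels == g)
    if (!length(idx)) stop("empty age group: ", g)
    rowMeans(fpkm$mat[, idx, drop = FALSE]) >= threshold
  })
  colnames(act) <- paste0("group", lv)
  act
}

#' LASSO selection of age-associated genes
#'
#' L1-penalized least squares of age on standardized expression, evaluated
#' over a penalty grid. The grid values are relative: they are mapped onto
#' the data-driven glmnet path as fractions of lambda_max (the smallest
#' penalty shrinking every coefficient to zero), with the largest grid value
#' anchored at lambda_max, so any grid spans "select almost all" to "select
#' none" regardless of units.
#'
#' @param vst Output of [vst_transform()].
#' @param ages Numeric ages per sample (column order of `vst$mat`).
#' @param penalties Relative penalty grid (default `c(0.25, 0.5, 1, 2, 4)`).
#' @return List with `selected` (list of gene id vectors per penalty),
#'   `coefficients` (long data frame), `lambda_used`.
#' @export
select_age_genes_lasso <- function(vst, ages,
                                   penalties = c(0.25, 0.5, 1, 2, 4)) {
  if (length(unique(ages)) < 2) stop("need >= 2 distinct ages")
  x <- t(vst$mat)
  keep <- apply(x, 2, sd) > 0
  x <- x[, keep, drop = FALSE]
  fit <- glmnet::glmnet(x, ages, alpha = 1, standardize = TRUE)
  lambda_max <- max(fit$lambda)
  # geometric mapping of the relative grid onto the glmnet path: the largest
  # grid value lands on lambda_max (empty selection) and each halving of the
  # grid value divides the effective penalty by 8, so a 16-fold grid spans
  # "select almost all" to "select none"
  lambda_used <- lambda_max * (penalties / max(penalties))^3
  sel <- list()
  coefs <- NULL
  for (i in seq_along(penalties)) {
    cf <- as.matrix(coef(fit, s = lambda_used[i], exact = TRUE, x = x, y = ages))
    nz <- rownames(cf)[cf[, 1] != 0]
    nz <- setdiff(nz, "(Intercept)")
    sel[[as.character(penalties[i])]] <- nz
    if (length(nz))
      coefs <- rbind(coefs, data.frame(penalty = penalties[i], gene = nz,
                                       coefficient = cf[nz, 1]))
  }
  list(selected = sel, coefficients = coefs,
       lambda_used = setNames(lambda_used, penalties))
}

#' Define age groups by clustering on age-associated genes
#'
#' Hierarchical clustering (Euclidean distance, ward.D2 agglomeration) of
#' samples on the variance-stabilized profiles of the selected genes, cut to
#' `n_clusters`; clusters whose age min-max ranges overlap are merged (ties
#' broken by merging the pair with the smallest combined range first), and
#' the resulting groups are relabeled 1..K by ascending age midpoint.
#'
#' @param vst Output of [vst_transform()] restricted or not; only
#'   `selected_genes` rows are used.
#' @param ages Numeric ages per sample.
#' @param selected_genes Gene ids from the LASSO stage.
#' @param n_clusters Number of dendrogram clusters before merging (default 6).
#' @return An `age_groups` object: `labels` (named integer vector),
#'   `ranges` (per-group age range), `linkage` (the hclust object),
#'   `cut_height` (phenetic height equivalent to the cut).
#' @export
define_age_groups <- function(vst, ages, selected_genes, n_clusters = 6) {
  m <- vst$mat[intersect(selected_genes, rownames(vst$mat)), , drop = FALSE]
  if (nrow(m) == 0) stop("no selected genes present in the expression matrix")
  prof <- t(m)
  if (nrow(unique(prof)) < n_clusters)
    stop("n_clusters exceeds the number of distinct sample profiles")
  d <- dist(prof)
  hc <- hclust(d, method = "ward.D2")
  cl <- cutree(hc, k = n_clusters)
  heights <- sort(hc$height, decreasing = TRUE)
  cut_height <- if (n_clusters > 1) mean(heights[c(n_clusters - 1, n_clusters)]) else Inf

  ages <- ages[colnames(m)]
  ranges <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    a <- ages[cl == k]
    data.frame(cluster = k, min = min(a), max = max(a))
  }))
  # merge clusters with overlapping age ranges, smallest combined range first
  repeat {
    ov <- NULL
    for (i in seq_len(nrow(ranges) - 1)) for (j in (i + 1):nrow(ranges)) {
      if (ranges$min[i] <= ranges$max[j] && ranges$min[j] <= ranges$max[i]) {
        comb <- max(ranges$max[i], ranges$max[j]) - min(ranges$min[i], ranges$min[j])
        ov <- rbind(ov, data.frame(i = i, j = j, span = comb))
      }
    }
    if (is.null(ov)) break
    pick <- ov[which.min(ov$span), ]
    ki <- ranges$cluster[pick$i]; kj <- ranges$cluster[pick$j]
    cl[cl == kj] <- ki
    ranges <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
      a <- ages[cl == k]
      data.frame(cluster = k, min = min(a), max = max(a))
    }))
  }
  mid <- (ranges$min + ranges$max) / 2
  relabel <- setNames(rank(mid, ties.method = "first"), ranges$cluster)
  labels <- setNames(as.integer(relabel[as.character(cl)]), names(cl))
  ranges <- data.frame(group = as.integer(relabel[as.character(ranges$cluster)]),
                       min = ranges$min, max = ranges$max)
  ranges <- ranges[order(ranges$group), ]
  structure(list(labels = labels, ranges = ranges, linkage = hc,
                 cut_height = cut_height),
            class = "age_groups")
}

#' @export
print.age_groups <- function(x, ...) {
  cat(sprintf("age_groups: %d groups over %d samples\n",
              nrow(x$ranges), length(x$labels)))
  for (i in seq_len(nrow(x$ranges)))
    cat(sprintf("  group %d: %g-%g years (%d samples)\n", x$ranges$group[i],
                x$ranges$min[i], x$ranges$max[i],
                sum(x$labels == x$ranges$group[i])))
  invisible(x)
}
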