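# Coupling of DE genes and bridge TFs to intermingling changes.

#' Map genes to Hi-C loci
#'
#' bin = floor(gene start / resolution); a gene spanning several bins is
#' mapped to the first bin in genomic order. Genes on masked bins or
#' undeclared chromosomes are flagged unmapped with a warning.
#'
#' @param catalog A `gene_catalog`.
#' @param resolution Bin width in bp.
#' @param bins Data frame `chrom, n_bins` of declared chromosomes.
#' @param bin_mask Optional named list of per-chromosome logical masks.
#' @return List: `map` (data frame `gene, chrom, bin`), `unmapped` (gene ids
#'   with reason).
#' @export
map_genes_to_loci <- function(catalog, resolution, bins, bin_mask = NULL) {
  bin <- floor(catalog$start / resolution)
  known <- catalog$chrom %in% bins$chrom
  nb <- setNames(bins$n_bins, bins$chrom)
  in_range <- known & bin < nb[catalog$chrom]
  masked <- rep(FALSE, nrow(catalog))
  if (!is.null(bin_mask)) {
    for (i in which(in_range)) {
      m <- bin_mask[[catalog$chrom[i]]]
      if (!is.null(m) && m[bin[i] + 1]) masked[i] <- TRUE
    }
  }
  ok <- in_range & !masked
  unmapped <- data.frame(
    gene = catalog$gene[!ok],
    reason = ifelse(!known[!ok], "undeclared_chromosome",
                    ifelse(!in_range[!ok], "out_of_range", "masked_bin")))
  if (nrow(unmapped))
    warning(sprintf("%d gene(s) unmapped (undeclared chromosome or masked bin)",
                    nrow(unmapped)))
  list(map = data.frame(gene = catalog$gene[ok], chrom = catalog$chrom[ok],
                        bin = bin[ok], stringsAsFactors = FALSE),
       unmapped = unmapped)
}

pixel_key_for <- function(chrom1, bin1, chrom2, bin2) {
  flip <- chrom1 > chrom2 | (chrom1 == chrom2 & bin1 > bin2)
  key <- character(length(chrom1))
  key[!flip] <- paste(chrom1[!flip], bin1[!flip], chrom2[!flip], bin2[!flip], sep = ":")
  key[flip] <- paste(chrom2[flip], bin2[flip], chrom1[flip], bin1[flip], sep = ":")
  key
}

#' Intermingling difference labels for a gene set
#'
#' For every unordered pair of mapped genes, looks up the label of the pixel
#' at their loci in the condition difference map (young_only / old_only /
#' shared, or none when the pixel is in no accepted submatrix). Pairs mapping
#' to the same bin are excluded. Percentages are over labeled (non-none)
#' pairs; a gene is "specific" when it has at least one young_only or
#' old_only pair.
#'
#' @param genes Character gene ids.
#' @param locus_map Output of [map_genes_to_loci()].
#' @param diff Output of [build_difference_map()].
#' @return A `geneset_intermingling` list: `pairs` (long data frame),
#'   `percent` (named young_only/old_only/shared percentages),
#'   `gene_groups` (named vector gene -> "specific"/"nonspecific"),
#'   `n_labeled`.
#' @export
geneset_difference_map <- function(genes, locus_map, diff) {
  lm <- locus_map$map[locus_map$map$gene %in% genes, , drop = FALSE]
  if (nrow(lm) < 2) stop("need >= 2 mapped genes")
  pr <- combn(nrow(lm), 2)
  g1 <- pr[1, ]; g2 <- pr[2, ]
  same_bin <- lm$chrom[g1] == lm$chrom[g2] & lm$bin[g1] == lm$bin[g2]
  g1 <- g1[!same_bin]; g2 <- g2[!same_bin]
  key <- pixel_key_for(lm$chrom[g1], lm$bin[g1], lm$chrom[g2], lm$bin[g2])
  lab <- unname(diff$labels[key])
  lab[is.na(lab)] <- "none"
  pairs <- data.frame(gene1 = lm$gene[g1], gene2 = lm$gene[g2],
                      label = lab, stringsAsFactors = FALSE)
  labeled <- pairs$label != "none"
  pct <- c(young_only = 0, old_only = 0, shared = 0)
  if (any(labeled)) {
    tab <- table(factor(pairs$label[labeled],
                        levels = c("young_only", "old_only", "shared")))
    pct <- 100 * as.numeric(tab) / sum(tab)
    names(pct) <- c("young_only", "old_only", "shared")
  }
  spec_genes <- unique(c(pairs$gene1[pairs$label %in% c("young_only", "old_only")],
                         pairs$gene2[pairs$label %in% c("young_only", "old_only")]))
  groups <- setNames(ifelse(lm$gene %in% spec_genes, "specific", "nonspecific"),
                     lm$gene)
  structure(list(pairs = pairs, percent = pct, gene_groups = groups,
                 n_labeled = sum(labeled)),
            class = "geneset_intermingling")
}

#' Random-gene-set null for intermingling percentages
#'
#' Draws `n_draws` gene sets of the observed size from the universe and
#' reports, per class, the fraction of draws whose class percentage is at
#' least the observed one.
#'
#' @param observed A `geneset_intermingling`.
#' @param universe Character gene pool (must exceed the gene-set size).
#' @param locus_map Output of [map_genes_to_loci()].
#' @param diff Output of [build_difference_map()].
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed.
#' @return Data frame `class, observed, p, p_label`.
#' @export
random_geneset_null <- function(observed, universe, locus_map, diff,
                                n_draws = 1000L, seed = 1L) {
  size <- length(observed$gene_groups)
  universe <- unique(universe)
  if (length(universe) <= size) stop("universe too small for the gene-set size")
  set.seed(seed)
  classes <- c("young_only", "old_only", "shared")
  draws <- matrix(NA_real_, n_draws, length(classes),
                  dimnames = list(NULL, classes))
  for (i in seq_len(n_draws)) {
    g <- sample(universe, size)
    gi <- tryCatch(geneset_difference_map(g, locus_map, diff),
                   error = function(e) NULL)
    if (!is.null(gi)) draws[i, ] <- gi$percent[classes]
  }
  out <- do.call(rbind, lapply(classes, function(cl) {
    ok <- !is.na(draws[, cl])
    p <- sum(draws[ok, cl] >= observed$percent[cl]) / sum(ok)
    data.frame(class = cl, observed = unname(observed$percent[cl]), p = p,
               p_label = if (p == 0) sprintf("< %g", 1 / sum(ok)) else format(p))
  }))
  attr(out, "null_draws") <- draws
  out
}

# Direction-matched target-DE genes of a solved network: the network's
# majority direction unless overridden.
target_de_direction <- function(sol, target_de) {
  r <- attr(sol, "roles")
  tg <- unique(r$gene[r$role == "target_de"])
  dirs <- target_de$direction[match(tg, target_de$gene)]
  if (!length(dirs) || all(is.na(dirs))) return("up")
  names(which.max(table(dirs)))
}

#' Bridge-TF targeting versus intermingling change of target DE genes
#'
#' Per direction-matched target-DE gene, counts the distinct bridge TFs
#' targeting it through selected regulatory edges of the Steiner network,
#' then compares the counts of genes with specific intermingling against
#' those without (one-sided Welch t, specific > nonspecific).
#'
#' @param sol Role-classified `steiner_network`.
#' @param net Its `transition_network`.
#' @param gsi `geneset_intermingling` of the direction-matched target genes.
#' @return List: `counts` (per-gene TF counts with group), `t`, `df`, `p`.
#' @export
tf_targeting_vs_intermingling <- function(sol, net, gsi) {
  reg <- sol$edges[sol$edges$kind == "regulatory", , drop = FALSE]
  btf <- bridge_tfs(sol)
  reg <- reg[reg$a %in% btf, , drop = FALSE]
  genes <- names(gsi$gene_groups)
  cnt <- vapply(genes, function(g)
    length(unique(reg$a[reg$b == target_id(g)])), integer(1))
  grp <- gsi$gene_groups[genes]
  if (sum(grp == "specific") < 2 || sum(grp == "nonspecific") < 2)
    stop("each intermingling group needs >= 2 genes")
  ht <- t.test(cnt[grp == "specific"], cnt[grp == "nonspecific"],
               alternative = "greater", var.equal = FALSE)
  list(counts = data.frame(gene = genes, n_bridge_tfs = cnt, group = unname(grp)),
       t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Intermingling change percentage for one bridge TF
#'
#' Builds the pair-label multiset among the TF's direction-matched target-DE
#' genes and returns the percentage of labeled pairs that are condition
#' specific ((young_only + old_only) / labeled); NA when no labeled pairs
#' (or fewer than two mapped targets).
#'
#' @param tf TF id.
#' @param targets Its direction-matched target-DE genes.
#' @param locus_map Output of [map_genes_to_loci()].
#' @param diff Output of [build_difference_map()].
#' @return Numeric percentage or NA.
#' @export
per_tf_intermingling_change <- function(tf, targets, locus_map, diff) {
  gsi <- tryCatch(geneset_difference_map(targets, locus_map, diff),
                  error = function(e) NULL)
  if (is.null(gsi) || gsi$n_labeled == 0) return(NA_real_)
  unname(gsi$percent["young_only"] + gsi$percent["old_only"])
}

#' Per-TF feature table (z-scored, clipped)
#'
#' Assembles per bridge TF the enrichment p, the intermingling-change
#' percentage, the DE-target count and the selected-PPI-edge count;
#' z-scores each feature over non-missing TFs, clips to [-2, 2] (constant
#' features get z = 0 with a warning), and exports a hierarchical-clustering
#' row order (Euclidean, complete linkage) over TFs without missing values.
#'
#' @param features Data frame with `tf` plus numeric feature columns.
#' @return List: `raw`, `z` (clipped), `row_order`.
#' @export
tf_feature_table <- function(features) {
  num_cols <- setdiff(names(features), "tf")
  z <- features
  for (cl in num_cols) {
    v <- features[[cl]]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("constant feature '", cl, "': z set to 0")
      z[[cl]] <- ifelse(is.na(v), NA_real_, 0)
    } else {
      z[[cl]] <- pmin(pmax((v - mean(v, na.rm = TRUE)) / s, -2), 2)
    }
  }
  zm <- as.matrix(z[, num_cols, drop = FALSE])
  rownames(zm) <- z$tf
  comp <- complete.cases(zm)
  ord <- z$tf
  if (sum(comp) >= 2 && length(num_cols) >= 1) {
    hc <- hclust(dist(zm[comp, , drop = FALSE]), method = "complete")
    ord <- c(rownames(zm)[comp][hc$order], rownames(zm)[!comp])
  }
  list(raw = features, z = z, row_order = ord)
}

#' Export the intermingling network of one TF and its targets
#'
#' Nodes are the TF and its direction-matched DE targets (with chromosome
#' attribute, TF flagged); edges are the labeled gene pairs among them;
#' targets without any labeled pair remain as isolated nodes.
#'
#' @param tf TF id.
#' @param targets Its direction-matched target-DE genes.
#' @param locus_map Output of [map_genes_to_loci()].
#' @param diff Output of [build_difference_map()].
#' @return List: `nodes` (gene, chrom, is_tf), `edges` (gene1, gene2, label),
#'   `summary` (counts per label).
#' @export
export_tf_intermingling_network <- function(tf, targets, locus_map, diff) {
  members <- unique(c(tf, targets))
  lm <- locus_map$map[locus_map$map$gene %in% members, , drop = FALSE]
  if (!tf %in% lm$gene) stop("TF is not mapped to a locus")
  edges <- data.frame(gene1 = character(), gene2 = character(),
                      label = character())
  if (nrow(lm) >= 2) {
    gsi <- geneset_difference_map(lm$gene, locus_map, diff)
    edges <- gsi$pairs[gsi$pairs$label != "none", , drop = FALSE]
  }
  nodes <- data.frame(gene = lm$gene, chrom = lm$chrom,
                      is_tf = lm$gene == tf)
  tab <- table(factor(edges$label, levels = c("young_only", "old_only", "shared")))
  list(nodes = nodes, edges = edges,
       summary = data.frame(label = names(tab), n = as.integer(tab)))
}
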