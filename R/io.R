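#' @importFrom stats median sd var quantile rnorm runif rbinom rpois rnbinom
#'   setNames complete.cases pnorm p.adjust t.test hclust cutree dist cor
#'   cor.test ks.test coef predict
#' @importFrom utils read.delim write.table modifyList combn head
NULL

# ---- domain containers ------------------------------------------------------

#' Cohort counts container
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param ages Numeric vector of ages (years), one per sample, named or in
#'   column order.
#' @return A `cohort_counts` object.
#' @export
cohort_counts <- function(counts, ages) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene id in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample id in counts")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  if (!is.null(names(ages))) ages <- ages[colnames(counts)]
  if (length(ages) != ncol(counts) || anyNA(ages))
    stop("ages must cover every sample")
  if (any(ages < 0)) stop("ages must be non-negative")
  structure(list(counts = counts, ages = setNames(as.numeric(ages), colnames(counts))),
            class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(sprintf("cohort_counts: %d genes x %d samples, ages %g-%g years\n",
              nrow(x$counts), ncol(x$counts), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Gene catalog constructor
#'
#' Coordinates are 0-based half-open (BED convention) internally.
#'
#' @param df Data frame with columns `gene, chrom, start, end, strand,
#'   transcript_length`.
#' @param one_based Set TRUE for GFF-like 1-based closed inputs; converted at
#'   this boundary.
#' @return Validated `gene_catalog` data frame.
#' @export
gene_catalog <- function(df, one_based = FALSE) {
  need <- c("gene", "chrom", "start", "end", "strand", "transcript_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene catalog missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (one_based) df$start <- df$start - 1L
  if (anyDuplicated(df$gene)) stop("duplicate gene id in catalog")
  if (any(df$end <= df$start)) stop("gene catalog intervals must satisfy start < end")
  if (any(df$transcript_length <= 0)) stop("transcript lengths must be positive")
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# ---- tabular readers --------------------------------------------------------

read_tsv_file <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("file '%s' missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  df
}

#' Read a counts table and sample metadata
#'
#' @param counts_path TSV with a `gene` column followed by one column per
#'   sample.
#' @param samples_path TSV with columns `sample_id, age`.
#' @return A `cohort_counts`.
#' @export
read_counts <- function(counts_path, samples_path) {
  ct <- read_tsv_file(counts_path, required = "gene")
  meta <- read_tsv_file(samples_path, required = c("sample_id", "age"))
  m <- as.matrix(ct[, setdiff(names(ct), "gene"), drop = FALSE])
  rownames(m) <- ct$gene
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count in '%s' at row %d (gene '%s')",
                 counts_path, neg[1, 1], rownames(m)[neg[1, 1]]))
  cohort_counts(m, setNames(meta$age, meta$sample_id))
}

#' Read the gene catalog
#' @param path TSV with `gene, chrom, start, end, strand, transcript_length`
#'   (BED-style 0-based half-open coordinates).
#' @param one_based Convert from 1-based closed coordinates on read.
#' @export
read_gene_catalog <- function(path, one_based = FALSE) {
  gene_catalog(read_tsv_file(path,
    required = c("gene", "chrom", "start", "end", "strand", "transcript_length")),
    one_based = one_based)
}

#' Read a PPI edge list
#' @param path TSV with `protein_a, protein_b, score`.
#' @export
read_ppi <- function(path) {
  df <- read_tsv_file(path, required = c("protein_a", "protein_b", "score"))
  if (!is.numeric(df$score)) stop("PPI scores must be numeric in ", path)
  df
}

#' Read TF -> target regulatory links
#' @param path TSV with `tf, target`.
#' @export
read_regulons <- function(path) {
  df <- read_tsv_file(path, required = c("tf", "target"))
  unique(df[, c("tf", "target")])
}

#' Read a BED-format exclusion list
#' @param path BED3 file (0-based half-open), no header.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED file: ", path))
  if (ncol(df) < 3) stop("malformed BED file (need >= 3 columns): ", path)
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  if (!is.numeric(df$start) || !is.numeric(df$end) || any(df$end < df$start))
    stop("malformed BED intervals in ", path)
  df
}

#' Write a BED-convention table
#' @param df Data frame with `chrom, start, end` leading columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Hi-C containers --------------------------------------------------------

#' Contact map constructor
#'
#' A per-chromosome-pair binned contact matrix with masking and normalization
#' state. Cis maps (`chrom_a == chrom_b`) must be symmetric.
#'
#' @param chrom_a,chrom_b Chromosome names (a <= b lexical order by
#'   convention of the map set).
#' @param mat Numeric matrix (bins_a x bins_b), non-negative where finite.
#' @param resolution Bin width in bp.
#' @param condition,replicate Sample labels.
#' @param state Normalization state.
#' @return A `contact_map`.
#' @export
contact_map <- function(chrom_a, chrom_b, mat, resolution,
                        condition = NA_character_, replicate = NA_integer_,
                        state = "raw") {
  mat <- as.matrix(mat)
  if (any(mat[is.finite(mat)] < 0)) stop("contact values must be non-negative")
  if (chrom_a == chrom_b && !isTRUE(all.equal(mat, t(mat), tolerance = 1e-8)))
    stop("cis contact map must be symmetric")
  structure(list(chrom_a = chrom_a, chrom_b = chrom_b, mat = mat,
                 resolution = as.integer(resolution),
                 condition = condition, replicate = replicate,
                 state = state,
                 mask_row = rep(FALSE, nrow(mat)),
                 mask_col = rep(FALSE, ncol(mat))),
            class = "contact_map")
}

is_cis <- function(map) map$chrom_a == map$chrom_b

pair_key <- function(a, b) paste(a, b, sep = "|")

#' One Hi-C sample: all chromosome-pair maps at one resolution
#'
#' @param maps Named list of `contact_map`s keyed "chromA|chromB".
#' @param bins Data frame `chrom, n_bins` (declared chromosome order).
#' @param resolution Bin width in bp.
#' @param condition,replicate Sample labels.
#' @export
hic_sample <- function(maps, bins, resolution, condition, replicate) {
  stopifnot(all(c("chrom", "n_bins") %in% names(bins)))
  structure(list(maps = maps, bins = bins, resolution = as.integer(resolution),
                 condition = condition, replicate = replicate),
            class = "hic_sample")
}

#' Read one Hi-C sample from sparse COO triplet files
#'
#' Each chromosome-pair file holds `bin_i, bin_j, value` triplets (0-based
#' bins, chrom_a rows / chrom_b columns). Unlisted entries are zero.
#'
#' @param paths Named character vector of file paths keyed "chromA|chromB".
#' @param chrom_sizes_path TSV with `chrom, size` (bp).
#' @param resolution Bin width in bp.
#' @param condition,replicate Sample labels.
#' @return A `hic_sample`.
#' @export
read_hic_sample <- function(paths, chrom_sizes_path, resolution,
                            condition = NA_character_, replicate = NA_integer_) {
  sizes <- read_tsv_file(chrom_sizes_path, required = c("chrom", "size"))
  bins <- data.frame(chrom = sizes$chrom,
                     n_bins = as.integer(ceiling(sizes$size / resolution)))
  maps <- list()
  for (key in names(paths)) {
    chr <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (!all(chr %in% bins$chrom))
      stop(sprintf("Hi-C triplets in '%s' reference undeclared chromosome '%s'",
                   paths[[key]], setdiff(chr, bins$chrom)[1]))
    trip <- read_tsv_file(paths[[key]], required = c("bin_i", "bin_j", "value"))
    na <- bins$n_bins[bins$chrom == chr[1]]
    nb <- bins$n_bins[bins$chrom == chr[2]]
    if (any(trip$bin_i < 0 | trip$bin_i >= na | trip$bin_j < 0 | trip$bin_j >= nb))
      stop(sprintf("bin index out of range in '%s'", paths[[key]]))
    m <- matrix(0, na, nb)
    m[cbind(trip$bin_i + 1L, trip$bin_j + 1L)] <- trip$value
    if (chr[1] == chr[2]) m <- pmax(m, t(m))   # triplets store upper triangle
    maps[[key]] <- contact_map(chr[1], chr[2], m, resolution, condition, replicate)
  }
  hic_sample(maps, bins, resolution, condition, replicate)
}

#' Write one Hi-C sample as sparse COO triplets
#' @param sample A `hic_sample`.
#' @param dir Output directory.
#' @return Named vector of written triplet paths (plus `chrom_sizes.tsv`).
#' @export
write_hic_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- data.frame(chrom = sample$bins$chrom,
                      size = sample$bins$n_bins * sample$resolution)
  write.table(sizes, file.path(dir, "chrom_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- character(0)
  for (key in names(sample$maps)) {
    map <- sample$maps[[key]]
    m <- map$mat
    if (is_cis(map)) m[lower.tri(m)] <- 0
    idx <- which(m != 0 & is.finite(m), arr.ind = TRUE)
    trip <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                       value = m[idx])
    trip <- trip[order(trip$bin_i, trip$bin_j), ]
    fn <- file.path(dir, sprintf("hic_%s_%s_%s_rep%s.tsv", map$chrom_a,
                                 map$chrom_b, map$condition, map$replicate))
    write.table(trip, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    out[key] <- fn
  }
  invisible(out)
}

# ---- bundle reader ----------------------------------------------------------

#' Read and cross-validate all pipeline inputs
#'
#' Loads counts, catalog, PPI, regulons and Hi-C maps; genes referenced by a
#' regulon or PPI node but absent from the catalog are collected in a warning
#' list rather than dropped.
#'
#' @param handles Named list of paths: `counts`, `samples`, `catalog`, `ppi`,
#'   `regulons`, optional `hic` (named triplet paths), `chrom_sizes`,
#'   `blacklist`.
#' @param config A `pipeline_config`.
#' @return List of validated datasets plus `warnings` (unknown gene ids).
#' @export
read_inputs <- function(handles, config) {
  validate_config(config)
  out <- list()
  out$counts <- read_counts(handles$counts, handles$samples)
  out$catalog <- read_gene_catalog(handles$catalog)
  out$ppi <- read_ppi(handles$ppi)
  out$regulons <- read_regulons(handles$regulons)
  if (!is.null(handles$blacklist)) out$blacklist <- read_bed(handles$blacklist)
  if (!is.null(handles$hic)) {
    out$hic <- lapply(handles$hic, function(h)
      read_hic_sample(h$paths, handles$chrom_sizes, config$resolution,
                      condition = h$condition, replicate = h$replicate))
  }
  known <- out$catalog$gene
  referenced <- unique(c(out$ppi$protein_a, out$ppi$protein_b,
                         out$regulons$tf, out$regulons$target))
  out$warnings <- setdiff(referenced, known)
  out
}

#' Write a TSV with a provenance header
#'
#' Every tabular stage output starts with a comment line carrying the
#' configuration hash and the stage seed.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param cfg A `pipeline_config` (optional).
#' @param seed Stage seed recorded in the header (optional).
#' @export
write_stage_table <- function(df, path, cfg = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (is.null(cfg)) "none" else config_hash(cfg)
  writeLines(sprintf("# agelink config_hash=%s seed=%s", hash,
                     if (is.null(seed)) "none" else seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
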