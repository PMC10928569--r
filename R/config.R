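#' Pipeline configuration
#'
#' Builds the validated configuration object shared by every pipeline stage.
#' Defaults follow the study conditions: 250 kb Hi-C bins, an FPKM activity
#' threshold of 0.8 (the end of the first mode of the bimodal log mean-FPKM
#' histogram), a five-value LASSO penalty grid, 100 subsamples of 80% of the
#' individuals per age group for the differential-expression robustness
#' filter, and score-threshold 0 for the LAS decomposition.
#'
#' @param resolution Genomic bin width in bp (positive integer).
#' @param fpkm_activity_threshold Mean-FPKM activity cutoff per age group.
#' @param lasso_penalties Relative penalty grid for the age-gene LASSO.
#' @param de_config List with `n_subsamples`, `subsample_fraction`,
#'   `subsample_fdr`, `n_primary` (target gene count after the p-value
#'   filter), `robustness_threshold`, `n_final` (target count after the
#'   fold-change filter).
#' @param pcst_config List with `beta` (prize scale), `omega` (per-tree
#'   penalty) and `mode` ("heuristic" or "exact").
#' @param las_config List with `score_threshold`, `max_submatrices`,
#'   `n_restarts`, `score_variant` ("contiguous" or "subset").
#' @param seeds Named integer seeds per stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(resolution = 250000L,
                            fpkm_activity_threshold = 0.8,
                            lasso_penalties = c(0.25, 0.5, 1, 2, 4),
                            de_config = list(),
                            pcst_config = list(),
                            las_config = list(),
                            seeds = list()) {
  de_default <- list(n_subsamples = 100L, subsample_fraction = 0.8,
                     subsample_fdr = 0.1, n_primary = 400L,
                     robustness_threshold = 0.7, n_final = 170L)
  pcst_default <- list(beta = 1, omega = 6, mode = "heuristic")
  las_default <- list(score_threshold = 0, max_submatrices = 50L,
                      n_restarts = 8L, score_variant = "contiguous",
                      max_len = Inf)
  seed_default <- list(simulate = 1L, de = 2L, las = 3L, null = 4L)
  cfg <- list(
    resolution = as.integer(resolution),
    fpkm_activity_threshold = fpkm_activity_threshold,
    lasso_penalties = as.numeric(lasso_penalties),
    de_config = utils::modifyList(de_default, de_config),
    pcst_config = utils::modifyList(pcst_default, pcst_config),
    las_config = utils::modifyList(las_default, las_config),
    seeds = utils::modifyList(seed_default, seeds)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!(is.integer(cfg$resolution) && length(cfg$resolution) == 1L && cfg$resolution > 0L))
    stop("resolution must be a positive integer")
  if (cfg$fpkm_activity_threshold <= 0)
    stop("fpkm_activity_threshold must be strictly positive")
  if (any(cfg$lasso_penalties <= 0)) stop("lasso penalties must be strictly positive")
  de <- cfg$de_config
  if (de$subsample_fraction <= 0 || de$subsample_fraction >= 1)
    stop("subsample_fraction must lie in (0, 1)")
  if (de$subsample_fdr <= 0 || de$n_subsamples < 1 ||
      de$robustness_threshold <= 0 || de$n_primary < 1 || de$n_final < 1)
    stop("de_config thresholds must be strictly positive")
  if (cfg$pcst_config$beta <= 0) stop("pcst beta must be strictly positive")
  if (cfg$pcst_config$omega < 0) stop("pcst omega must be non-negative")
  if (!cfg$pcst_config$mode %in% c("heuristic", "exact"))
    stop("pcst mode must be 'heuristic' or 'exact'")
  if (!cfg$las_config$score_variant %in% c("contiguous", "subset"))
    stop("las score_variant must be 'contiguous' or 'subset'")
  if (cfg$las_config$max_submatrices < 1 || cfg$las_config$n_restarts < 1)
    stop("las_config counts must be strictly positive")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round trip is bit-identical so that the configuration hash is
#' stable across serialization.
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `read_config` returns the `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  writeLines(yaml::as.yaml(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(resolution = raw$resolution,
                  fpkm_activity_threshold = raw$fpkm_activity_threshold,
                  lasso_penalties = raw$lasso_penalties,
                  de_config = raw$de_config,
                  pcst_config = raw$pcst_config,
                  las_config = raw$las_config,
                  seeds = raw$seeds)
}

#' Configuration hash for provenance
#'
#' MD5 of the canonical YAML serialization; stamped into every output header.
#'
#' @param cfg A `pipeline_config`.
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Desk-scale configuration for synthetic runs
#'
#' The default [pipeline_config()] carries the study-scale differential-
#' expression count targets (about 400 genes after the p-value filter and
#' 160-180 after the fold-change filter, appropriate for a ~20,000-gene
#' transcriptome). The synthetic cohort plants 50 DE genes per transition
#' among 2000 genes, so its companion configuration scales the targets
#' accordingly (200 primary, 50 final) while keeping every other default.
#'
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
sim_config <- function(...) {
  over <- list(...)
  las <- utils::modifyList(list(score_threshold = 20, max_submatrices = 20L,
                                max_len = 16),
                           if (is.null(over$las_config)) list() else over$las_config)
  over$las_config <- las
  de <- utils::modifyList(list(n_primary = 200L, n_final = 50L),
                          if (is.null(over$de_config)) list() else over$de_config)
  over$de_config <- de
  do.call(pipeline_config, over)
}
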