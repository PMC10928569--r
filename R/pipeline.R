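# Pipeline orchestration: stage execution, artifact writing, dependency
# checks, and the programmatic entry point behind the command-line wrapper.

stage_order <- c("simulate", "expression", "de", "network", "hic", "integrate")

state_path <- function(out_dir) file.path(out_dir, "state.rds")

load_state <- function(out_dir, needed_stage) {
  sp <- state_path(out_dir)
  if (!file.exists(sp))
    stop(sprintf("missing upstream artifacts: run stage '%s' first", needed_stage))
  st <- readRDS(sp)
  if (!needed_stage %in% st$done)
    stop(sprintf("missing upstream artifacts: run stage '%s' first", needed_stage))
  st
}

save_state <- function(state, out_dir) saveRDS(state, state_path(out_dir))

#' Run the pipeline
#'
#' Executes one stage (or `"all"`) of the synthetic-data pipeline: simulate
#' -> expression -> de -> network -> hic -> integrate. Each stage writes
#' versioned tabular outputs (with the configuration hash and stage seed in
#' a header line) under `out_dir` plus a cumulative state cache consumed by
#' downstream stages; running a stage whose dependencies have not been run
#' is a dependency error naming the stage to run first. Reruns with
#' identical config and seeds reproduce identical tables.
#'
#' @param config A `pipeline_config`.
#' @param stage One of simulate, expression, de, network, hic, integrate,
#'   all.
#' @param out_dir Output directory.
#' @param spec Optional `sim_spec` overriding the default study conditions.
#' @return Invisibly, the cumulative state list (all in-memory results).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stage = c("all", stage_order),
                         out_dir = tempfile("agelink_"),
                         spec = NULL) {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") stage_order else stage
  for (s in stages) {
    st <- switch(s,
      simulate = stage_simulate(config, out_dir, spec),
      expression = stage_expression(config, out_dir),
      de = stage_de(config, out_dir),
      network = stage_network(config, out_dir),
      hic = stage_hic(config, out_dir),
      integrate = stage_integrate(config, out_dir))
  }
  invisible(readRDS(state_path(out_dir)))
}

stage_simulate <- function(config, out_dir, spec = NULL) {
  if (is.null(spec)) spec <- sim_spec(seed = config$seeds$simulate,
                                      resolution = config$resolution)
  sim <- simulate_cohort_counts(spec)
  sim2 <- simulate_interactome(spec, sim)
  hic <- simulate_hic(spec, list(truth = sim2$truth))
  state <- list(done = "simulate", config = config, spec = spec,
                cohort = sim$cohort, catalog = sim$catalog,
                ppi = sim2$ppi, regulons = sim2$regulons,
                hic_samples = hic$samples, truth = hic$truth)
  counts_df <- data.frame(gene = rownames(sim$cohort$counts), sim$cohort$counts,
                          check.names = FALSE)
  write_stage_table(counts_df, file.path(out_dir, "counts.tsv"), config, spec$seed)
  write_stage_table(data.frame(sample_id = names(sim$cohort$ages),
                               age = sim$cohort$ages),
                    file.path(out_dir, "samples.tsv"), config, spec$seed)
  write_stage_table(as.data.frame(sim$catalog), file.path(out_dir, "catalog.tsv"),
                    config, spec$seed)
  write_stage_table(sim2$ppi, file.path(out_dir, "ppi.tsv"), config, spec$seed)
  write_stage_table(sim2$regulons, file.path(out_dir, "regulons.tsv"),
                    config, spec$seed)
  for (nm in names(hic$samples))
    write_hic_sample(hic$samples[[nm]], file.path(out_dir, "hic"))
  write_ground_truth(hic$truth, file.path(out_dir, "ground_truth.json"))
  save_state(state, out_dir)
  state
}

stage_expression <- function(config, out_dir) {
  state <- load_state(out_dir, "simulate")
  sf <- compute_size_factors(state$cohort)
  fpkm <- compute_fpkm(state$cohort, state$catalog)
  vst <- vst_transform(state$cohort, sf)
  lasso <- select_age_genes_lasso(vst, state$cohort$ages, config$lasso_penalties)
  mid <- as.character(config$lasso_penalties[ceiling(length(config$lasso_penalties) / 2)])
  selected <- lasso$selected[[mid]]
  groups <- define_age_groups(vst, state$cohort$ages, selected)
  activity <- call_active_genes(fpkm, groups, config$fpkm_activity_threshold)
  state <- modifyList(state, list(
    done = c(state$done, "expression"), size_factors = sf, fpkm = fpkm,
    vst = vst, lasso = lasso, lasso_genes = selected, groups = groups,
    activity = activity))
  write_stage_table(data.frame(sample_id = names(sf), size_factor = sf),
                    file.path(out_dir, "size_factors.tsv"), config)
  if (!is.null(lasso$coefficients))
    write_stage_table(lasso$coefficients,
                      file.path(out_dir, "lasso_selection.tsv"), config)
  write_stage_table(data.frame(gene = rownames(fpkm$mat), fpkm$mat,
                               check.names = FALSE),
                    file.path(out_dir, "fpkm.tsv"), config)
  write_stage_table(data.frame(gene = rownames(vst$mat), vst$mat,
                               check.names = FALSE),
                    file.path(out_dir, "vst.tsv"), config)
  write_stage_table(data.frame(sample_id = names(groups$labels),
                               group = groups$labels,
                               age = state$cohort$ages[names(groups$labels)]),
                    file.path(out_dir, "age_groups.tsv"), config)
  write_stage_table(data.frame(gene = rownames(activity), activity),
                    file.path(out_dir, "activity.tsv"), config)
  save_state(state, out_dir)
  state
}

stage_de <- function(config, out_dir) {
  state <- load_state(out_dir, "expression")
  n_groups <- nrow(state$groups$ranges)
  de <- list()
  for (t in seq_len(n_groups - 1)) {
    de[[as.character(t)]] <- robust_de_selection(
      state$cohort, state$groups, t, config, seed = config$seeds$de + t)
    write_stage_table(de[[as.character(t)]],
                      file.path(out_dir, sprintf("de_transition%d.tsv", t)),
                      config, config$seeds$de + t)
  }
  n_sig <- min(170L, floor(nrow(state$cohort$counts) / 3))
  sig <- list(young = state_signature_genes(state$cohort, state$groups, 1, n_sig),
              old = state_signature_genes(state$cohort, state$groups, n_groups,
                                          n_sig))
  imb <- length_imbalance_test(de[[as.character(n_groups - 1)]], state$catalog)
  state <- modifyList(state, list(done = c(state$done, "de"), de = de,
                                  signatures = sig, length_imbalance = imb))
  write_stage_table(imb, file.path(out_dir, "length_imbalance.tsv"), config)
  save_state(state, out_dir)
  state
}

stage_network <- function(config, out_dir) {
  state <- load_state(out_dir, "de")
  ppi <- transform_edge_costs(state$ppi)
  n_nets <- length(state$de) - 1
  sols <- list(); nets <- list()
  older <- NULL
  for (k in rev(seq_len(n_nets))) {   # oldest first (design-2 propagation)
    net <- build_transition_network(
      ppi, state$activity, source_de = state$de[[as.character(k)]],
      target_de = state$de[[as.character(k + 1)]],
      regulons = state$regulons, source_groups = c(k, k + 1),
      design = 2L, older = older)
    sol <- solve_pcst(net, beta = config$pcst_config$beta,
                      omega = config$pcst_config$omega,
                      mode = config$pcst_config$mode)
    sol <- classify_roles(sol, net, state$regulons)
    nets[[k]] <- net; sols[[k]] <- sol
    older <- sol
    roles <- attr(sol, "roles")
    write_stage_table(roles, file.path(out_dir, sprintf("steiner_S%d_nodes.tsv", k)),
                      config)
    write_stage_table(sol$edges, file.path(out_dir, sprintf("steiner_S%d_edges.tsv", k)),
                      config)
    write_stage_table(attr(sol, "summary"),
                      file.path(out_dir, sprintf("steiner_S%d_summary.tsv", k)), config)
  }
  state <- modifyList(state, list(done = c(state$done, "network"),
                                  ppi_costed = ppi, networks = nets,
                                  steiner = sols))
  save_state(state, out_dir)
  state
}

stage_hic <- function(config, out_dir) {
  state <- load_state(out_dir, "simulate")
  if (!"network" %in% state$done)
    state <- load_state(out_dir, "network")
  las_cfg <- config$las_config
  processed <- lapply(state$hic_samples, function(s) {
    s <- mask_excluded_regions(s, blacklist = state$blacklist)
    s <- balance_hic(s)
    log_zscore(s)
  })
  las <- lapply(processed, function(s) {
    lapply(s$maps, function(map)
      las_decompose(map, las_cfg$score_threshold, las_cfg$max_submatrices,
                    las_cfg$n_restarts, seed = config$seeds$las,
                    variant = las_cfg$score_variant,
                    max_len = if (is.null(las_cfg$max_len)) Inf else las_cfg$max_len))
  })
  pixels <- list()
  correlations <- list()
  for (cond in c("young", "old")) {
    r1 <- sprintf("%s_rep1", cond); r2 <- sprintf("%s_rep2", cond)
    px <- character(0); cors <- NULL
    for (key in names(processed[[r1]]$maps)) {
      rec <- reconcile_replicates(las[[r1]][[key]], las[[r2]][[key]],
                                  processed[[r1]]$maps[[key]],
                                  processed[[r2]]$maps[[key]],
                                  las_cfg$score_threshold)
      px <- c(px, rec$pixels)
      cors <- rbind(cors, data.frame(pair = key, r = rec$correlation,
                                     p = rec$cor_p,
                                     n = nrow(rec$kept)))
    }
    pixels[[cond]] <- unique(px)
    correlations[[cond]] <- cors
    write_stage_table(data.frame(pixel = pixels[[cond]]),
                      file.path(out_dir, sprintf("pixels_%s.tsv", cond)),
                      config, config$seeds$las)
  }
  diff <- build_difference_map(pixels$young, pixels$old)
  write_stage_table(data.frame(pixel = names(diff$labels), label = diff$labels),
                    file.path(out_dir, "difference_map.tsv"), config)
  write_stage_table(diff$summary, file.path(out_dir, "difference_summary.tsv"),
                    config)
  state <- modifyList(state, list(done = c(state$done, "hic"),
                                  hic_processed = processed, las = las,
                                  pixels = pixels,
                                  replicate_correlations = correlations,
                                  diff = diff))
  save_state(state, out_dir)
  state
}

stage_integrate <- function(config, out_dir) {
  state <- load_state(out_dir, "hic")
  if (!"network" %in% state$done)
    stop("missing upstream artifacts: run stage 'network' first")
  locus_map <- map_genes_to_loci(
    state$catalog, config$resolution,
    state$hic_samples[[1]]$bins,
    attr(state$hic_processed[[1]], "bin_mask"))
  gsi <- list()
  for (nm in names(state$signatures)) {
    for (dir in c("up", "down")) {
      sg <- state$signatures[[nm]]
      genes <- sg$gene[sg$direction == dir]
      key <- sprintf("%s_%s", nm, dir)
      gsi[[key]] <- tryCatch(
        geneset_difference_map(genes, locus_map, state$diff),
        error = function(e) NULL)
      if (!is.null(gsi[[key]]))
        write_stage_table(
          data.frame(class = names(gsi[[key]]$percent),
                     percent = gsi[[key]]$percent),
          file.path(out_dir, sprintf("geneset_intermingling_%s.tsv", key)), config)
    }
  }
  # TF-level statistics
  sols <- state$steiner
  tf_stats <- list()
  M <- nrow(state$cohort$counts)
  genome_targets <- split(state$regulons$target, state$regulons$tf)
  for (k in seq_along(sols)) {
    btf <- bridge_tfs(sols[[k]])
    if (!length(btf)) next
    tgt_de <- state$de[[as.character(k + 1)]]
    de_set <- tgt_de$gene[tgt_de$selected]
    enr <- tf_target_enrichment(genome_targets[btf], de_set, M)
    write_stage_table(enr, file.path(out_dir, sprintf("tf_enrichment_S%d.tsv", k)),
                      config)
    tf_stats[[k]] <- enr
  }
  partition <- if (length(sols) >= 3)
    partition_bridge_tfs(sols[[1]], sols[[2]], sols[[3]]) else NULL
  if (!is.null(partition))
    write_stage_table(partition, file.path(out_dir, "tf_partition.tsv"), config)
  state <- modifyList(state, list(done = c(state$done, "integrate"),
                                  locus_map = locus_map,
                                  geneset_intermingling = gsi,
                                  tf_enrichment = tf_stats,
                                  tf_partition = partition))
  save_state(state, out_dir)
  state
}
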