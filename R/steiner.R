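# Transition-network construction and prize-collecting Steiner solving.
#
# The pipeline connects the differentially expressed (DE) genes of one age
# transition (source) to the DE genes of the next transition (target) through
# a costed protein-interaction network augmented with TF -> target regulatory
# edges, and solves a prize-collecting Steiner forest to extract the "bridge"
# transcription factors.

#' Transform PPI confidence scores into edge costs
#'
#' cost(x) = 1 - (x - min_score)/(max_score - min_score) + pseudo_count, so
#' the highest-confidence interaction gets the minimum cost (the pseudo-count
#' alone) and the lowest-confidence one gets 1 + pseudo_count.
#'
#' @param ppi Data frame `protein_a, protein_b, score`.
#' @param pseudo_count Additive floor preventing zero-cost edges
#'   (default 0.01).
#' @return The data frame with a `cost` column and `score_min`/`score_max`
#'   attributes.
#' @export
transform_edge_costs <- function(ppi, pseudo_count = 0.01) {
  smin <- min(ppi$score); smax <- max(ppi$score)
  if (smax <= smin) stop("all PPI scores equal: cost normalization undefined")
  ppi$cost <- 1 - (ppi$score - smin) / (smax - smin) + pseudo_count
  attr(ppi, "score_min") <- smin
  attr(ppi, "score_max") <- smax
  attr(ppi, "pseudo_count") <- pseudo_count
  ppi
}

target_id <- function(gene) paste0("tgt:", gene)

#' Build a transition network (designs 1-5)
#'
#' Design 1: the costed PPI restricted to genes active in either of the two
#' source-transition age groups; source DE genes prized by |log2FC|; target
#' DE genes added as separate nodes prized by |log2FC| and connected by
#' regulatory edges (cost = the PPI pseudo-count, i.e. the minimum PPI cost)
#' from TFs present in the PPI part. Designs are cumulative: Design 2 also
#' adds the bridge TFs of the next-older solved network as extra target nodes
#' prized with the minimum target prize; Design 3 adds PPI edges among target
#' nodes; Design 4 adds all remaining older-network nodes and their PPI edges
#' to target nodes (unprized); Design 5 prizes those nodes at the minimum
#' target prize as well.
#'
#' @param ppi Costed PPI from [transform_edge_costs()].
#' @param activity Logical gene x group matrix from [call_active_genes()].
#' @param source_de,target_de `de_result`s with `selected` flags.
#' @param regulons Data frame `tf, target`.
#' @param source_groups Integer labels of the two source-transition groups.
#' @param design Integer in 1..5 (default 1).
#' @param older Solved `steiner_network` of the next-older transition
#'   (required for designs >= 2 when available).
#' @return A `transition_network`: `nodes` (id, gene, prize, kind, is_tf),
#'   `edges` (a, b, cost, kind), `design`, `warnings`.
#' @export
build_transition_network <- function(ppi, activity, source_de, target_de,
                                     regulons, source_groups, design = 1L,
                                     older = NULL) {
  stopifnot(design %in% 1:5)
  # designs >= 2 propagate information from the next-older solved network;
  # for the oldest transition no such network exists and the additions are
  # skipped
  if (is.null(older) && design >= 2) design_eff <- 1L else design_eff <- design
  pseudo <- attr(ppi, "pseudo_count")
  if (is.null(pseudo)) stop("ppi must come from transform_edge_costs()")

  gcols <- paste0("group", source_groups)
  active <- rownames(activity)[rowSums(activity[, gcols, drop = FALSE]) > 0]
  keep <- ppi$protein_a %in% active & ppi$protein_b %in% active
  ppi_part <- ppi[keep, , drop = FALSE]
  ppi_nodes <- unique(c(ppi_part$protein_a, ppi_part$protein_b))

  src <- source_de[source_de$selected, , drop = FALSE]
  missing_src <- setdiff(src$gene, ppi_nodes)
  src_prize <- setNames(abs(src$log2fc), src$gene)
  src_prize <- src_prize[intersect(names(src_prize), ppi_nodes)]

  tgt <- target_de[target_de$selected, , drop = FALSE]
  tgt_prize <- setNames(abs(tgt$log2fc), tgt$gene)
  min_tgt_prize <- if (length(tgt_prize)) min(tgt_prize) else 0

  tfs_in_ppi <- intersect(unique(regulons$tf), ppi_nodes)
  reg <- regulons[regulons$tf %in% tfs_in_ppi, , drop = FALSE]

  nodes <- data.frame(id = ppi_nodes, gene = ppi_nodes,
                      prize = unname(ifelse(ppi_nodes %in% names(src_prize),
                                            src_prize[ppi_nodes], 0)),
                      kind = "ppi", stringsAsFactors = FALSE)
  tgt_genes <- names(tgt_prize)
  nodes <- rbind(nodes, data.frame(id = target_id(tgt_genes), gene = tgt_genes,
                                   prize = unname(tgt_prize), kind = "target_de"))
  edges <- data.frame(a = ppi_part$protein_a, b = ppi_part$protein_b,
                      cost = ppi_part$cost, kind = "ppi",
                      stringsAsFactors = FALSE)
  reg_tgt <- reg[reg$target %in% tgt_genes, , drop = FALSE]
  if (nrow(reg_tgt))
    edges <- rbind(edges, data.frame(a = reg_tgt$tf, b = target_id(reg_tgt$target),
                                     cost = pseudo, kind = "regulatory"))

  if (design_eff >= 2) {
    older_tfs <- setdiff(bridge_tfs(older), nodes$gene[nodes$kind != "ppi"])
    older_tfs <- setdiff(older_tfs, tgt_genes)
    if (length(older_tfs)) {
      nodes <- rbind(nodes, data.frame(id = target_id(older_tfs), gene = older_tfs,
                                       prize = min_tgt_prize, kind = "target_de"))
      reg_old <- reg[reg$target %in% older_tfs, , drop = FALSE]
      if (nrow(reg_old))
        edges <- rbind(edges, data.frame(a = reg_old$tf,
                                         b = target_id(reg_old$target),
                                         cost = pseudo, kind = "regulatory"))
    }
  }
  tgt_side <- nodes$gene[nodes$kind == "target_de"]
  if (design_eff >= 3) {
    tt <- ppi[ppi$protein_a %in% tgt_side & ppi$protein_b %in% tgt_side, ,
              drop = FALSE]
    if (nrow(tt))
      edges <- rbind(edges, data.frame(a = target_id(tt$protein_a),
                                       b = target_id(tt$protein_b),
                                       cost = tt$cost, kind = "ppi"))
  }
  if (design_eff >= 4) {
    older_genes <- unique(sub("^tgt:", "", older$nodes))
    older_rest <- setdiff(older_genes, c(nodes$gene, bridge_tfs(older)))
    if (length(older_rest)) {
      prize5 <- if (design_eff == 5) min_tgt_prize else 0
      nodes <- rbind(nodes, data.frame(id = target_id(older_rest),
                                       gene = older_rest, prize = prize5,
                                       kind = "older_node"))
      ot <- ppi[(ppi$protein_a %in% older_rest & ppi$protein_b %in% tgt_side) |
                (ppi$protein_b %in% older_rest & ppi$protein_a %in% tgt_side), ,
                drop = FALSE]
      if (nrow(ot))
        edges <- rbind(edges, data.frame(a = target_id(ot$protein_a),
                                         b = target_id(ot$protein_b),
                                         cost = ot$cost, kind = "ppi"))
    }
  }
  edges <- unique(edges)
  nodes$is_tf <- nodes$gene %in% unique(regulons$tf)
  structure(list(nodes = nodes, edges = edges, design = design,
                 pseudo_count = pseudo, warnings = missing_src),
            class = "transition_network")
}

# ---- PCST solving -----------------------------------------------------------

# Optimal edge set for a fixed included-node set: minimum spanning forest by
# Kruskal where an edge is taken only when it merges two components and its
# cost is below omega (merging two trees saves one per-tree penalty).
forest_for_nodes <- function(include, edges_idx, edge_cost, omega, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  sel <- logical(nrow(edges_idx))
  ok <- include[edges_idx[, 1]] & include[edges_idx[, 2]] & edge_cost < omega
  for (e in which(ok)) {
    ra <- find(edges_idx[e, 1]); rb <- find(edges_idx[e, 2])
    if (ra != rb) { parent[ra] <- rb; sel[e] <- TRUE }
  }
  sel
}

pcst_objective <- function(include, sel_edges, edge_cost, prize, beta, omega) {
  n_trees <- sum(include) - sum(sel_edges)
  sum(edge_cost[sel_edges]) + beta * sum(prize[!include]) + omega * n_trees
}

# Strong pruning of one tree component: bottom-up net worth
# W(v) = beta*p(v) + sum over children of max(0, W(child) - cost(child, v));
# subtrees with non-positive margin are removed.
strong_prune <- function(tree_nodes, adj, edge_cost_lookup, prize, beta, root) {
  keep <- setNames(rep(TRUE, length(tree_nodes)), tree_nodes)
  W <- setNames(beta * prize[tree_nodes], tree_nodes)
  parent <- setNames(rep(NA_integer_, length(tree_nodes)), tree_nodes)
  order_visit <- character(0)
  stack <- root
  seen <- setNames(rep(FALSE, length(tree_nodes)), tree_nodes)
  seen[as.character(root)] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_visit <- c(order_visit, v)
    for (u in adj[[v]]) if (!seen[u]) {
      seen[u] <- TRUE; parent[u] <- v; stack <- c(stack, u)
    }
  }
  for (v in rev(order_visit)) {
    pv <- parent[v]
    if (!is.na(pv)) {
      c_uv <- edge_cost_lookup[[paste(sort(c(v, pv)), collapse = "\r")]]
      if (W[v] <= c_uv) {
        # prune whole subtree rooted at v
        drop <- v
        i <- 1
        while (i <= length(drop)) {
          for (u in adj[[drop[i]]]) if (!is.na(parent[u]) && parent[u] == drop[i] && keep[u])
            drop <- c(drop, u)
          i <- i + 1
        }
        keep[drop] <- FALSE
      } else {
        W[pv] <- W[pv] + (W[v] - c_uv)
      }
    }
  }
  names(keep)[keep]
}

#' Solve the prize-collecting Steiner forest
#'
#' Minimizes sum of selected edge costs + beta * sum of excluded node prizes
#' + omega * (number of trees). `mode = "exact"` enumerates all node subsets
#' (provably optimal; feasible up to ~20 nodes); `mode = "heuristic"` grows a
#' terminal-spanning tree from the metric closure of the prized nodes,
#' strong-prunes it, drops unprofitable components, and (on graphs up to
#' `local_search_max` nodes) hill-climbs over single-node inclusion flips.
#' For a fixed node set the optimal edge set is the minimum spanning forest
#' that admits only edges cheaper than omega.
#'
#' @param net A `transition_network` (or any list with `nodes`/`edges`).
#' @param beta Prize scale (default 1).
#' @param omega Per-tree penalty (default 6).
#' @param mode "heuristic" or "exact".
#' @param local_search_max Hill-climb only when the graph has at most this
#'   many nodes (default 500).
#' @return A `steiner_network`: `nodes` (included ids), `edges`, `objective`,
#'   `solver` metadata.
#' @export
solve_pcst <- function(net, beta = 1, omega = 6, mode = c("heuristic", "exact"),
                       local_search_max = 500L) {
  mode <- match.arg(mode)
  ids <- net$nodes$id
  n <- length(ids)
  idx_of <- setNames(seq_len(n), ids)
  prize <- net$nodes$prize
  ord <- order(net$edges$cost)
  edges <- net$edges[ord, , drop = FALSE]
  eidx <- cbind(idx_of[edges$a], idx_of[edges$b])
  ecost <- edges$cost

  eval_nodes <- function(include) {
    sel <- forest_for_nodes(include, eidx, ecost, omega, n)
    list(sel = sel, obj = pcst_objective(include, sel, ecost, prize, beta, omega))
  }

  if (mode == "exact") {
    if (n > 20) stop("exact mode supports at most 20 nodes")
    best <- list(obj = Inf, include = rep(FALSE, n), sel = logical(nrow(edges)))
    for (code in 0:(2^n - 1)) {
      include <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
      ev <- eval_nodes(include)
      if (ev$obj < best$obj - 1e-12)
        best <- list(obj = ev$obj, include = include, sel = ev$sel)
    }
    include <- best$include; sel <- best$sel; obj <- best$obj
  } else {
    include <- heuristic_start(ids, prize, edges, eidx, ecost, beta, omega, n)
    ev <- eval_nodes(include)
    include <- prune_solution(include, ev$sel, eidx, ecost, prize, beta, omega, ids)
    ev <- eval_nodes(include)
    if (n <= local_search_max) {
      repeat {
        improved <- FALSE
        for (v in seq_len(n)) {
          cand <- include; cand[v] <- !cand[v]
          ev2 <- eval_nodes(cand)
          if (ev2$obj < ev$obj - 1e-12) {
            include <- cand; ev <- ev2; improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    sel <- ev$sel; obj <- ev$obj
  }
  structure(list(nodes = ids[include],
                 edges = edges[sel, , drop = FALSE],
                 objective = obj,
                 solver = list(beta = beta, omega = omega, mode = mode)),
            class = "steiner_network")
}

# Metric-closure construction: shortest paths among prized nodes, MST of the
# closure, expansion to the underlying paths.
heuristic_start <- function(ids, prize, edges, eidx, ecost, beta, omega, n) {
  include <- prize > 0 & beta * prize > 0   # all terminals start included
  terminals <- ids[prize > 0]
  if (length(terminals) >= 2 && nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                       vertices = data.frame(name = ids))
    igraph::E(g)$weight <- edges$cost
    dmat <- igraph::distances(g, v = terminals, to = terminals)
    finite <- is.finite(dmat)
    cg_edges <- which(upper.tri(dmat) & finite, arr.ind = TRUE)
    if (nrow(cg_edges)) {
      cg <- igraph::graph_from_data_frame(
        data.frame(a = terminals[cg_edges[, 1]], b = terminals[cg_edges[, 2]]),
        directed = FALSE, vertices = data.frame(name = terminals))
      igraph::E(cg)$weight <- dmat[cg_edges]
      mst <- igraph::mst(cg)
      me <- igraph::as_data_frame(mst, what = "edges")
      for (k in seq_len(nrow(me))) {
        if (me$weight[k] >= omega) next   # cheaper to keep separate trees
        sp <- igraph::shortest_paths(g, from = me$from[k], to = me$to[k],
                                     output = "vpath")$vpath[[1]]
        include[match(names(sp), ids)] <- TRUE
      }
    }
  }
  include
}

# Drop components whose total kept value does not pay for their edges + tree
# penalty; also strong-prune each component tree.
prune_solution <- function(include, sel, eidx, ecost, prize, beta, omega, ids) {
  if (!any(include)) return(include)
  n <- length(include)
  comp <- rep(NA_integer_, n)
  adj <- vector("list", n)
  for (e in which(sel)) {
    a <- eidx[e, 1]; b <- eidx[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  cid <- 0L
  for (v in which(include)) if (is.na(comp[v])) {
    cid <- cid + 1L
    stack <- v; comp[v] <- cid
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[u]]) if (is.na(comp[w])) { comp[w] <- cid; stack <- c(stack, w) }
    }
  }
  lookup <- list()
  for (e in which(sel))
    lookup[[paste(sort(ids[eidx[e, ]]), collapse = "\r")]] <- ecost[e]
  adj_named <- setNames(lapply(seq_len(n), function(v) ids[adj[[v]]]), ids)
  pr <- setNames(prize, ids)
  for (k in seq_len(cid)) {
    members <- which(comp == k)
    mnames <- ids[members]
    root <- mnames[which.max(pr[mnames])]
    kept <- strong_prune(mnames, adj_named, lookup, pr, beta, root)
    dropped <- setdiff(mnames, kept)
    include[match(dropped, ids)] <- FALSE
    kept_idx <- match(kept, ids)
    edge_sum <- 0
    for (e in which(sel)) if (all(eidx[e, ] %in% kept_idx)) edge_sum <- edge_sum + ecost[e]
    keep_value <- beta * sum(pr[kept])
    if (length(kept) && keep_value <= edge_sum + omega)
      include[kept_idx] <- FALSE
  }
  include
}

#' Extract bridge TFs from a solved network
#' @param sol A `steiner_network` with roles (from [classify_roles()]), or a
#'   role-annotated solution.
#' @return Character vector of bridge TF gene ids.
#' @export
bridge_tfs <- function(sol) {
  r <- attr(sol, "roles")
  if (is.null(r)) stop("solution has no role annotation; run classify_roles()")
  unique(r$gene[r$role == "bridge_tf"])
}

#' Classify node roles in a Steiner solution
#'
#' Roles (not mutually exclusive): `source_de` / `target_de` for included
#' prized nodes of each kind; `steiner` for included unprized nodes;
#' `bridge_tf` for TFs incident to at least one *selected* regulatory edge
#' into an included target node.
#'
#' @param sol A `steiner_network` from [solve_pcst()].
#' @param net The `transition_network` it was solved on.
#' @param regulons Data frame `tf, target`.
#' @return `sol` with a `roles` attribute (long data frame `id, gene, role`)
#'   and a `summary` attribute (counts per role plus node/edge totals).
#' @export
classify_roles <- function(sol, net, regulons) {
  nd <- net$nodes
  inc <- nd[nd$id %in% sol$nodes, , drop = FALSE]
  roles <- NULL
  add_role <- function(ids, genes, role) {
    if (length(ids)) rbind(roles, data.frame(id = ids, gene = genes, role = role))
    else roles
  }
  src <- inc[inc$kind == "ppi" & inc$prize > 0, ]
  roles <- add_role(src$id, src$gene, "source_de")
  tgt <- inc[inc$kind == "target_de" & inc$prize > 0, ]
  roles <- add_role(tgt$id, tgt$gene, "target_de")
  st <- inc[inc$prize == 0, ]
  roles <- add_role(st$id, st$gene, "steiner")
  sel_reg <- sol$edges[sol$edges$kind == "regulatory", , drop = FALSE]
  if (nrow(sel_reg)) {
    into_included <- sel_reg$b %in% sol$nodes & sel_reg$a %in% sol$nodes
    btf <- unique(sel_reg$a[into_included])
    btf <- btf[btf %in% unique(regulons$tf)]
    roles <- add_role(btf, btf, "bridge_tf")
  }
  if (is.null(roles)) roles <- data.frame(id = character(), gene = character(),
                                          role = character())
  attr(sol, "roles") <- roles
  attr(sol, "summary") <- data.frame(
    nodes = length(sol$nodes), edges = nrow(sol$edges),
    source_de = sum(roles$role == "source_de"),
    target_de = sum(roles$role == "target_de"),
    steiner = sum(roles$role == "steiner"),
    bridge_tfs = sum(roles$role == "bridge_tf"))
  sol
}
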