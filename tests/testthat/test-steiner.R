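test_that("the confidence-to-cost transform hits its endpoints and midpoint", {
  ppi <- data.frame(protein_a = c("a", "b", "x"), protein_b = c("b", "c", "y"),
                    score = c(150, 575, 1000))
  pc <- transform_edge_costs(ppi)
  expect_equal(pc$cost[pc$score == 1000], 0.01)   # max score -> minimum cost
  expect_equal(pc$cost[pc$score == 150], 1.01)    # min score -> 1 + pseudo-count
  expect_equal(pc$cost[pc$score == 575], 0.51)    # midpoint
  expect_true(all(diff(pc$cost[order(pc$score)]) < 0))  # strictly decreasing
  expect_error(transform_edge_costs(data.frame(protein_a = "a",
                                               protein_b = "b", score = 5)),
               "equal")
})

make_toy_transition <- function(design = 1L, older = NULL) {
  ppi <- transform_edge_costs(data.frame(
    protein_a = c("srcA", "srcA", "tf1", "tf2", "inact", "srcB"),
    protein_b = c("conn", "tf1", "tf2", "srcB", "srcA", "conn"),
    score = c(900, 1000, 800, 700, 600, 500)))
  activity <- matrix(TRUE, 6, 3,
                     dimnames = list(c("srcA", "srcB", "conn", "tf1", "tf2",
                                       "inact"),
                                     c("group1", "group2", "group3")))
  activity["inact", ] <- FALSE
  source_de <- data.frame(gene = c("srcA", "srcB", "ghost"),
                          log2fc = c(1.5, -2, 1), selected = TRUE)
  target_de <- data.frame(gene = c("tgtX", "tgtY"), log2fc = c(2.5, -1.2),
                          selected = TRUE)
  regulons <- data.frame(tf = c("tf1", "tf1", "tf2", "tf2"),
                         target = c("tgtX", "tgtY", "tgtY", "tf1"))
  build_transition_network(ppi, activity, source_de, target_de, regulons,
                           source_groups = c(1, 2), design = design,
                           older = older)
}

test_that("transition networks apply the activity filter, prize rules and the fixed regulatory cost", {
  net <- make_toy_transition()
  # every regulatory edge costs the pseudo-count (minimum PPI cost)
  reg <- net$edges[net$edges$kind == "regulatory", ]
  expect_gt(nrow(reg), 0)
  expect_true(all(reg$cost == 0.01))
  # a gene inactive in both source-transition groups is absent from the PPI part
  expect_false("inact" %in% net$nodes$id)
  # source DE genes missing from the PPI node set are warned, not dropped silently
  expect_identical(net$warnings, "ghost")
  # prizes: source DE by |log2FC|, target nodes separate with their own prizes
  expect_equal(net$nodes$prize[net$nodes$id == "srcB"], 2)
  expect_equal(net$nodes$prize[net$nodes$id == "tgt:tgtY"], 1.2)
  # regulatory edges only reach target-side nodes
  expect_true(all(grepl("^tgt:", reg$b)))
})

test_that("design 2 adds older-network bridge TFs as target nodes at the minimum target prize", {
  net1 <- make_toy_transition()
  sol <- solve_pcst(net1, beta = 5, omega = 0.5)
  sol <- classify_roles(sol, net1, data.frame(tf = c("tf1", "tf2"),
                                              target = c("tgtX", "tgtY")))
  older <- sol
  # pretend tf2 was a bridge TF in the older network
  roles <- attr(older, "roles")
  if (!"tf2" %in% roles$gene[roles$role == "bridge_tf"])
    attr(older, "roles") <- rbind(roles, data.frame(id = "tf2", gene = "tf2",
                                                    role = "bridge_tf"))
  net2 <- make_toy_transition(design = 2L, older = older)
  ids <- net2$nodes$id
  added <- setdiff(ids, make_toy_transition()$nodes$id)
  expect_true(any(grepl("^tgt:tf", added)))
  min_prize <- min(c(2.5, 1.2))
  expect_true(all(net2$nodes$prize[net2$nodes$id %in% added] == min_prize))
})

test_that("solve_pcst handles the canonical small cases", {
  # two prized nodes joined by a cheap edge: connecting beats excluding
  net <- list(nodes = data.frame(id = c("A", "B"), gene = c("A", "B"),
                                 prize = c(5, 5), kind = "ppi"),
              edges = data.frame(a = "A", b = "B", cost = 1, kind = "ppi"))
  for (mode in c("exact", "heuristic")) {
    sol <- solve_pcst(net, beta = 1, omega = 3, mode = mode)
    expect_setequal(sol$nodes, c("A", "B"))
    expect_equal(sol$objective, 1 + 3)   # edge + one tree penalty
  }
  # an isolated node with a tiny prize is excluded and its prize paid
  net2 <- list(nodes = data.frame(id = c("A", "B"), gene = c("A", "B"),
                                  prize = c(0.1, 0), kind = "ppi"),
               edges = data.frame(a = "A", b = "B", cost = 1, kind = "ppi"))
  sol2 <- solve_pcst(net2, beta = 1, omega = 3, mode = "exact")
  expect_length(sol2$nodes, 0)
  expect_equal(sol2$objective, 0.1)
})

test_that("the reported objective equals its recomputed decomposition", {
  for (seed in 1:5) {
    inst <- random_pcst_instance(seed + 100)
    sol <- solve_pcst(inst, beta = 1, omega = 2, mode = "heuristic")
    edge_sum <- sum(sol$edges$cost)
    excluded <- setdiff(inst$nodes$id, sol$nodes)
    prize_sum <- sum(inst$nodes$prize[inst$nodes$id %in% excluded])
    # tree count: components of the selected forest (isolated nodes included)
    n_trees <- length(sol$nodes) - nrow(sol$edges)
    expect_equal(sol$objective, edge_sum + prize_sum + 2 * n_trees,
                 tolerance = 1e-9)
  }
})

test_that("raising beta never decreases the number of included prized nodes", {
  inst <- random_pcst_instance(7)
  n_prized <- sapply(c(0.5, 1, 2, 4, 8), function(b) {
    sol <- solve_pcst(inst, beta = b, omega = 2, mode = "exact")
    sum(inst$nodes$prize[inst$nodes$id %in% sol$nodes] > 0)
  })
  expect_true(all(diff(n_prized) >= 0))
})

test_that("roles are classified per definition and are not exclusive", {
  net <- make_toy_transition()
  regulons <- data.frame(tf = c("tf1", "tf1", "tf2"),
                         target = c("tgtX", "tgtY", "tgtY"))
  sol <- solve_pcst(net, beta = 5, omega = 0.5, mode = "exact")
  sol <- classify_roles(sol, net, regulons)
  roles <- attr(sol, "roles")
  # a TF whose selected regulatory edge reaches an included target is a bridge TF
  sel_reg <- sol$edges[sol$edges$kind == "regulatory", ]
  expect_true(all(unique(sel_reg$a) %in% roles$gene[roles$role == "bridge_tf"]))
  # included unprized nodes are steiner nodes
  unprized <- net$nodes$id[net$nodes$prize == 0]
  inc_unprized <- intersect(sol$nodes, unprized)
  expect_setequal(roles$id[roles$role == "steiner"], inc_unprized)
  # summary counts agree with the role table
  sm <- attr(sol, "summary")
  expect_identical(sm$bridge_tfs, sum(roles$role == "bridge_tf"))
  expect_identical(sm$nodes, length(sol$nodes))
})
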