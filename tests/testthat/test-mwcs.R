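test_that("align_inputs reconciles network nodes and scored genes", {
  net <- network_from_edges(c("A", "B"), c("B", "C"))
  sc <- make_scores(c(A = 1, B = -1))
  al <- align_inputs(net, sc, "drop")
  expect_setequal(igraph::V(al$network)$name, c("A", "B"))
  expect_equal(al$network_absent, character(0))

  sc2 <- make_scores(c(A = 1, B = -1, D = 2))
  al2 <- align_inputs(net, sc2, "drop")
  expect_equal(al2$network_absent, "D")

  expect_warning(al3 <- align_inputs(net, sc, "impute_zero"), "imputed")
  expect_setequal(igraph::V(al3$network)$name, c("A", "B", "C"))
  expect_equal(unname(al3$scores$scores[["C"]]), 0)

  expect_error(align_inputs(net, make_scores(c(Z = 1)), "drop"), "overlap")
})

test_that("exact solver reproduces hand-enumerated optima", {
  # path A(-1)-B(+2)-C(-0.5)-D(+1): best of all 10 connected subsets
  inst <- path_graph(c(A = -1, B = 2, C = -0.5, D = 1))
  mod <- solve_exact(inst$network, inst$scores)
  expect_equal(mod$members, c("B", "C", "D"))
  expect_equal(mod$total_score, 2.5)
  expect_equal(mod$solver, "exact")
  expect_equal(mod$total_score, sum(mod$node_scores), tolerance = 1e-9)

  # star: center never profitable; leaf tie broken lexicographically
  star <- network_from_edges(rep("E", 3), c("F", "G", "H"))
  mod2 <- solve_exact(star, make_scores(c(E = -3, F = 1, G = 1, H = 1)))
  expect_equal(mod2$members, "F")
  expect_equal(mod2$total_score, 1.0)

  # single node
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "X"
  mod3 <- solve_exact(g1, make_scores(c(X = 0.7)))
  expect_equal(mod3$members, "X")
  expect_equal(mod3$total_score, 0.7)

  big <- igraph::sample_gnp(25, 0.2)
  igraph::V(big)$name <- paste0("n", 1:25)
  expect_error(
    solve_exact(big, make_scores(setNames(rnorm(25), paste0("n", 1:25)))),
    "solve_heuristic")
})

test_that("exact solver matches the naive enumerator on random instances", {
  for (seed in 1:25) {
    inst <- random_scored_instance(n = sample(6:12, 1), seed = seed)
    ex <- suppressWarnings(solve_exact(inst$network, inst$scores))
    nv <- naive_mwcs(inst$network, inst$scores$scores)
    expect_equal(ex$total_score, nv$total_score, tolerance = 1e-9)
    expect_equal(ex$members, nv$members)
  }
})

test_that("heuristic matches exact on the toy cases and falls back sanely", {
  inst <- path_graph(c(A = -1, B = 2, C = -0.5, D = 1))
  h <- solve_heuristic(inst$network, inst$scores)
  expect_equal(h$members, c("B", "C", "D"))
  expect_equal(h$total_score, 2.5)
  expect_equal(h$solver, "heuristic")

  # all-negative path: documented single-node fallback with warning
  neg <- path_graph(c(L = -1, M = -0.2, N = -3))
  expect_warning(hf <- solve_heuristic(neg$network, neg$scores),
                 "no positively scoring")
  expect_equal(hf$members, "M")
  expect_equal(hf$total_score, -0.2)

  # unprofitable bridge: (+3) and (+2) joined through a -4 node
  bridge <- path_graph(c(P = 3, Q = -4, R = 2))
  hb <- solve_heuristic(bridge$network, bridge$scores)
  expect_equal(hb$members, "P")
  expect_equal(hb$total_score, 3)

  # profitable bridge is taken
  bridge2 <- path_graph(c(P = 3, Q = -1, R = 2))
  hb2 <- solve_heuristic(bridge2$network, bridge2$scores)
  expect_equal(hb2$members, c("P", "Q", "R"))
  expect_equal(hb2$total_score, 4)
})

test_that("heuristic modules never beat the optimum and keep invariants", {
  n_at_least_95 <- 0; total <- 0
  for (seed in 1:40) {
    inst <- random_scored_instance(n = sample(6:12, 1), seed = 100 + seed)
    nv <- naive_mwcs(inst$network, inst$scores$scores)
    h <- suppressWarnings(solve_heuristic(inst$network, inst$scores))
    expect_lte(h$total_score, nv$total_score + 1e-9)
    expect_gte(h$total_score, max(inst$scores$scores))

    # connectivity of the returned member set
    sub <- igraph::induced_subgraph(inst$network, h$members)
    expect_true(igraph::is_connected(sub))

    # no removable non-positive leaf
    if (length(h$members) > 1) {
      deg <- igraph::degree(sub)
      leaf_scores <- inst$scores$scores[names(deg)[deg == 1]]
      expect_true(all(leaf_scores > 0))
    }

    # each positive component wholly in or out
    gpos <- igraph::induced_subgraph(
      inst$network, names(inst$scores$scores)[inst$scores$scores > 0])
    comps <- split(igraph::V(gpos)$name,
                   igraph::components(gpos)$membership)
    for (cp in comps) {
      inside <- cp %in% h$members
      expect_true(all(inside) || all(!inside))
    }

    total <- total + 1
    if (nv$total_score <= 0 ||
        h$total_score >= 0.95 * nv$total_score) {
      n_at_least_95 <- n_at_least_95 + 1
    }
  }
  expect_gte(n_at_least_95 / total, 0.9)
})

test_that("disconnected graphs are solved per component, best returned", {
  net <- network_from_edges(c("A", "C"), c("B", "D"))  # two components
  sc <- make_scores(c(A = 1, B = 0.5, C = 4, D = -1))
  ex <- solve_exact(net, sc)
  expect_equal(ex$members, "C")
  h <- solve_heuristic(net, sc)
  expect_equal(h$members, "C")
})

test_that("module_report counts members and gene-set overlap", {
  inst <- path_graph(c(B = 2, C = -0.5, D = 1))
  mod <- solve_exact(inst$network, inst$scores)
  rep0 <- module_report(mod, inst$network)
  expect_equal(rep0$n_members, 3)
  expect_equal(rep0$set_overlap, integer(0))

  sets <- gene_sets(list(X = "B", full = c("B", "C", "D")))
  rep1 <- module_report(mod, inst$network, sets)
  expect_equal(unname(rep1$set_overlap["X"]), 1L)
  expect_equal(unname(rep1$set_overlap["full"]), 3L)
})
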