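test_that("decile assignment partitions genes into near-equal rank bins", {
  tab <- gene_table(sprintf("g%03d", 1:100), runif(100),
                    mean_expression = sample(1000, 100))
  bins <- assign_expression_deciles(tab)
  expect_equal(as.vector(table(bins$assignment)), rep(10L, 10))

  tab2 <- gene_table(sprintf("g%02d", 1:20), runif(20),
                     mean_expression = runif(20))
  bins2 <- assign_expression_deciles(tab2)
  expect_equal(as.vector(table(bins2$assignment)), rep(2L, 10))

  # monotone relabeling of expression leaves the assignment unchanged
  tab3 <- tab
  tab3$mean_expression <- log1p(tab$mean_expression) * 7
  expect_equal(assign_expression_deciles(tab3)$assignment, bins$assignment)

  expect_error(assign_expression_deciles(
    gene_table(paste0("g", 1:5), runif(5), mean_expression = 1:5)),
    "at least 10")
})

test_that("decile-matched sampling reproduces the target bin histogram exactly", {
  set.seed(1)
  tab <- gene_table(sprintf("g%03d", 1:200), runif(200),
                    mean_expression = rlnorm(200, 4, 1))
  bins <- assign_expression_deciles(tab)
  target <- sample(tab$gene, 25)
  draws <- sample_matched_set(bins, target, tab$gene, "decile",
                              n_sets = 20, seed = 9)
  expect_length(draws, 20)
  thist <- table(factor(bins$assignment[target], levels = 1:10))
  for (d in draws) {
    expect_length(d, 25)
    expect_length(intersect(d, target), 0)
    expect_equal(table(factor(bins$assignment[d], levels = 1:10)), thist)
  }
  # determinism
  expect_identical(draws,
                   sample_matched_set(bins, target, tab$gene, "decile",
                                      n_sets = 20, seed = 9))
})

test_that("pct10 matching draws replacements within a +/-10% expression window", {
  expr <- c(100, 91, 108, 250, 95, 104, 300, 99, 101, 111, 89, 110.5)
  tab <- gene_table(paste0("g", seq_along(expr)), runif(length(expr)),
                    mean_expression = expr)
  bins <- assign_expression_deciles(tab)
  target <- "g1"  # expression 100: candidates must lie in [90, 110]
  draws <- sample_matched_set(bins, target, tab$gene, "pct10",
                              n_sets = 50, seed = 2)
  picked <- unlist(draws)
  ex <- bins$expression[picked]
  expect_true(all(ex >= 90 & ex <= 110))
  expect_false("g1" %in% picked)

  # infeasible window errors and names the gene
  lonely <- gene_table(paste0("h", 1:12), runif(12),
                       mean_expression = c(1000, seq(1, 12, length.out = 11)))
  lbins <- assign_expression_deciles(lonely)
  expect_error(sample_matched_set(lbins, "h1", lonely$gene, "pct10",
                                  n_sets = 1, seed = 1), "h1")
})

test_that("connectivity statistic counts cross edges over incident edges", {
  # 6-cycle with chord 1-4: cross = {1-4}, incident = all 7 edges
  net <- network_from_edges(c("1", "2", "3", "4", "5", "6", "1"),
                            c("2", "3", "4", "5", "6", "1", "4"))
  expect_equal(connectivity_statistic(net, c("1", "2"), c("4", "5")), 1 / 7)
  # symmetry
  expect_equal(connectivity_statistic(net, c("4", "5"), c("1", "2")), 1 / 7)
  # disjoint sets with no cross edges
  expect_equal(connectivity_statistic(net, "1", "4"), 1 / 5)
  expect_equal(connectivity_statistic(net, "2", "5"), 0)
  # all nodes covered, every edge crosses on a bipartite graph
  bip <- network_from_edges(c("a", "a", "b", "b"), c("x", "y", "x", "y"))
  expect_equal(connectivity_statistic(bip, c("a", "b"), c("x", "y")), 1)
  # overlapping genes are assigned to the first set
  expect_warning(s <- connectivity_statistic(net, c("1", "4"), c("4", "5")),
                 "both sets")
  expect_equal(s, connectivity_statistic(net, c("1", "4"), "5"))
  expect_error(connectivity_statistic(net, "zz", "yy"), "empty")
})

test_that("connectivity enrichment adjusts over the number of disease sets", {
  inst <- simulate_instance(n_nodes = 200, model = "erdos_renyi", p = 0.04,
                            module_size = 10, disease_size = 15,
                            cross_edge_excess = 15, de_top = 25, seed = 8)
  set.seed(99)
  other <- sample(setdiff(inst$table$gene,
                          c(inst$disease_set, inst$de_set)), 15)
  sets <- gene_sets(list(planted = inst$disease_set, control = other))
  res <- suppressWarnings(
    connectivity_enrichment(inst$network, sets, inst$de_set, inst$table,
                            B = 50, seed = 4))
  expect_named(res, c("planted", "control"))
  for (r in res) {
    expect_equal(r$empirical_p,
                 (1 + sum(r$null_stats >= r$observed_stat)) / 51)
    expect_equal(r$adjusted_p, min(1, 2 * r$empirical_p))
    expect_length(r$null_stats, 50)
  }
  # the planted excess should score far above its expression-matched nulls
  expect_lt(res$planted$empirical_p, res$control$empirical_p + 0.5)
  expect_gt(res$planted$observed_stat, mean(res$planted$null_stats))
})

test_that("overlap test matches the closed-form hypergeometric tail", {
  # universe 50, reference 10, query 10, overlap 5
  uni <- paste0("u", 1:50)
  ref <- uni[1:10]
  qry <- c(uni[1:5], uni[41:45])
  res <- overlap_test(qry, ref, uni)
  manual <- sum(choose(10, 5:10) * choose(40, 10 - (5:10))) / choose(50, 10)
  expect_equal(res$overlap_count, 5)
  expect_equal(res$hypergeom_p, manual, tolerance = 1e-12)
  expect_equal(res$binomial_p,
               sum(dbinom(5:10, 10, 10 / 50)), tolerance = 1e-12)

  # saturation: query = reference = universe
  sat <- overlap_test(uni, uni, uni)
  expect_equal(sat$overlap_count, 50)
  expect_equal(sat$hypergeom_p, 1)

  # zero overlap still yields a finite odds ratio under Haldane correction
  z <- overlap_test(uni[1:5], uni[6:10], uni)
  expect_equal(z$overlap_count, 0)
  expect_true(is.finite(z$odds_ratio) && z$odds_ratio < 1)
  expect_error(overlap_test("a", "b", character(0)), "empty universe")
})
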