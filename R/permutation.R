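#' Randomize a network while preserving node degrees
#'
#' Produces a degree-preserving random reference network by repeated
#' double-edge swaps; a proposed swap is rejected whenever it would create
#' a self-loop or a duplicate edge, so the result is always simple and
#' every node keeps its degree. Graphs admitting no valid swap (no two
#' edges with four distinct endpoints, e.g. a triangle or a star) are
#' returned unchanged with a warning.
#'
#' @param network Undirected simple `igraph` graph with at least 2 edges.
#' @param n_swaps Number of swap proposals; default `10 * ecount(network)`.
#' @param seed Integer seed.
#' @return A rewired simple `igraph` graph with the same degree sequence.
#' @export
rewire_preserving_degrees <- function(network,
                                      n_swaps = 10L * igraph::ecount(network),
                                      seed = 1L) {
  m <- igraph::ecount(network)
  if (m < 2L) stop2("degree-preserving rewiring needs at least 2 edges")
  el <- igraph::as_edgelist(network, names = TRUE)
  # a valid double-edge swap needs two edges on four distinct nodes
  has_disjoint <- FALSE
  for (i in seq_len(m - 1L)) {
    if (any(!(el[(i + 1L):m, 1] %in% el[i, ]) &
            !(el[(i + 1L):m, 2] %in% el[i, ]))) { has_disjoint <- TRUE; break }
  }
  if (!has_disjoint) {
    warn2("no valid degree-preserving swap exists; returning input unchanged")
    return(network)
  }
  set.seed(seed)
  igraph::rewire(network,
                 igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
}

#' Permute p-values across genes
#'
#' Randomly reassigns the observed p-values over the gene identifiers; the
#' multiset of p-values is exactly preserved, only the gene-to-p map is
#' shuffled. Other columns stay attached to their genes.
#'
#' @param table A `gene_table`.
#' @param seed Integer seed.
#' @return A `gene_table` with permuted `p_value`.
#' @export
permute_scores <- function(table, seed = 1L) {
  if (nrow(table) == 0L) stop2("empty gene table")
  set.seed(seed)
  table$p_value <- table$p_value[sample.int(nrow(table))]
  table
}

#' Empirical module-membership significance by joint permutation
#'
#' Assesses the non-randomness of every gene's presence in the observed
#' MWCS module. For each of `B` null iterations, p-values are permuted
#' across genes AND the network is rewired with preserved node degrees
#' (both, every iteration, on independent substream seeds); node scores
#' are recomputed from the permuted p-values with the observed fit's
#' `(alpha, tau)` — so the score multiset is exactly preserved and only
#' the assignment and topology are randomized — and the MWCS is re-solved.
#' The per-gene null frequency `k/B` estimates how often a gene enters a
#' module by chance; the empirical p-value uses the pseudocounted
#' `(k+1)/(B+1)` estimator and is Bonferroni-adjusted over the observed
#' module size.
#'
#' @param network Undirected `igraph` graph.
#' @param table A `gene_table` of observed p-values.
#' @param B Number of permutations (the reference analysis uses 1000).
#' @param solver `"heuristic"` or `"exact"`.
#' @param seed Master seed; per-iteration substreams are derived from it.
#' @param fit Optional precomputed `bum_fit`; fitted from `table` otherwise.
#' @param tau Score-zero threshold; defaults to the Bonferroni threshold
#'   over the genes in `table`.
#' @param n_swaps Swap proposals per rewiring; default `10 * ecount`.
#' @param refit Refit the mixture to each permuted table instead of reusing
#'   the observed `(alpha, tau)` (slower; changes the score multiset).
#' @param missing_policy Passed to [align_inputs()].
#' @return A `permutation_summary`: per observed-module gene, `score`,
#'   null count `k`, `frequency = k/B`, `empirical_p = (k+1)/(B+1)`,
#'   `adjusted_p = min(1, empirical_p * module size)`, plus the observed
#'   module, `B`, and the seed.
#' @export
null_mwcs_frequencies <- function(network, table, B = 1000L,
                                  solver = c("heuristic", "exact"),
                                  seed = 1L, fit = NULL, tau = NULL,
                                  n_swaps = 10L * igraph::ecount(network),
                                  refit = FALSE,
                                  missing_policy = "drop") {
  solver <- match.arg(solver)
  if (B < 1L) stop2("B must be >= 1")
  if (is.null(fit)) fit <- fit_bum(table$p_value, seed = seed)
  if (is.null(tau)) tau <- bonferroni_threshold(nrow(table))
  solve_fun <- if (solver == "exact") {
    function(g, sc, sd) solve_exact(g, sc)
  } else solve_heuristic

  observed <- {
    sc <- score_nodes(table, fit, tau)
    al <- align_inputs(network, sc, missing_policy)
    suppressWarnings(solve_fun(al$network, al$scores, seed))
  }

  counts <- stats::setNames(integer(nrow(table)), table$gene)
  iter_seeds <- substream_seeds(seed, 2L * B)
  for (b in seq_len(B)) {
    tab_b <- permute_scores(table, seed = iter_seeds[[2L * b - 1L]])
    net_b <- suppressWarnings(
      rewire_preserving_degrees(network, n_swaps, seed = iter_seeds[[2L * b]]))
    fit_b <- if (refit)
      suppressWarnings(fit_bum(tab_b$p_value, seed = iter_seeds[[2L * b]]))
    else fit
    sc_b <- score_nodes(tab_b, fit_b, tau)
    al_b <- suppressWarnings(align_inputs(net_b, sc_b, missing_policy))
    mod_b <- suppressWarnings(solve_fun(al_b$network, al_b$scores,
                                        iter_seeds[[2L * b]]))
    counts[mod_b$members] <- counts[mod_b$members] + 1L
  }

  genes <- observed$members
  k <- counts[genes]
  m <- length(genes)
  structure(
    list(B = as.integer(B),
         gene = genes,
         score = unname(observed$node_scores[genes]),
         null_counts = unname(k),
         frequency = unname(k) / B,
         empirical_p = (unname(k) + 1) / (B + 1),
         adjusted_p = pmin(1, m * (unname(k) + 1) / (B + 1)),
         observed_module = observed,
         seed = seed),
    class = "permutation_summary"
  )
}

#' @export
as.data.frame.permutation_summary <- function(x, ...) {
  data.frame(gene = x$gene, score = x$score, null_count = x$null_counts,
             frequency = x$frequency, empirical_p = x$empirical_p,
             adjusted_p = x$adjusted_p, stringsAsFactors = FALSE)
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("Permutation significance (B = %d) for a %d-gene module\n",
              x$B, length(x$gene)))
  print(utils::head(as.data.frame(x)[order(x$empirical_p), ], 10),
        row.names = FALSE)
  invisible(x)
}

#' Genes with significant module membership
#'
#' @param summary A `permutation_summary`.
#' @param level Significance level on the Bonferroni-adjusted empirical
#'   p-value (default 0.05).
#' @return Character vector of genes with `adjusted_p < level`.
#' @export
flag_significant <- function(summary, level = 0.05) {
  summary$gene[summary$adjusted_p < level]
}
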