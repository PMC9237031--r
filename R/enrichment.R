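#' Bin genes into expression deciles
#'
#' Ranks genes by mean expression (ties broken by gene identifier for
#' determinism) and splits them into `n_bins` near-equal rank bins. Used to
#' draw random gene sets matching the expression profile of a disease gene
#' set: co-expressed genes are better connected than random pairs, so null
#' sets must match the expression distribution of the target set.
#'
#' @param table A `gene_table` with `mean_expression` for every gene.
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @return An `expression_bins` list: `n_bins`, `assignment` (named integer
#'   vector, gene -> bin in `1..n_bins`), and `expression` (named numeric).
#' @export
assign_expression_deciles <- function(table, n_bins = 10L) {
  if (is.null(table$mean_expression) || anyNA(table$mean_expression))
    stop2("mean_expression is required for every gene")
  n <- nrow(table)
  if (n < n_bins) stop2("need at least ", n_bins, " genes to form ", n_bins,
                        " bins")
  ord <- order(table$mean_expression, table$gene, method = "radix")
  ranks <- integer(n); ranks[ord] <- seq_len(n)
  bin <- ceiling(ranks * n_bins / n)
  structure(
    list(n_bins = as.integer(n_bins),
         assignment = stats::setNames(as.integer(bin), table$gene),
         expression = stats::setNames(table$mean_expression, table$gene)),
    class = "expression_bins"
  )
}

#' Sample expression-matched random gene sets
#'
#' Draws `n_sets` random gene sets matched to a target set's expression
#' profile, without replacement, from `universe` minus the target.
#' `"decile"` matching reproduces the target's per-bin counts exactly;
#' `"pct10"` replaces each target gene by a random gene whose mean
#' expression lies within ±10% of it.
#'
#' @param bins An `expression_bins` from [assign_expression_deciles()]
#'   (its `expression` field drives `pct10` matching).
#' @param target_set Character vector of target genes; members outside
#'   `universe` or without expression are dropped with a warning.
#' @param universe Character vector of candidate genes (must be binned).
#' @param strategy `"decile"` or `"pct10"`.
#' @param n_sets Number of random sets.
#' @param seed Integer seed.
#' @return A list of `n_sets` character vectors, each of the (restricted)
#'   target size.
#' @export
sample_matched_set <- function(bins, target_set, universe,
                               strategy = c("decile", "pct10"),
                               n_sets = 1L, seed = 1L) {
  strategy <- match.arg(strategy)
  known <- names(bins$assignment)
  universe <- intersect(universe, known)
  target0 <- unique(target_set)
  target <- intersect(target0, universe)
  if (length(target) < length(target0))
    warn2(length(target0) - length(target),
          " target gene(s) outside the expression universe dropped")
  if (length(target) == 0L) stop2("no target genes left after restriction")
  pool_all <- setdiff(universe, target)
  set.seed(seed)

  if (strategy == "decile") {
    tbin <- bins$assignment[target]
    need <- table(tbin)
    pool_by_bin <- split(pool_all, bins$assignment[pool_all])
    for (b in names(need)) {
      if (length(pool_by_bin[[b]] %||% character(0)) < need[[b]])
        stop2("bin ", b, ": ", need[[b]], " genes needed but only ",
              length(pool_by_bin[[b]] %||% character(0)), " candidates")
    }
    lapply(seq_len(n_sets), function(i) {
      picks <- unlist(lapply(names(need), function(b)
        sample(pool_by_bin[[b]], need[[b]])), use.names = FALSE)
      sort_genes(picks)
    })
  } else {
    expr <- bins$expression
    windows <- lapply(target, function(g) {
      e <- expr[[g]]
      cand <- pool_all[expr[pool_all] >= 0.9 * e & expr[pool_all] <= 1.1 * e]
      if (length(cand) == 0L)
        stop2("no candidate within ±10% expression of gene '", g, "'")
      cand
    })
    lapply(seq_len(n_sets), function(i) {
      chosen <- character(0)
      # target genes in ascending candidate-count order so tight windows
      # draw first; sampling is without replacement within a set
      ord <- order(lengths(windows))
      for (j in ord) {
        cand <- setdiff(windows[[j]], chosen)
        if (length(cand) == 0L)
          stop2("±10% window exhausted for gene '", target[[j]], "'")
        chosen <- c(chosen, if (length(cand) == 1L) cand else sample(cand, 1L))
      }
      sort_genes(chosen)
    })
  }
}

#' Cross-connectivity statistic between two gene sets
#'
#' The proportion of all connections involving either set that link the two
#' sets: the number of network edges with one endpoint in `set_a` and the
#' other in `set_b`, divided by the number of edges with at least one
#' endpoint in their union. Genes present in both sets are removed from
#' `set_b` with a warning (a gene cannot link the sets to themselves).
#'
#' @param network Undirected `igraph` graph.
#' @param set_a,set_b Character vectors of gene identifiers; silently
#'   restricted to network nodes.
#' @param denominator `"incident"` (edges touching the union; default) or
#'   `"within"` (edges with both endpoints inside the union).
#' @return A proportion in `[0, 1]`; 0 with a warning when no edge touches
#'   either set.
#' @export
connectivity_statistic <- function(network, set_a, set_b,
                                   denominator = c("incident", "within")) {
  denominator <- match.arg(denominator)
  vn <- igraph::V(network)$name
  a <- intersect(set_a, vn)
  b <- intersect(set_b, vn)
  both <- intersect(a, b)
  if (length(both) > 0L) {
    warn2(length(both), " gene(s) in both sets removed from the second set")
    b <- setdiff(b, both)
  }
  if (length(a) == 0L && length(b) == 0L)
    stop2("both sets are empty after restriction to the network")
  el <- igraph::as_edgelist(network, names = TRUE)
  in_a1 <- el[, 1] %in% a; in_a2 <- el[, 2] %in% a
  in_b1 <- el[, 1] %in% b; in_b2 <- el[, 2] %in% b
  cross <- sum((in_a1 & in_b2) | (in_a2 & in_b1))
  denom <- if (denominator == "incident") {
    sum(in_a1 | in_a2 | in_b1 | in_b2)
  } else {
    sum((in_a1 | in_b1) & (in_a2 | in_b2))
  }
  if (denom == 0L) {
    warn2("no edge touches either set; statistic set to 0")
    return(0)
  }
  cross / denom
}

#' Connectivity enrichment against expression-matched nulls
#'
#' Tests whether disease genes are more connected to differentially
#' expressed genes than expected: for each disease set, the observed
#' cross-connectivity proportion is compared with `B` random gene sets of
#' the same size matched to the disease set's expression profile (the DE
#' set stays fixed). Empirical p-values use the one-sided pseudocounted
#' estimator `(1 + #[null >= observed]) / (B + 1)` and are
#' Bonferroni-adjusted over the number of disease sets tested.
#'
#' @param network Undirected `igraph` graph.
#' @param disease_sets A `gene_sets` collection (or named list).
#' @param de_set Character vector of differentially expressed genes
#'   (upstream, e.g. FDR < 5%).
#' @param table `gene_table` with `mean_expression` (the matching universe).
#' @param B Number of matched random sets (default 1000).
#' @param matching `"decile"` or `"pct10"`.
#' @param seed Integer seed.
#' @param denominator Passed to [connectivity_statistic()].
#' @return A list of `connectivity_enrichment` objects, one per disease
#'   set: `disease_set_name`, `observed_stat`, `null_stats`, `empirical_p`,
#'   `adjusted_p`, `matching`, `B`, `seed`.
#' @export
connectivity_enrichment <- function(network, disease_sets, de_set, table,
                                    B = 1000L,
                                    matching = c("decile", "pct10"),
                                    seed = 1L,
                                    denominator = "incident") {
  matching <- match.arg(matching)
  bins <- assign_expression_deciles(table)
  universe <- table$gene
  set_seeds <- substream_seeds(seed, length(disease_sets))
  n_sets_tested <- length(disease_sets)
  out <- vector("list", n_sets_tested)
  for (i in seq_along(disease_sets)) {
    name <- names(disease_sets)[[i]]
    disease <- disease_sets[[i]]
    # genes in both sets count as disease genes only (no self-linking)
    de_use <- setdiff(de_set, disease)
    observed <- suppressWarnings(
      connectivity_statistic(network, disease, de_use, denominator))
    nulls <- sample_matched_set(bins, disease, universe,
                                strategy = matching, n_sets = B,
                                seed = set_seeds[[i]])
    null_stats <- vapply(nulls, function(rs)
      suppressWarnings(connectivity_statistic(network, rs,
                                              setdiff(de_set, rs),
                                              denominator)),
      numeric(1))
    emp <- (1 + sum(null_stats >= observed)) / (B + 1)
    out[[i]] <- structure(
      list(disease_set_name = name,
           observed_stat = observed,
           null_stats = null_stats,
           empirical_p = emp,
           adjusted_p = min(1, emp * n_sets_tested),
           matching = matching, B = as.integer(B), seed = seed),
      class = "connectivity_enrichment"
    )
  }
  names(out) <- names(disease_sets)
  out
}

#' @export
print.connectivity_enrichment <- function(x, ...) {
  cat(sprintf(
    "Connectivity enrichment '%s': observed %.4f vs null mean %.4f (B = %d)\n",
    x$disease_set_name, x$observed_stat, mean(x$null_stats), x$B))
  cat(sprintf("  empirical p = %.4g, Bonferroni-adjusted p = %.4g (%s matching)\n",
              x$empirical_p, x$adjusted_p, x$matching))
  invisible(x)
}

#' Overlap of two gene sets in a universe
#'
#' Classical gene-set overlap tests: the hypergeometric upper-tail p-value
#' of the observed overlap, a binomial upper-tail p-value with success
#' probability `|reference| / |universe|`, and the odds ratio of the 2x2
#' table (Haldane 0.5 correction when any cell is empty).
#'
#' @param query_set,reference_set Character vectors; restricted to
#'   `universe`.
#' @param universe Character vector of background genes.
#' @param binom_prob Optional success probability for the binomial test;
#'   defaults to `|reference| / |universe|`.
#' @return A list: `overlap_count`, `odds_ratio`, `hypergeom_p`,
#'   `binomial_p`, and the restricted sizes `n_query`, `n_reference`,
#'   `n_universe`.
#' @export
overlap_test <- function(query_set, reference_set, universe,
                         binom_prob = NULL) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop2("empty universe")
  q <- intersect(unique(query_set), universe)
  r <- intersect(unique(reference_set), universe)
  k <- length(intersect(q, r))
  N <- length(universe); K <- length(r); n <- length(q)
  hyper_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p0 <- binom_prob %||% (K / N)
  binom_p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  # 2x2: overlap / query-only / reference-only / neither
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                              c <- c + 0.5; d <- d + 0.5 }
  list(overlap_count = k,
       odds_ratio = (a * d) / (b * c),
       hypergeom_p = hyper_p,
       binomial_p = binom_p,
       n_query = n, n_reference = K, n_universe = N)
}
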