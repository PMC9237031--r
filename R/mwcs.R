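#' Align a network and node scores for module search
#'
#' The reference interaction network and the scored gene table rarely cover
#' the same identifiers. `drop` restricts the search graph to nodes that
#' carry a score; `impute_zero` keeps unscored network nodes with score 0
#' (and a warning). Genes scored but absent from the network are reported
#' and excluded from the search.
#'
#' @param network Undirected `igraph` graph.
#' @param scores A `node_scores` object.
#' @param missing_policy `"drop"` or `"impute_zero"`.
#' @return A list with `network` (the search graph), `scores` (a
#'   `node_scores` restricted/extended to its nodes), and
#'   `network_absent`, the genes with scores but no network node.
#' @export
align_inputs <- function(network, scores,
                         missing_policy = c("drop", "impute_zero")) {
  missing_policy <- match.arg(missing_policy)
  vn <- igraph::V(network)$name
  scored <- names(scores$scores)
  absent <- setdiff(scored, vn)
  if (missing_policy == "drop") {
    keep <- intersect(vn, scored)
    if (length(keep) == 0L)
      stop2("no overlap between network nodes and scored genes")
    g <- igraph::induced_subgraph(network, keep)
    s <- scores$scores[igraph::V(g)$name]
  } else {
    unscored <- setdiff(vn, scored)
    if (length(intersect(vn, scored)) == 0L)
      stop2("no overlap between network nodes and scored genes")
    if (length(unscored) > 0L)
      warn2(length(unscored), " network node(s) without scores imputed to 0")
    g <- network
    s <- stats::setNames(rep(0, length(vn)), vn)
    s[intersect(vn, scored)] <- scores$scores[intersect(vn, scored)]
  }
  list(
    network = g,
    scores = structure(list(tau = scores$tau, alpha_used = scores$alpha_used,
                            scores = s),
                       class = "node_scores"),
    network_absent = absent
  )
}

new_module_result <- function(members, node_scores, solver) {
  members <- sort_genes(members)
  structure(
    list(members = members,
         total_score = sum(node_scores[members]),
         solver = solver,
         node_scores = node_scores[members],
         n_positive_members = sum(node_scores[members] > 0)),
    class = "mwcs_module"
  )
}

#' @export
print.mwcs_module <- function(x, ...) {
  cat(sprintf("MWCS module (%s solver): %d genes, %d positive, total score %.4f\n",
              x$solver, length(x$members), x$n_positive_members, x$total_score))
  show <- utils::head(x$members, 10)
  cat("  ", paste(show, collapse = ", "),
      if (length(x$members) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# candidate comparison: higher score, then fewer nodes, then lexicographic
better_candidate <- function(score, members, best_score, best_members,
                             tol = 1e-12) {
  if (is.null(best_members)) return(TRUE)
  if (score > best_score + tol) return(TRUE)
  if (score < best_score - tol) return(FALSE)
  if (length(members) < length(best_members)) return(TRUE)
  if (length(members) > length(best_members)) return(FALSE)
  lex_lt(members, best_members)
}

#' Exact most-weighted connected subgraph
#'
#' Exhaustively enumerates every connected induced node subset of a
#' node-weighted graph (connectivity-aware recursion over extension sets,
#' with a positive-score upper bound for pruning) and returns the one with
#' the largest total score. Ties are broken by fewer nodes, then by the
#' lexicographically smallest sorted member list, so the output is stable.
#' Intended for small graphs and as the reference oracle for the heuristic;
#' larger graphs should use [solve_heuristic()].
#'
#' @param network Undirected `igraph` graph whose vertex names are genes.
#' @param scores A `node_scores` object covering every network node.
#' @param max_nodes Refuse graphs larger than this (enumeration is
#'   exponential); default 20.
#' @return A `mwcs_module` with `solver = "exact"`.
#' @export
solve_exact <- function(network, scores, max_nodes = 20L) {
  vn <- igraph::V(network)$name
  n <- length(vn)
  if (n == 0L) stop2("empty graph")
  if (n > max_nodes)
    stop2("graph has ", n, " nodes (> max_nodes = ", max_nodes,
          "); use solve_heuristic()")
  s <- scores$scores[vn]
  if (anyNA(s)) stop2("every network node needs a score (see align_inputs)")

  if (n > 30L) stop2("exact enumeration supports at most 30 nodes")

  # order vertices by name for deterministic, locale-free enumeration
  ord <- order(vn, method = "radix")
  vn <- vn[ord]; s <- as.numeric(s[ord])
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE) > 0
  adj <- adj[vn, vn, drop = FALSE]

  bit <- bitwShiftL(1L, 0:(n - 1L))
  nbr_mask <- integer(n)
  for (i in seq_len(n))
    nbr_mask[i] <- Reduce(bitwOr, bit[adj[i, ]], 0L)
  bits_of <- function(mask) which(bitwAnd(bit, mask) != 0L)

  best <- new.env(parent = emptyenv())
  best$score <- -Inf; best$members <- NULL

  consider <- function(set_idx, score) {
    members <- vn[set_idx]
    if (better_candidate(score, members, best$score, best$members)) {
      best$score <- score; best$members <- members
    }
  }

  pos <- pmax(s, 0)

  # enumerate all connected subsets whose minimum-index vertex is v, by
  # recursive extension: branching on candidate u bans it from the sibling
  # branches, so each connected subset is visited exactly once; branches
  # are pruned when current score plus every still-allowed positive score
  # cannot beat the incumbent (ties kept for deterministic tie-breaking)
  recurse <- function(set_idx, score, ext_idx, banned_mask) {
    consider(set_idx, score)
    while (length(ext_idx) > 0L) {
      u <- ext_idx[[1L]]
      ext_idx <- ext_idx[-1L]
      new_banned <- bitwOr(banned_mask, bit[u])
      reach <- bitwAnd(nbr_mask[u], bitwNot(new_banned))
      new_ext <- ext_idx
      if (reach != 0L) new_ext <- union(new_ext, bits_of(reach))
      allowed <- setdiff(seq_len(n), c(bits_of(new_banned), set_idx))
      ub <- score + s[u] + sum(pos[allowed])
      if (ub >= best$score - 1e-12) {
        recurse(c(set_idx, u), score + s[u], new_ext, new_banned)
      }
      banned_mask <- new_banned
    }
  }

  for (v in seq_len(n)) {
    banned <- Reduce(bitwOr, bit[seq_len(v)], 0L)  # {1..v-1} forbidden, v in set
    ext <- bits_of(bitwAnd(nbr_mask[v], bitwNot(banned)))
    recurse(v, s[v], ext, banned)
  }

  if (best$score <= 0)
    warn2("optimal module has non-positive total score (weak signal)")
  new_module_result(best$members, scores$scores, "exact")
}

#' Heuristic most-weighted connected subgraph
#'
#' A scalable prize-collecting heuristic: (1) connected components of
#' positive-score nodes are contracted to super-nodes weighted by their
#' score sum; (2) a Steiner-like tree over super-nodes is grown greedily,
#' connecting the next super-node through its cheapest node-weighted path
#' (path cost = minus the sum of non-positive interior scores) whenever the
#' super-node weight exceeds that cost; (3) the tree is expanded back to
#' original nodes, absorbing any positive component a path runs through;
#' (4) leaves with score <= 0 are pruned to a fixpoint. On a disconnected
#' graph each component is searched and the best module returned. If no
#' node scores positive, the single highest-scoring node is returned with a
#' warning. The result never retains a prunable non-positive leaf and never
#' scores below the best single node.
#'
#' @param network Undirected `igraph` graph.
#' @param scores A `node_scores` covering every network node.
#' @param seed Integer seed (the pipeline is deterministic; the seed is
#'   consumed only to fix any internal tie sampling and is kept in the
#'   interface for reproducibility contracts).
#' @return A `mwcs_module` with `solver = "heuristic"`.
#' @export
solve_heuristic <- function(network, scores, seed = 1L) {
  vn <- igraph::V(network)$name
  if (length(vn) == 0L) stop2("empty graph")
  s <- scores$scores[vn]
  if (anyNA(s)) stop2("every network node needs a score (see align_inputs)")
  s <- stats::setNames(as.numeric(s), vn)

  pos_nodes <- vn[s > 0]
  if (length(pos_nodes) == 0L) {
    warn2("no positively scoring node; returning the single best node")
    top <- vn[order(-s, vn, method = "radix")][1L]
    return(new_module_result(top, s, "heuristic"))
  }

  # positive components = super-nodes
  gpos <- igraph::induced_subgraph(network, pos_nodes)
  comp <- igraph::components(gpos)
  super <- split(igraph::V(gpos)$name, comp$membership)
  super <- lapply(super, sort_genes)
  sweights <- vapply(super, function(m) sum(s[m]), numeric(1))
  # deterministic order: weight desc, then lexicographic first member
  sord <- order(-sweights, vapply(super, `[[`, character(1), 1L),
                method = "radix")
  super <- super[sord]; sweights <- sweights[sord]
  scomp_of <- stats::setNames(rep(seq_along(super), lengths(super)),
                              unlist(super))

  # node-cost shortest paths: directed arcs weighted by the head's cost,
  # so dist(u -> v) sums the costs of every path node after u
  cost <- pmax(-s, 0)  # argument order keeps names
  gdir <- igraph::as_directed(network, mode = "mutual")
  heads <- igraph::ends(gdir, igraph::E(gdir), names = TRUE)[, 2]

  grow_from <- function(start_comp) {
    tree <- super[[start_comp]]
    used <- start_comp
    repeat {
      remaining <- setdiff(seq_along(super), used)
      # drop super-nodes already absorbed via a path
      absorbed <- remaining[vapply(remaining, function(k)
        all(super[[k]] %in% tree), logical(1))]
      used <- c(used, absorbed)
      remaining <- setdiff(remaining, absorbed)
      if (length(remaining) == 0L) break
      cost_dyn <- cost
      cost_dyn[tree] <- 0  # already-paid tree nodes are free to route through
      igraph::E(gdir)$weight <- cost_dyn[heads]
      d <- igraph::distances(gdir, v = tree, to = vn, mode = "out")
      dmin <- apply(d, 2, min)
      names(dmin) <- vn
      gains <- vapply(remaining, function(k)
        sweights[[k]] - min(dmin[super[[k]]]), numeric(1))
      if (max(gains) <= 0) break
      k <- remaining[order(-gains,
                           vapply(super[remaining], `[[`, character(1), 1L),
                           method = "radix")][1L]
      target_opts <- super[[k]]
      target <- target_opts[order(dmin[target_opts], target_opts,
                                  method = "radix")][1L]
      src <- tree[order(d[, target], tree, method = "radix")][1L]
      path <- igraph::shortest_paths(gdir, from = src, to = target,
                                     mode = "out", weights = NULL,
                                     output = "vpath")$vpath[[1L]]
      path_names <- igraph::V(gdir)$name[as.integer(path)]
      tree <- unique(c(tree, path_names, super[[k]]))
      # absorb every positive component the path touched
      touched <- unique(stats::na.omit(scomp_of[path_names]))
      used <- unique(c(used, k, touched))
      for (t in touched) tree <- unique(c(tree, super[[t]]))
    }
    tree
  }

  prune <- function(members) {
    repeat {
      if (length(members) <= 1L) break
      g <- igraph::induced_subgraph(network, members)
      deg <- igraph::degree(g)
      drop <- igraph::V(g)$name[deg <= 1 & s[igraph::V(g)$name] <= 0]
      if (length(drop) == 0L) break
      members <- setdiff(members, drop)
    }
    members
  }

  # one growth per connected component holding at least one super-node
  comp_all <- igraph::components(network)
  comp_of_node <- stats::setNames(comp_all$membership, vn)
  start_comps <- vapply(super, function(m) comp_of_node[[m[[1L]]]], numeric(1))
  best_members <- NULL; best_score <- -Inf
  for (gc in unique(start_comps)) {
    seeds_here <- which(start_comps == gc)
    tree <- grow_from(seeds_here[[1L]])  # heaviest super-node in component
    tree <- prune(tree)
    sc <- sum(s[tree])
    if (better_candidate(sc, sort_genes(tree), best_score, best_members)) {
      best_score <- sc; best_members <- sort_genes(tree)
    }
  }

  # never worse than the single best node
  top <- vn[order(-s, vn, method = "radix")][1L]
  if (s[[top]] > best_score + 1e-12) {
    best_members <- top
  }
  new_module_result(best_members, s, "heuristic")
}

#' Summarize a module against the network and optional gene sets
#'
#' @param result A `mwcs_module`.
#' @param network The search network the module came from.
#' @param gene_sets Optional `gene_sets`; membership counts of the module
#'   in each set are reported.
#' @return A list with `n_members`, `n_positive`, `total_score`, `solver`,
#'   and `set_overlap`, a named integer vector of per-set member counts.
#' @export
module_report <- function(result, network, gene_sets = NULL) {
  overlap <- integer(0)
  if (!is.null(gene_sets)) {
    overlap <- vapply(gene_sets, function(set)
      length(intersect(result$members, set)), integer(1))
  }
  list(
    n_members = length(result$members),
    n_positive = result$n_positive_members,
    total_score = result$total_score,
    solver = result$solver,
    set_overlap = overlap
  )
}
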