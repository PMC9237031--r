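# Independent brute-force MWCS oracle: enumerate every non-empty node
# subset as a bitmask and flood-fill connectivity over precomputed
# neighbor masks. Deliberately shares no code with solve_exact().
naive_mwcs <- function(network, scores) {
  vn <- sort(igraph::V(network)$name, method = "radix")
  n <- length(vn)
  stopifnot(n <= 20)
  s <- as.numeric(scores[vn])
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE) > 0
  adj <- adj[vn, vn, drop = FALSE]
  bit <- bitwShiftL(1L, 0:(n - 1L))
  nbr <- vapply(seq_len(n), function(i)
    Reduce(bitwOr, bit[adj[i, ]], 0L), integer(1))

  connected <- function(mask) {
    lowest <- bitwAnd(mask, -mask)
    reach <- lowest
    repeat {
      grow <- reach
      for (i in seq_len(n)) {
        if (bitwAnd(reach, bit[i]) != 0L)
          grow <- bitwOr(grow, bitwAnd(nbr[i], mask))
      }
      if (grow == reach) break
      reach <- grow
    }
    reach == mask
  }

  best_score <- -Inf; best_members <- NULL
  for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
    if (!connected(mask)) next
    idx <- which(bitwAnd(bit, mask) != 0L)
    sc <- sum(s[idx])
    memb <- vn[idx]
    if (sc > best_score + 1e-12 ||
        (abs(sc - best_score) <= 1e-12 &&
         (length(memb) < length(best_members) ||
          (length(memb) == length(best_members) &&
           paste(memb, collapse = "\r") <
           paste(best_members, collapse = "\r"))))) {
      best_score <- sc; best_members <- memb
    }
  }
  list(members = best_members, total_score = best_score)
}

# shorthand constructors used across tests
make_scores <- function(scores, tau = 0.05, alpha = 0.5) {
  structure(list(tau = tau, alpha_used = alpha, scores = scores),
            class = "node_scores")
}

random_scored_instance <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  s <- stats::setNames(stats::rnorm(n), igraph::V(g)$name)
  list(network = g, scores = make_scores(s))
}

path_graph <- function(scores) {
  nm <- names(scores)
  list(network = mwcsnet::network_from_edges(nm[-length(nm)], nm[-1]),
       scores = make_scores(scores))
}
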