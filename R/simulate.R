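#' Generate a synthetic interaction network
#'
#' Random simple undirected graphs for testing: Erdős–Rényi G(n, p),
#' preferential attachment (scale-free, like real interactomes), or a
#' configuration-model graph realizing a supplied degree sequence without
#' self-loops or multi-edges.
#'
#' @param n_nodes Number of nodes (>= 3); nodes are named `G0001`, ...
#' @param model `"erdos_renyi"`, `"preferential_attachment"`, or
#'   `"configuration"`.
#' @param p Edge probability (Erdős–Rényi).
#' @param m Edges added per new node (preferential attachment).
#' @param degrees Integer degree sequence (configuration model).
#' @param seed Integer seed.
#' @return A simple undirected `igraph` graph with named vertices.
#' @export
generate_network <- function(n_nodes,
                             model = c("erdos_renyi",
                                       "preferential_attachment",
                                       "configuration"),
                             p = 0.1, m = 2L, degrees = NULL, seed = 1L) {
  model <- match.arg(model)
  if (n_nodes < 3L) stop2("n_nodes must be >= 3")
  set.seed(seed)
  g <- switch(model,
    erdos_renyi = igraph::sample_gnp(n_nodes, p),
    preferential_attachment =
      igraph::as_undirected(igraph::sample_pa(n_nodes, m = m)),
    configuration = {
      if (is.null(degrees)) stop2("configuration model needs 'degrees'")
      if (length(degrees) != n_nodes)
        stop2("degree sequence length must equal n_nodes")
      tryCatch(
        igraph::sample_degseq(degrees, method = "vl"),
        error = function(e)
          tryCatch(igraph::sample_degseq(degrees, method = "fast.heur.simple"),
                   error = function(e2)
                     stop2("infeasible degree sequence: ",
                           conditionMessage(e2)))
      )
    })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  g
}

#' Plant a connected module in a network
#'
#' Grows a random connected subgraph of the requested size by a random walk
#' with restart over the already-selected frontier, starting from a random
#' node of a sufficiently large connected component.
#'
#' @param network Undirected `igraph` graph.
#' @param module_size Requested module size.
#' @param seed Integer seed.
#' @return Character vector of member genes inducing a connected subgraph.
#' @export
plant_module <- function(network, module_size, seed = 1L) {
  comp <- igraph::components(network)
  big <- which(comp$csize >= module_size)
  if (length(big) == 0L)
    stop2("no connected component of size >= ", module_size)
  set.seed(seed)
  cid <- big[[sample.int(length(big), 1L)]]
  nodes <- igraph::V(network)$name[comp$membership == cid]
  start <- sample(nodes, 1L)
  members <- start
  frontier <- setdiff(igraph::neighbors(network, start)$name, members)
  while (length(members) < module_size) {
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    members <- c(members, nxt)
    frontier <- setdiff(
      unique(c(frontier, igraph::neighbors(network, nxt)$name)), members)
  }
  sort_genes(members)
}

#' Generate p-values with a planted signal module
#'
#' Planted genes draw p-values from the Beta(`alpha_signal`, 1) signal law
#' (density `alpha * x^(alpha - 1)`, stochastically small); every other
#' gene draws from Uniform(0, 1) — a sharp-null mixture, so module-recovery
#' truth is unambiguous. Mean expression is drawn log-normal, independent
#' of the p-values.
#'
#' @param network Undirected `igraph` graph supplying the gene universe.
#' @param planted Character vector of signal genes (subset of the network).
#' @param alpha_signal Beta shape in (0, 1); smaller = stronger signal.
#' @param seed Integer seed.
#' @param expr_meanlog,expr_sdlog Log-normal parameters for mean
#'   expression (defaults emulate normalized count scales: median ~150,
#'   long right tail).
#' @return A `gene_table` with `p_value` and `mean_expression`.
#' @export
generate_pvalues <- function(network, planted, alpha_signal = 0.1, seed = 1L,
                             expr_meanlog = 5, expr_sdlog = 1.5) {
  if (alpha_signal <= 0 || alpha_signal >= 1)
    stop2("alpha_signal must lie in (0, 1)")
  genes <- igraph::V(network)$name
  if (!all(planted %in% genes)) stop2("planted genes must be network nodes")
  set.seed(seed)
  p <- stats::runif(length(genes))
  is_sig <- genes %in% planted
  p[is_sig] <- stats::runif(sum(is_sig))^(1 / alpha_signal)
  p <- pmax(p, .Machine$double.xmin)
  expr <- stats::rlnorm(length(genes), meanlog = expr_meanlog,
                        sdlog = expr_sdlog)
  gene_table(gene = genes, p_value = p, mean_expression = expr)
}

#' Add cross-edges between two gene sets
#'
#' Adds exactly `extra_edges` new simple edges between randomly chosen
#' (disease, DE) gene pairs that are not already adjacent; used to plant a
#' known connectivity-enrichment signal.
#'
#' @param network Undirected `igraph` graph.
#' @param disease_set,de_set Character vectors of node names.
#' @param extra_edges Number of new cross-edges to add.
#' @param seed Integer seed.
#' @return The augmented `igraph` graph.
#' @export
plant_cross_connectivity <- function(network, disease_set, de_set,
                                     extra_edges, seed = 1L) {
  if (extra_edges == 0L) return(network)
  a <- setdiff(intersect(disease_set, igraph::V(network)$name), de_set)
  b <- intersect(de_set, igraph::V(network)$name)
  pairs <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  open <- !mapply(function(x, y) adj[x, y] > 0, pairs$a, pairs$b)
  pairs <- pairs[open, , drop = FALSE]
  if (nrow(pairs) < extra_edges)
    stop2("only ", nrow(pairs), " non-adjacent cross pairs available; ",
          extra_edges, " requested")
  set.seed(seed)
  pick <- pairs[sample.int(nrow(pairs), extra_edges), , drop = FALSE]
  igraph::add_edges(network, as.vector(rbind(pick$a, pick$b)))
}

#' Generate a complete synthetic study instance
#'
#' Bundles a network, a planted connected module with beta-distributed
#' p-values, mean expression, and (optionally) a disease gene set with a
#' planted cross-connectivity excess to the top differentially expressed
#' genes — everything the module-detection and enrichment analyses consume,
#' with known ground truth.
#'
#' @param n_nodes Network size (default 500).
#' @param model Network model (default `"preferential_attachment"`).
#' @param m Preferential-attachment edges per node (default 3).
#' @param p Erdős–Rényi edge probability (used for that model).
#' @param module_size Planted module size (default 20).
#' @param alpha_signal Signal Beta shape (default 0.1).
#' @param disease_size Disease-set size (0 = none; default 0).
#' @param cross_edge_excess Extra planted disease-DE edges (default 0).
#' @param de_top Size of the "differentially expressed" set taken as the
#'   genes with the smallest p-values (default 40).
#' @param seed Integer seed.
#' @return A `synthetic_instance` list: `network`, `planted_module`,
#'   `table`, `de_set`, `disease_set` (or NULL), and `truth` (generating
#'   parameters).
#' @export
simulate_instance <- function(n_nodes = 500L,
                              model = "preferential_attachment",
                              m = 3L, p = 0.02,
                              module_size = 20L, alpha_signal = 0.1,
                              disease_size = 0L, cross_edge_excess = 0L,
                              de_top = 40L, seed = 1L) {
  seeds <- substream_seeds(seed, 5L)
  net <- generate_network(n_nodes, model, p = p, m = m, seed = seeds[[1L]])
  planted <- plant_module(net, module_size, seed = seeds[[2L]])
  tab <- generate_pvalues(net, planted, alpha_signal, seed = seeds[[3L]])
  de_set <- tab$gene[order(tab$p_value, tab$gene,
                           method = "radix")][seq_len(de_top)]
  disease_set <- NULL
  if (disease_size > 0L) {
    set.seed(seeds[[4L]])
    disease_set <- sort_genes(sample(setdiff(tab$gene, de_set), disease_size))
    if (cross_edge_excess > 0L)
      net <- plant_cross_connectivity(net, disease_set, de_set,
                                      cross_edge_excess, seed = seeds[[5L]])
  }
  structure(
    list(network = net, planted_module = planted, table = tab,
         de_set = de_set, disease_set = disease_set,
         truth = list(alpha_signal = alpha_signal,
                      module_size = module_size,
                      cross_edge_excess = cross_edge_excess,
                      model = model, n_nodes = n_nodes),
         seed = seed),
    class = "synthetic_instance"
  )
}
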