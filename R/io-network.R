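#' Read an undirected interaction network
#'
#' Loads a protein-protein interaction network from a plain-text edge list
#' or a SIF (simple interaction format) file and returns a simple undirected
#' [igraph::igraph] graph. Edge direction in the input is ignored, reversed
#' duplicates (`A B` and `B A`) are collapsed, and self-loops are dropped;
#' both removals are counted in the attached load report.
#'
#' @param path Path to the network file.
#' @param format `"edge_list"` (two or three whitespace/tab-separated
#'   columns; a third column, e.g. an interaction confidence, is parsed but
#'   ignored) or `"sif"` (`nodeA<TAB>relation<TAB>nodeB [nodeC ...]`).
#' @return A simple undirected `igraph` graph with a `load_report` graph
#'   attribute: a list with `n_duplicates` and `n_self_loops` removed.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "C C", "A C"), f)
#' net <- read_network(f)
#' igraph::ecount(net)  # 2: A-B and A-C survive
#' @export
read_network <- function(path, format = c("edge_list", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop2("empty network file: ", path)

  from <- character(0); to <- character(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1]]
    if (format == "edge_list") {
      if (length(fields) < 2L)
        stop2(sprintf("malformed edge list line %d in %s (need >= 2 columns)",
                      i, path))
      from <- c(from, fields[[1]]); to <- c(to, fields[[2]])
    } else {
      if (length(fields) == 1L)
        stop2(sprintf("malformed SIF line %d in %s (isolated node entries not supported)",
                      i, path))
      if (length(fields) < 3L)
        stop2(sprintf("malformed SIF line %d in %s (need node, relation, node)",
                      i, path))
      targets <- fields[3:length(fields)]
      from <- c(from, rep(fields[[1]], length(targets)))
      to <- c(to, targets)
    }
  }
  network_from_edges(from, to)
}

#' Build a network from edge endpoint vectors
#'
#' @param from,to Character vectors of equal length naming edge endpoints.
#' @param nodes Optional additional (possibly isolated) node names.
#' @return A simple undirected `igraph` graph with a `load_report` attribute.
#' @export
network_from_edges <- function(from, to, nodes = NULL) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  vnames <- sort_genes(c(from, to, nodes))
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "load_report",
                              list(n_duplicates = n_dup, n_self_loops = n_self))
  g
}

#' Write a network as a tab-separated edge list
#'
#' @param network An undirected `igraph` graph.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Report of edges dropped while loading a network
#'
#' @param network A graph returned by [read_network()] or
#'   [network_from_edges()].
#' @return A list with `n_duplicates` and `n_self_loops`.
#' @export
load_report <- function(network) {
  igraph::graph_attr(network, "load_report") %||%
    list(n_duplicates = NA_integer_, n_self_loops = NA_integer_)
}
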