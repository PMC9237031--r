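#' Write analysis results to disk
#'
#' Serializes a module, permutation summary, or connectivity-enrichment
#' result. `tsv` writes the per-gene node table (gene, score, and, when
#' available, null count, frequency, empirical and adjusted p); `json`
#' writes the full result; `graphml` (modules only) writes the induced
#' subgraph with a `score` vertex attribute.
#'
#' @param result A `mwcs_module`, `permutation_summary`, or
#'   `connectivity_enrichment` object.
#' @param path Output path.
#' @param format One of `"tsv"`, `"json"`, `"graphml"`.
#' @param network Required for `graphml`: the network the module lives on.
#' @export
write_results <- function(result, path, format = c("tsv", "json", "graphml"),
                          network = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    if (!inherits(result, "mwcs_module"))
      stop2("graphml export is defined for modules only")
    if (is.null(network)) stop2("graphml export needs the network")
    g <- igraph::induced_subgraph(network, result$members)
    igraph::V(g)$score <- unname(result$node_scores[igraph::V(g)$name])
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  tab <- result_table(result)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- unclass(result)
    if (!is.null(payload$observed_module))
      payload$observed_module <- unclass(payload$observed_module)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

result_table <- function(result) {
  if (inherits(result, "mwcs_module")) {
    data.frame(gene = result$members,
               score = unname(result$node_scores[result$members]),
               stringsAsFactors = FALSE)
  } else if (inherits(result, "permutation_summary")) {
    as.data.frame(result)
  } else if (inherits(result, "connectivity_enrichment")) {
    data.frame(disease_set = result$disease_set_name,
               observed_stat = result$observed_stat,
               empirical_p = result$empirical_p,
               adjusted_p = result$adjusted_p,
               B = result$B,
               matching = result$matching,
               stringsAsFactors = FALSE)
  } else stop2("unsupported result type: ", paste(class(result), collapse = "/"))
}

#' Write a JSON run manifest
#'
#' Records the resolved parameters, master seed, package version, and MD5
#' digests of the input files, so a run can be reproduced exactly.
#'
#' @param path Output path for the JSON manifest.
#' @param seed Master seed of the run.
#' @param params Named list of resolved parameters.
#' @param inputs Character vector of input file paths to digest.
#' @export
write_manifest <- function(path, seed, params = list(), inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "mwcsnet",
    version = as.character(utils::packageVersion("mwcsnet")),
    seed = seed,
    params = params,
    input_md5 = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
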