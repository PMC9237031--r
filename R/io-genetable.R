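#' Read a per-gene statistics table
#'
#' Loads a tab-separated table of per-gene differential-expression
#' statistics: a gene identifier, a p-value, and optionally a log
#' fold-change and a mean expression (normalized count scale). The p-value
#' column holds the observed p-value distribution that the beta-uniform
#' mixture models; the mean expression column drives decile binning for
#' expression-matched null sampling.
#'
#' p-values of exactly zero are clamped to `clamp_floor` with a warning (the
#' mixture log-likelihood needs `log p` finite); p-values outside `[0, 1]`,
#' missing p-values, and duplicated gene identifiers are errors.
#'
#' @param path Path to a TSV file with a header line.
#' @param clamp_floor Positive replacement value for p-values of exactly 0.
#' @param gene_col,p_col,log_fc_col,expr_col Column names; defaults accept
#'   the common aliases (`gene`/`gene_id`, `p_value`/`pvalue`/`pval`/`p`,
#'   `log_fc`/`logFC`/`log2FoldChange`, `mean_expression`/`baseMean`/
#'   `mean_counts`).
#' @return A `gene_table`: a data.frame with columns `gene`, `p_value` and,
#'   when present in the input, `log_fc` and `mean_expression`.
#' @export
read_gene_table <- function(path, clamp_floor = 1e-300,
                            gene_col = NULL, p_col = NULL,
                            log_fc_col = NULL, expr_col = NULL) {
  if (!file.exists(path)) stop2("gene table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(given, aliases, required = FALSE, what = "") {
    if (!is.null(given)) {
      if (!given %in% names(raw)) stop2("column not found: ", given)
      return(given)
    }
    hit <- intersect(aliases, names(raw))
    if (length(hit) == 0L) {
      if (required) stop2("required ", what, " column missing (tried: ",
                          paste(aliases, collapse = ", "), ")")
      return(NULL)
    }
    hit[[1]]
  }
  gc <- pick(gene_col, c("gene", "gene_id", "Gene", "symbol"), TRUE, "gene id")
  pc <- pick(p_col, c("p_value", "pvalue", "pval", "p", "P.Value"), TRUE, "p-value")
  lc <- pick(log_fc_col, c("log_fc", "logFC", "log2FoldChange"))
  ec <- pick(expr_col, c("mean_expression", "mean_expr", "baseMean",
                         "mean_counts", "AveExpr"))

  p <- raw[[pc]]
  if (!is.numeric(p)) {
    p2 <- suppressWarnings(as.numeric(p))
    if (anyNA(p2) && !all(is.na(p[is.na(p2)])))
      stop2("non-numeric p-values in column '", pc, "'")
    p <- p2
  }
  gene_table(
    gene = as.character(raw[[gc]]),
    p_value = p,
    log_fc = if (!is.null(lc)) as.numeric(raw[[lc]]),
    mean_expression = if (!is.null(ec)) as.numeric(raw[[ec]]),
    clamp_floor = clamp_floor
  )
}

#' Construct and validate a gene table
#'
#' @param gene Character vector of unique gene identifiers.
#' @param p_value Numeric p-values in `(0, 1]`; exact zeros are clamped to
#'   `clamp_floor` with a warning.
#' @param log_fc Optional signed log fold-changes.
#' @param mean_expression Optional nonnegative mean expression values.
#' @param clamp_floor Replacement for p-values of exactly 0.
#' @return A data.frame of class `gene_table`.
#' @export
gene_table <- function(gene, p_value, log_fc = NULL, mean_expression = NULL,
                       clamp_floor = 1e-300) {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop2("duplicate gene ids: ",
          paste(utils::head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  if (anyNA(p_value)) stop2("missing p-values are not allowed")
  if (any(p_value < 0 | p_value > 1))
    stop2("p-values must lie in [0, 1]; clamping applies only to exact zeros")
  nzero <- sum(p_value == 0)
  if (nzero > 0L) {
    warn2(sprintf("%d p-value(s) of exactly 0 clamped to %g", nzero, clamp_floor))
    p_value[p_value == 0] <- clamp_floor
  }
  out <- data.frame(gene = gene, p_value = as.numeric(p_value),
                    stringsAsFactors = FALSE)
  if (!is.null(log_fc)) out$log_fc <- as.numeric(log_fc)
  if (!is.null(mean_expression)) {
    if (any(mean_expression < 0, na.rm = TRUE))
      stop2("mean_expression must be nonnegative")
    out$mean_expression <- as.numeric(mean_expression)
  }
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Write a gene table as TSV
#' @param table A `gene_table`.
#' @param path Output path.
#' @export
write_gene_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
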