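#' Read gene sets in GMT format
#'
#' GMT is the standard tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are deduplicated; duplicate set names, lines with fewer than
#' three fields, and sets with no members are errors.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_sets` object: a named list of character vectors with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop2("empty GMT file: ", path)
  sets <- list(); desc <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop2(sprintf("GMT line %d: fewer than 3 tab-separated fields", i))
    name <- fields[[1]]
    if (name %in% names(sets))
      stop2(sprintf("GMT line %d: duplicate set name '%s'", i, name))
    members <- unique(fields[3:length(fields)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop2(sprintf("GMT line %d: set '%s' has no members", i, name))
    sets[[name]] <- members
    desc[[name]] <- fields[[2]]
  }
  gene_sets(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (non-empty, unique names).
#' @param descriptions Optional named character vector of descriptions.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop2("every gene set must be named")
  if (anyDuplicated(names(sets))) stop2("gene set names must be unique")
  if (any(lengths(sets) == 0L)) stop2("gene sets must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' Write a gene-set collection in GMT format
#' @param sets A `gene_sets` object or named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
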