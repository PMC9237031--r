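`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

# deterministic lexicographic comparison, independent of locale
lex_lt <- function(a, b) {
  a <- paste(sort(a, method = "radix"), collapse = "\r")
  b <- paste(sort(b, method = "radix"), collapse = "\r")
  isTRUE(a < b)
}

sort_genes <- function(x) sort(unique(as.character(x)), method = "radix")

# draw per-iteration substream seeds from a master seed (kept < 2^31)
substream_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
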