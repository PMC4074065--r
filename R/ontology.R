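# Data-independent semantic similarity between genes from pre-propagated
# GO-style term sets, measured by the Jaccard index.

#' Jaccard index of two term sets
#'
#' `|a intersect b| / |a union b|`, defined as 0 when both sets are empty.
#'
#' @param a,b character vectors of term identifiers (duplicates ignored).
#' @return proportion in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise semantic similarity for a set of gene pairs
#'
#' Unannotated genes are treated as empty term sets (similarity 0 against
#' anything). Symmetric in the pair.
#'
#' @param ann named list mapping gene id to a character vector of
#'   pre-propagated term ids (an annotation set).
#' @param pairs data frame whose first two columns are gene ids (e.g. the
#'   `source`/`target` columns of an edge table).
#' @return `pairs` with a `jaccard` column appended.
#' @export
pairwise_similarity <- function(ann, pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  empty <- character()
  pairs$jaccard <- mapply(function(a, b) {
    jaccard_index(ann[[a]] %||% empty, ann[[b]] %||% empty)
  }, pairs[[1L]], pairs[[2L]], USE.NAMES = FALSE)
  pairs
}

#' Read gene annotations
#'
#' Accepts either a two-column TSV (`gene_id`, `term_id`, with a header) or a
#' GAF 2.x file, from which only columns 2 (object id) and 5 (term id) are
#' consumed. Term sets are assumed pre-propagated to the ontology root.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return named list of term-id character vectors.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop_invalid("annotation TSV needs two columns")
    return(lapply(split(df[[2L]], df[[1L]]), unique))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) >= 5L
  gene <- vapply(parts[ok], `[[`, character(1), 2L)
  term <- vapply(parts[ok], `[[`, character(1), 5L)
  lapply(split(term, gene), unique)
}

#' Write annotations as a two-column TSV
#'
#' @param ann named list of term-id vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(
    gene_id = rep(names(ann), lengths(ann)),
    term_id = unlist(ann, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
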