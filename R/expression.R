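# Expression matrix container, probeset collapse, scaling and gene selection.

#' Construct an expression matrix object
#'
#' A light container for a genes-by-stages expression matrix with ordered
#' stage labels, display symbols and an optional transcription-factor flag.
#'
#' @param values numeric matrix, one row per gene (rownames are gene ids),
#'   one column per ordered developmental stage (colnames are stage labels).
#' @param symbols character vector of display names, one per row; defaults to
#'   the gene ids.
#' @param scaled logical; `TRUE` once rows have been min-max scaled to
#'   `[0, 1]` by [scale_rows()].
#' @param is_tf optional named logical vector flagging transcription factors.
#' @return an object of class `grn_expr`.
#' @export
grn_expr <- function(values, symbols = NULL, scaled = FALSE, is_tf = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L) stop_invalid("empty expression matrix")
  if (is.null(rownames(values))) stop_invalid("`values` needs gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop_invalid("duplicate gene ids")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("stage", seq_len(ncol(values)))
  }
  symbols <- symbols %||% rownames(values)
  if (!is.null(is_tf)) is_tf <- setNames(as.logical(is_tf), names(is_tf))
  structure(
    list(values = values, symbols = setNames(symbols, rownames(values)),
         scaled = isTRUE(scaled), is_tf = is_tf),
    class = "grn_expr"
  )
}

#' @export
print.grn_expr <- function(x, ...) {
  cat(sprintf("<grn_expr> %d genes x %d stages (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "scaled to [0,1]" else "unscaled"))
  invisible(x)
}

#' @export
dim.grn_expr <- function(x) dim(x$values)

#' Gene ids of an expression matrix
#' @param m a `grn_expr`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Stage labels of an expression matrix
#' @param m a `grn_expr`.
#' @return character vector of stage labels, in input order.
#' @export
stages <- function(m) colnames(m$values)

subset_expr <- function(m, genes) {
  grn_expr(m$values[genes, , drop = FALSE],
           symbols = m$symbols[genes],
           scaled = m$scaled,
           is_tf = if (!is.null(m$is_tf)) m$is_tf[genes])
}

#' Read an expression table
#'
#' Expects a TSV with columns `gene_id`, optional `symbol`, optional
#' `probeset_id`, optional `is_tf` (0/1 or logical), followed by one numeric
#' column per stage in temporal order. If `probeset_id` is present the table
#' is returned as a data frame for [collapse_probesets()]; otherwise a
#' [grn_expr] object is returned directly.
#'
#' @param path file path.
#' @return a `grn_expr` or, for multi-probeset input, a data frame.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop_invalid("expression table needs a gene_id column")
  if ("probeset_id" %in% names(df)) return(df)
  as_grn_expr(df)
}

#' Convert a tidy expression data frame to a `grn_expr`
#'
#' @param df data frame with `gene_id`, optional `symbol` / `is_tf`, and one
#'   numeric column per stage.
#' @return a [grn_expr].
#' @export
as_grn_expr <- function(df) {
  meta <- intersect(c("gene_id", "symbol", "probeset_id", "is_tf"), names(df))
  stage_cols <- setdiff(names(df), meta)
  vals <- as.matrix(df[, stage_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$gene_id
  is_tf <- if ("is_tf" %in% names(df)) setNames(as.logical(df$is_tf), df$gene_id)
  grn_expr(vals,
           symbols = if ("symbol" %in% names(df)) df$symbol,
           is_tf = is_tf)
}

#' Write an expression matrix as TSV
#'
#' @param m a [grn_expr].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = gene_ids(m), symbol = unname(m$symbols),
                   stringsAsFactors = FALSE)
  if (!is.null(m$is_tf)) df$is_tf <- as.integer(m$is_tf[gene_ids(m)])
  df <- cbind(df, as.data.frame(m$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probesets to one row per gene
#'
#' When several probesets measure the same gene, the probeset with the
#' highest dynamic range (max minus min across stages) is retained; ties are
#' broken by the lexicographically smallest probeset identifier.
#'
#' @param raw data frame with columns `gene_id`, `probeset_id`, optional
#'   `symbol` / `is_tf`, and one numeric column per stage.
#' @return a [grn_expr] with one row per distinct gene.
#' @export
collapse_probesets <- function(raw) {
  if (!is.data.frame(raw) || nrow(raw) == 0L) stop_invalid("empty expression input")
  if (!all(c("gene_id", "probeset_id") %in% names(raw))) {
    stop_invalid("need gene_id and probeset_id columns")
  }
  meta <- intersect(c("gene_id", "symbol", "probeset_id", "is_tf"), names(raw))
  stage_cols <- setdiff(names(raw), meta)
  vals <- as.matrix(raw[, stage_cols, drop = FALSE])
  rng <- apply(vals, 1L, function(r) max(r) - min(r))
  # order: by gene, then range descending, then probeset id ascending
  ord <- order(raw$gene_id, -rng, raw$probeset_id)
  keep <- ord[!duplicated(raw$gene_id[ord])]
  out <- raw[keep, setdiff(names(raw), "probeset_id"), drop = FALSE]
  as_grn_expr(out)
}

#' Min-max scale each row to [0, 1]
#'
#' Each gene profile is mapped linearly so its minimum becomes 0 and its
#' maximum 1. Constant rows cannot be scaled; they are set to 0.5 everywhere
#' and recorded in the `constant_rows` attribute (with a message).
#' Idempotent: scaling an already scaled matrix changes nothing.
#'
#' @param m a [grn_expr].
#' @return the scaled [grn_expr] with `scaled = TRUE`.
#' @export
scale_rows <- function(m) {
  v <- m$values
  lo <- apply(v, 1L, min)
  hi <- apply(v, 1L, max)
  const <- hi - lo <= 0
  rngv <- ifelse(const, 1, hi - lo)
  out <- (v - lo) / rngv
  if (any(const)) {
    out[const, ] <- 0.5
    message(sum(const), " constant row(s) set to 0.5 (cannot min-max scale)")
  }
  res <- grn_expr(out, symbols = m$symbols, scaled = TRUE, is_tf = m$is_tf)
  attr(res, "constant_rows") <- rownames(v)[const]
  res
}

#' Select genes by differential-expression rank, TF rank and a curated list
#'
#' Reproduces the study-style gene-of-interest selection: the union of (i)
#' the top `top_de_genes` by a cross-stage change statistic, (ii) the top
#' `top_de_tfs` by the same statistic among transcription-factor-flagged
#' genes, and (iii) a curated list. The union is deduplicated and returned
#' ordered by gene id, so the result is invariant to input row order.
#'
#' @param m a [grn_expr].
#' @param top_de_genes number of top-ranked genes to take over all genes.
#' @param top_de_tfs number of top-ranked genes among TF-flagged genes.
#' @param curated character vector of gene ids to include regardless of rank.
#' @param ranking change statistic: `"variance"` (population variance of the
#'   row-scaled profile, the default) or `"range"` (max minus min of the
#'   input profile).
#' @param tf_flags optional named logical vector; defaults to `m$is_tf`.
#' @return a [grn_expr] restricted to the selected genes. Curated ids absent
#'   from the matrix trigger a warning and are recorded in the
#'   `missing_curated` attribute.
#' @export
select_genes <- function(m, top_de_genes = 0L, top_de_tfs = 0L,
                         curated = character(),
                         ranking = c("variance", "range"),
                         tf_flags = NULL) {
  ranking <- match.arg(ranking)
  tf_flags <- tf_flags %||% m$is_tf
  if (top_de_tfs > 0L && is.null(tf_flags)) {
    stop_invalid("top_de_tfs > 0 requires transcription-factor flags")
  }
  ids <- gene_ids(m)
  stat <- switch(ranking,
    variance = {
      sm <- if (m$scaled) m$values else scale_rows(m)$values
      apply(sm, 1L, function(r) mean((r - mean(r))^2))
    },
    range = apply(m$values, 1L, function(r) max(r) - min(r))
  )
  top_of <- function(pool, k) {
    if (k <= 0L || !length(pool)) return(character())
    pool[order(-stat[pool], pool)][seq_len(min(k, length(pool)))]
  }
  tf_pool <- if (!is.null(tf_flags)) ids[ids %in% names(tf_flags)[tf_flags %in% TRUE]] else character()
  missing <- setdiff(curated, ids)
  if (length(missing)) {
    warning("curated genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  sel <- sort(unique(c(top_of(ids, top_de_genes), top_of(tf_pool, top_de_tfs),
                       intersect(curated, ids))))
  if (!length(sel)) stop_invalid("gene selection is empty")
  out <- subset_expr(m, sel)
  attr(out, "missing_curated") <- missing
  out
}
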