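# Fidelity score: weighted sum of the z-scored log-confidence and z-scored
# Jaccard similarity of each edge, used to rank and filter networks.
# z-scores use the population SD and are always computed within the edge
# population under analysis, so scores are not comparable across networks.

#' z-score the log of the confidence metric
#'
#' `zc = (log c - mean(log c)) / sd_pop(log c)` over the current edge
#' population. Confidence values are frequencies in `(0, 1]`; an edge with
#' zero confidence was never observed and cannot be in the population.
#'
#' @param records edge data frame with a `confidence` column.
#' @return `records` with a `zc` column appended.
#' @export
zscore_log_confidence <- function(records) {
  if (nrow(records) < 2L) stop("degenerate population: fewer than 2 edges")
  if (any(records$confidence <= 0)) stop_invalid("confidence must be > 0")
  lc <- log(records$confidence)
  s <- pop_sd(lc)
  if (s == 0) stop("degenerate population: zero variance of log-confidence")
  records$zc <- (lc - mean(lc)) / s
  records
}

#' z-score the Jaccard similarities with the zero-overlap sentinel
#'
#' Only the nonzero Jaccard indices are z-scored (population SD, among
#' themselves); edges with zero term overlap are assigned the sentinel
#' `min(nonzero zj) - 1`, keeping the nonzero scores centred while still
#' ranking semantically dissimilar pairs lowest. With fewer than two nonzero
#' values the similarity channel is uninformative: all `zj` are set to 0
#' with a warning (weight effectively disabled).
#'
#' @param records edge data frame with a `jaccard` column.
#' @return `records` with a `zj` column appended.
#' @export
zscore_jaccard <- function(records) {
  nz <- records$jaccard > 0
  if (sum(nz) < 2L) {
    warning("fewer than 2 nonzero Jaccard values; zj set to 0 (weight disabled)")
    records$zj <- 0
    return(records)
  }
  x <- records$jaccard[nz]
  s <- pop_sd(x)
  if (s == 0) stop("degenerate population: nonzero Jaccard values all equal")
  zj <- rep(NA_real_, nrow(records))
  zj[nz] <- (x - mean(x)) / s
  zj[!nz] <- min(zj[nz]) - 1
  records$zj <- zj
  records
}

#' Fidelity score at weight w
#'
#' `Z(w) = zc + w * zj`: the weighted sum of the z-scored log-confidence and
#' the z-scored Jaccard index. `w = 0` is the confidence-only filter; `w = 1`
#' weighs both metrics equally (the optimum reported on the cardiogenesis
#' data).
#'
#' @param records edge data frame with `zc` and `zj` columns (see
#'   [score_fidelity()] for the one-call version).
#' @param w nonnegative weight on the similarity channel.
#' @return `records` with a `z_w` column appended.
#' @export
fidelity <- function(records, w = 1) {
  if (w < 0) stop_invalid("w must be nonnegative")
  if (is.null(records$zc) || is.null(records$zj)) {
    stop_invalid("records need zc and zj columns; see score_fidelity()")
  }
  records$z_w <- records$zc + w * records$zj
  records
}

#' Compute all fidelity components in one call
#'
#' Convenience wrapper: [zscore_log_confidence()], [zscore_jaccard()], then
#' [fidelity()] at weight `w`.
#'
#' @param records edge data frame with `confidence` and `jaccard` columns.
#' @param w nonnegative weight.
#' @return `records` with `zc`, `zj` and `z_w` columns.
#' @export
score_fidelity <- function(records, w = 1) {
  fidelity(zscore_jaccard(zscore_log_confidence(records)), w)
}

#' Optimize the similarity weight against a reference edge set
#'
#' Sweeps a weight grid and returns the weight maximizing the area under the
#' precision-recall curve of the `Z(w)`-ranked (undirected) edges against
#' the reference; ties resolve to the smallest weight.
#'
#' @param records edge data frame with `zc` and `zj` columns.
#' @param reference two-column data frame of known undirected interactions.
#' @param grid candidate weights (default `c(0, 0.25, 0.5, 1, 2, 5, 10)`).
#' @param genes gene population for the curves (default: all genes in
#'   `records`).
#' @return list with `w` (the optimum), and `aupr` per grid value.
#' @export
optimize_weight <- function(records, reference,
                            grid = c(0, 0.25, 0.5, 1, 2, 5, 10),
                            genes = NULL) {
  if (is.null(reference) || nrow(reference) == 0L) stop_invalid("reference is empty")
  grid <- sort(grid)
  genes <- genes %||% sort(unique(c(records$source, records$target)))
  auprs <- vapply(grid, function(w) {
    evaluate_curves(fidelity(records, w), reference, genes, score = "z_w")$aupr
  }, numeric(1))
  list(w = grid[which.max(auprs)], aupr = setNames(auprs, grid))
}

#' Filter a scored network at a fidelity cutoff
#'
#' Retains edges with `z_w` strictly above the cutoff and drops isolated
#' nodes. Raising the cutoff yields exactly nested edge sets.
#'
#' @param records edge data frame with a `z_w` column.
#' @param cutoff score threshold (`-Inf` retains everything).
#' @return object of class `grn_network`: `edges`, `nodes`, `cutoff`.
#' @export
filter_network <- function(records, cutoff) {
  keep <- records[records$z_w > cutoff, , drop = FALSE]
  rownames(keep) <- NULL
  structure(
    list(edges = keep,
         nodes = sort(unique(c(keep$source, keep$target))),
         cutoff = cutoff),
    class = "grn_network"
  )
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("<grn_network> %d node(s), %d edge(s) at cutoff %s\n",
              length(x$nodes), nrow(x$edges), format(x$cutoff)))
  invisible(x)
}
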