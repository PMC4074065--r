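# Benchmarking a scored network against a reference edge set: undirected
# comparison, precision-recall / ROC curves and AUCs, hypergeometric network
# significance, and top-k true-positive enrichment.

ref_keys <- function(reference) {
  if (is.data.frame(reference)) {
    unique(pair_key(reference[[1L]], reference[[2L]]))
  } else {
    unique(as.character(reference))
  }
}

#' Collapse a directed edge table to undirected pairs
#'
#' Curated reference interactions lack directionality, so networks are
#' compared as undirected graphs. Per unordered pair the row with the
#' maximum score is kept.
#'
#' @param records edge data frame with `source` and `target` columns.
#' @param score name of the score column used to resolve reciprocal pairs
#'   (default `"z_w"`, falling back to `"confidence"`).
#' @return the undirected edge data frame (one row per unordered pair).
#' @export
to_undirected <- function(records, score = NULL) {
  score <- score %||% (if ("z_w" %in% names(records)) "z_w" else "confidence")
  key <- pair_key(records$source, records$target)
  ord <- order(key, -records[[score]])
  out <- records[ord[!duplicated(key[ord])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of possible undirected pairs called as edges
#'
#' @param n_edges number of undirected edges called.
#' @param n_genes number of genes in the network.
#' @return proportion `n_edges / choose(n_genes, 2)`.
#' @export
edge_call_fraction <- function(n_edges, n_genes) {
  n_edges / choose(n_genes, 2)
}

#' Recall of a reference edge set
#'
#' @param hits number of called edges present in the reference.
#' @param reference_size total reference edges.
#' @return proportion `hits / reference_size`.
#' @export
reference_recall <- function(hits, reference_size) hits / reference_size

#' Precision-recall and ROC curves against a reference
#'
#' The evaluation population is every unordered gene pair among `genes`
#' (required for a defined false-positive rate); pairs missing from the
#' scored table rank jointly at the bottom. Thresholds sweep the distinct
#' scores, tied scores grouped into single sweep steps; both AUCs use the
#' trapezoid rule.
#'
#' @param records scored edge data frame (directions are collapsed with
#'   [to_undirected()]).
#' @param reference two-column data frame (or vector of pair keys) of known
#'   undirected interactions, restricted to `genes`.
#' @param genes gene population defining the possible pairs (default: genes
#'   appearing in `records`).
#' @param score score column (default `z_w` if present, else `confidence`).
#' @return object of class `grn_curves`: `pr_points` (recall, precision),
#'   `roc_points` (fpr, tpr), `aupr`, `auroc`, `baseline_precision`.
#' @export
evaluate_curves <- function(records, reference, genes = NULL, score = NULL) {
  score <- score %||% (if ("z_w" %in% names(records)) "z_w" else "confidence")
  genes <- sort(genes %||% unique(c(records$source, records$target)))
  if (length(genes) < 2L) stop_invalid("need at least two genes")
  und <- to_undirected(records, score)
  pairs <- combn(genes, 2L)
  keys <- pair_key(pairs[1L, ], pairs[2L, ])
  scores <- setNames(rep(-Inf, length(keys)), keys)
  uk <- pair_key(und$source, und$target)
  uk_in <- uk %in% keys
  scores[uk[uk_in]] <- und[[score]][uk_in]
  labels <- keys %in% ref_keys(reference)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) stop("need at least one positive and one negative pair")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(l)[grp_end]
  called <- grp_end
  fp <- called - tp
  recall <- tp / P
  precision <- tp / called
  fpr <- fp / N
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  roc_x <- c(0, fpr); roc_y <- c(0, recall)
  auroc <- trap(roc_x, roc_y)
  pr_x <- c(0, recall); pr_y <- c(precision[1L], precision)
  aupr <- trap(pr_x, pr_y)
  structure(
    list(pr_points = data.frame(recall = recall, precision = precision),
         roc_points = data.frame(fpr = fpr, tpr = recall),
         aupr = aupr, auroc = auroc,
         baseline_precision = P / (P + N)),
    class = "grn_curves"
  )
}

#' @export
print.grn_curves <- function(x, ...) {
  cat(sprintf("<grn_curves> AUPR %.3f (baseline %.3f), AUROC %.3f\n",
              x$aupr, x$baseline_precision, x$auroc))
  invisible(x)
}

#' Plot PR and ROC curves
#'
#' @param x a `grn_curves`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.grn_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$pr_points$recall, x$pr_points$precision, type = "l",
       xlab = "recall", ylab = "precision", xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("PR (AUC %.3f)", x$aupr), ...)
  graphics::abline(h = x$baseline_precision, lty = 3)
  plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
       xlab = "false positive rate", ylab = "true positive rate",
       xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("ROC (AUC %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `x` reference edges when `n` of the `N` possible pairs are
#' called and `K` of them are in the reference. The upper tail (not the
#' cumulative the classic `hygecdf` routine returns) is the enrichment
#' question; computed in log space by `phyper`.
#'
#' @param N population size (possible undirected pairs).
#' @param K reference edges within the population.
#' @param n called edges.
#' @param x called edges found in the reference.
#' @return the p-value `P(X >= x)`.
#' @export
hypergeometric_significance <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > n || x > K) {
    stop_invalid("impossible hypergeometric counts")
  }
  if (x == 0L) return(1)
  exp(phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' True-positive enrichment in the top-k ranked edges
#'
#' Edges are collapsed to undirected pairs, ranked by score descending with
#' lexicographic pair tie-break, and the fraction of reference hits among
#' the top k is reported per k.
#'
#' @param records scored edge data frame.
#' @param reference reference edge set (data frame or pair keys).
#' @param ks vector of list lengths, each at most the number of scored pairs.
#' @param score score column (default `z_w` if present, else `confidence`).
#' @return data frame with `k`, `hits`, `fraction`.
#' @export
topk_enrichment <- function(records, reference, ks, score = NULL) {
  score <- score %||% (if ("z_w" %in% names(records)) "z_w" else "confidence")
  und <- to_undirected(records, score)
  if (any(ks > nrow(und))) stop_invalid("k exceeds the number of scored pairs")
  und <- und[order(-und[[score]], pmin(und$source, und$target),
                   pmax(und$source, und$target)), , drop = FALSE]
  hit <- pair_key(und$source, und$target) %in% ref_keys(reference)
  cum <- cumsum(hit)
  data.frame(k = ks, hits = cum[ks], fraction = cum[ks] / ks)
}

#' Network enrichment significance across fidelity cutoffs
#'
#' Filters the scored edges at each cutoff, collapses to undirected pairs
#' and computes the upper-tail hypergeometric enrichment of the retained
#' edges against the reference over the population of all unordered pairs
#' among `genes`. An empty retained set has undefined enrichment and is
#' reported as p = 1 with `empty = TRUE`.
#'
#' @param records scored edge data frame with `z_w`.
#' @param reference reference edge set.
#' @param cutoffs fidelity cutoffs to sweep.
#' @param genes gene population (default: genes in `records`).
#' @return data frame with `cutoff`, `n_called`, `hits`, `p_value`, `empty`.
#' @export
significance_vs_cutoff <- function(records, reference, cutoffs, genes = NULL) {
  genes <- sort(genes %||% unique(c(records$source, records$target)))
  N <- choose(length(genes), 2)
  keys_all <- {
    pairs <- combn(genes, 2L)
    pair_key(pairs[1L, ], pairs[2L, ])
  }
  K <- sum(keys_all %in% ref_keys(reference))
  do.call(rbind, lapply(cutoffs, function(ct) {
    und <- to_undirected(records[records$z_w > ct, , drop = FALSE], "z_w")
    n <- nrow(und)
    if (n == 0L) {
      return(data.frame(cutoff = ct, n_called = 0L, hits = 0L,
                        p_value = 1, empty = TRUE))
    }
    x <- sum(pair_key(und$source, und$target) %in% ref_keys(reference))
    data.frame(cutoff = ct, n_called = n, hits = x,
               p_value = hypergeometric_significance(N, K, n, x),
               empty = FALSE)
  }))
}

#' Write an evaluation report as JSON
#'
#' Bundles curve points and AUCs with optional significance-vs-cutoff and
#' top-k enrichment tables into one JSON report.
#'
#' @param curves a `grn_curves` from [evaluate_curves()].
#' @param path output path.
#' @param significance optional data frame from [significance_vs_cutoff()].
#' @param topk optional data frame from [topk_enrichment()].
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(curves, path, significance = NULL,
                                    topk = NULL) {
  rep <- list(aupr = curves$aupr, auroc = curves$auroc,
              baseline_precision = curves$baseline_precision,
              pr_points = curves$pr_points, roc_points = curves$roc_points)
  if (!is.null(significance)) rep$significance_vs_cutoff <- significance
  if (!is.null(topk)) rep$topk_enrichment <- topk
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
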