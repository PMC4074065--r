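# Phase 2: expand the filtered scaffold network over expression-profile
# clusters, rescore the expanded edge population and filter to the final
# network, then prioritize profile-unique predictions.

#' Expand a scaffold network over profile clusters
#'
#' Every scaffold edge A-B is replaced by all combinations of genes sharing
#' A's profile cluster with genes sharing B's cluster (clusters of sizes 5
#' and 7 yield 35 candidate pairs), excluding self-pairs. Expanded pairs
#' inherit the parent edge's confidence and sign call; Jaccard similarity is
#' recomputed per pair. When the same unordered pair arises from several
#' parents, the occurrence with the highest inherited confidence is kept.
#'
#' @param scaffold a `grn_network` from [filter_network()].
#' @param part a `grn_partition`; scaffold genes absent from it count as
#'   singletons.
#' @param ann annotation set (named list of term vectors) for the expanded
#'   gene universe.
#' @return data frame of expanded edges: `parent_source`, `parent_target`,
#'   `source`, `target`, `confidence`, `sign_call`, `jaccard`,
#'   `cluster_product`.
#' @export
expand_network <- function(scaffold, part, ann) {
  edges <- scaffold$edges
  if (nrow(edges) == 0L) {
    return(data.frame(parent_source = character(), parent_target = character(),
                      source = character(), target = character(),
                      confidence = numeric(), sign_call = character(),
                      jaccard = numeric(), cluster_product = integer()))
  }
  members_of <- function(g) {
    idx <- part$membership[g]
    if (is.na(idx)) g else part$clusters[[idx]]
  }
  blocks <- lapply(seq_len(nrow(edges)), function(i) {
    e <- edges[i, ]
    src <- members_of(e$source)
    tgt <- members_of(e$target)
    grid <- expand.grid(source = src, target = tgt,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$target, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    data.frame(parent_source = e$source, parent_target = e$target,
               source = grid$source, target = grid$target,
               confidence = e$confidence,
               sign_call = e$sign_call %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  # duplicates (same unordered pair arising from different parents): keep the
  # occurrence(s) contributed by the parent with the highest confidence;
  # both orientations of a same-cluster pair from one parent are retained
  key <- pair_key(out$source, out$target)
  parent <- paste(out$parent_source, out$parent_target)
  ord <- order(key, -out$confidence, parent)
  winner <- setNames(parent[ord][!duplicated(key[ord])],
                     key[ord][!duplicated(key[ord])])
  out <- out[parent == winner[key], , drop = FALSE]
  out <- pairwise_similarity(ann, out[, c("source", "target", "parent_source",
                                          "parent_target", "confidence",
                                          "sign_call")])
  out$cluster_product <- cluster_product(out$source, out$target, part)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescore and filter an expanded network
#'
#' Fidelity z-scores are recomputed over the expanded edge population (scores
#' are population-relative and cannot be carried over from Phase 1), then
#' edges with `Z(w)` above the cutoff are retained.
#'
#' @param expanded data frame from [expand_network()].
#' @param w similarity weight (default 1, the reported optimum).
#' @param cutoff fidelity cutoff (default 2.5, the study's Phase 2 setting).
#' @return a `grn_network` whose edges keep the expansion columns.
#' @export
rescore_and_filter <- function(expanded, w = 1, cutoff = 2.5) {
  if (nrow(expanded) == 0L) stop_invalid("expanded edge set is empty")
  filter_network(score_fidelity(expanded, w), cutoff)
}

#' Prioritize profile-unique predictions
#'
#' Applies the secondary cluster-product filter and ranks what remains:
#' edges whose cluster product exceeds `max_cluster_product` are dropped
#' (their prediction could be explained by too many profile-equivalent gene
#' combinations); survivors are ordered by fidelity score descending, then
#' cluster product ascending, then lexicographic pair.
#'
#' @param net a `grn_network` (or an edge data frame) with `z_w` and
#'   `cluster_product` columns.
#' @param max_cluster_product largest admissible cluster product
#'   (default 30; `Inf` disables the secondary filter).
#' @return ranked edge data frame.
#' @export
prioritize_edges <- function(net, max_cluster_product = 30) {
  edges <- if (inherits(net, "grn_network")) net$edges else net
  keep <- edges[edges$cluster_product <= max_cluster_product, , drop = FALSE]
  keep <- keep[order(-keep$z_w, keep$cluster_product, keep$source, keep$target), ,
               drop = FALSE]
  rownames(keep) <- NULL
  keep
}
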