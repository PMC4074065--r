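# Expression-profile modules by repeated self-organizing-map co-clustering:
# dispersion pre-filter, coincidence frequencies pooled over many SOM runs
# on randomly sized grids, threshold partition, and the cluster-product
# uniqueness metric.

#' Dispersion pre-filter
#'
#' Excludes "stable, non-dynamic" genes whose dispersion (population SD over
#' mean) across stages is below the cutoff. Dispersion is meaningful only on
#' the pre-scaling measurement scale; genes with nonpositive mean are
#' excluded (with a message).
#'
#' @param m a [grn_expr] on the pre-scaled, nonnegative measurement scale.
#' @param cutoff dispersion cutoff (default 0.20, i.e. SD/mean < 20%
#'   excluded).
#' @return list with `included`, `excluded` (gene id vectors) and the named
#'   `dispersion` values.
#' @export
dispersion_filter <- function(m, cutoff = 0.20) {
  if (cutoff <= 0) stop_invalid("cutoff must be positive")
  mu <- rowMeans(m$values)
  sdv <- apply(m$values, 1L, pop_sd)
  disp <- ifelse(mu > 0, sdv / mu, NA_real_)
  bad_mean <- !is.finite(disp)
  if (any(bad_mean)) {
    message(sum(bad_mean), " gene(s) with nonpositive mean excluded")
  }
  excl <- bad_mean | disp < cutoff
  list(included = gene_ids(m)[!excl],
       excluded = gene_ids(m)[excl],
       dispersion = setNames(disp, gene_ids(m)))
}

# One batch SOM run: returns the best-matching-unit index per gene.
# Gaussian neighborhood with radius shrinking linearly from side/2 to 0.5.
som_run <- function(X, side, epochs = 20L) {
  nu <- side * side
  gx <- rep(seq_len(side), each = side)
  gy <- rep(seq_len(side), times = side)
  gd2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  W <- X[sample.int(nrow(X), nu, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(nu * ncol(X), sd = 1e-4), nu)
  x2 <- rowSums(X^2)
  bmu <- NULL
  for (e in seq_len(epochs)) {
    score <- 2 * (X %*% t(W)) -
      matrix(rowSums(W^2), nrow(X), nu, byrow = TRUE)
    bmu <- max.col(score, ties.method = "first")
    sigma <- side / 2 + (e - 1) / max(epochs - 1, 1) * (0.5 - side / 2)
    H <- exp(-gd2 / (2 * sigma^2))
    S <- matrix(0, nu, ncol(X))
    hit <- rowsum(X, bmu)                  # one row per occupied unit
    S[as.integer(rownames(hit)), ] <- hit
    cnt <- tabulate(bmu, nbins = nu)
    num <- H %*% S
    den <- as.vector(H %*% cnt)
    upd <- den > 1e-12
    W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  # final assignment with the updated codebook
  score <- 2 * (X %*% t(W)) - matrix(rowSums(W^2), nrow(X), nu, byrow = TRUE)
  max.col(score, ties.method = "first")
}

#' Co-cluster profiles by repeated SOM runs
#'
#' Trains `n_runs` self-organizing maps on the gene profiles, each on a
#' square grid whose side is drawn uniformly between `grid_min` and
#' `grid_max` (the study varied 3x3 through 50x50 and pooled 2,240 runs).
#' The coincidence of a gene pair is the fraction of runs in which the two
#' genes map to the same map node.
#'
#' @param m a [grn_expr] (typically row-scaled).
#' @param n_runs number of SOM runs to pool (study fidelity: 2240; a few
#'   hundred suffice at benchmark scale).
#' @param grid_min,grid_max square-grid side range (defaults 3 and 50).
#' @param epochs batch-training epochs per run.
#' @param seed integer seed.
#' @return object of class `grn_coclust`: `genes`, symmetric `coincidence`
#'   matrix with unit diagonal, `n_runs`.
#' @export
co_cluster <- function(m, n_runs = 200L, grid_min = 3L, grid_max = 50L,
                       epochs = 20L, seed = 1L) {
  if (n_runs < 1L) stop_invalid("n_runs must be >= 1")
  X <- m$values
  if (nrow(X) < 2L) stop_invalid("need at least two genes to co-cluster")
  n <- nrow(X)
  count <- matrix(0L, n, n, dimnames = list(rownames(X), rownames(X)))
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      side <- sample(seq.int(grid_min, grid_max), 1L)
      bmu <- som_run(X, side, epochs)
      count <- count + outer(bmu, bmu, "==")
    }
  })
  structure(
    list(genes = rownames(X), coincidence = count / n_runs,
         n_runs = as.integer(n_runs)),
    class = "grn_coclust"
  )
}

#' @export
print.grn_coclust <- function(x, ...) {
  cat(sprintf("<grn_coclust> %d genes, %d SOM runs pooled\n",
              length(x$genes), x$n_runs))
  invisible(x)
}

#' Partition genes at a coincidence threshold
#'
#' Clusters are the connected components of the graph whose edges join gene
#' pairs with coincidence at or above the threshold (default 0.70).
#'
#' @param cc a `grn_coclust`.
#' @param threshold coincidence threshold in `(0, 1]`.
#' @return object of class `grn_partition`: `clusters` (list of gene-id
#'   vectors), `membership` (named cluster index), `threshold`,
#'   `singleton_count`.
#' @export
partition_clusters <- function(cc, threshold = 0.70) {
  if (threshold <= 0 || threshold > 1) stop_invalid("threshold must be in (0, 1]")
  adj <- cc$coincidence >= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  membership <- setNames(as.integer(comp$membership), cc$genes)
  clusters <- split(cc$genes, membership)
  names(clusters) <- NULL
  structure(
    list(clusters = clusters, membership = membership, threshold = threshold,
         singleton_count = sum(lengths(clusters) == 1L)),
    class = "grn_partition"
  )
}

#' @export
print.grn_partition <- function(x, ...) {
  cat(sprintf("<grn_partition> %d cluster(s) at threshold %.2f (%d singleton(s))\n",
              length(x$clusters), x$threshold, x$singleton_count))
  invisible(x)
}

cluster_size <- function(part, gene) {
  idx <- part$membership[gene]
  ifelse(is.na(idx), 1L, lengths(part$clusters)[idx])
}

#' Cluster product of an edge
#'
#' The product of the cluster sizes of an edge's two endpoints. Low values
#' mark profile-unique, high-priority predictions; genes absent from the
#' partition count as singletons.
#'
#' @param source,target gene ids (vectorized).
#' @param part a `grn_partition`.
#' @return integer vector of cluster products (always >= 1, symmetric in
#'   the pair).
#' @export
cluster_product <- function(source, target, part) {
  as.integer(cluster_size(part, source) * cluster_size(part, target))
}

#' Write the coincidence matrix as a sparse pair TSV
#'
#' Only off-diagonal pairs with positive coincidence are written.
#'
#' @param cc a `grn_coclust`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coincidence <- function(cc, path) {
  idx <- which(upper.tri(cc$coincidence) & cc$coincidence > 0, arr.ind = TRUE)
  df <- data.frame(gene_a = cc$genes[idx[, 1L]], gene_b = cc$genes[idx[, 2L]],
                   frequency = cc$coincidence[idx], stringsAsFactors = FALSE)
  write.table(df[order(df$gene_a, df$gene_b), ], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster partition as TSV
#'
#' @param part a `grn_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  df <- data.frame(
    cluster_id = rep(seq_along(part$clusters), lengths(part$clusters)),
    gene_id = unlist(part$clusters, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
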