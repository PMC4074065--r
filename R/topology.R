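# Topology characterization of filtered networks: degree histogram and
# Poisson mean-degree estimate, power-law exponent by log-log regression,
# and clustering-coefficient-vs-degree scaling (hierarchy signature).

as_undirected_igraph <- function(net) {
  edges <- if (inherits(net, "grn_network")) net$edges else net
  if (is.null(edges) || nrow(edges) == 0L) stop("empty graph")
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Degree histogram and Poisson mean-degree estimate
#'
#' Treats the network as an undirected simple graph. The Poisson parameter
#' estimate is the mean degree `2E/N` (unfiltered inference output is
#' hairball-like, with a Poisson degree distribution).
#'
#' @param net a `grn_network` or edge data frame with `source`/`target`.
#' @return list with `degree_hist` (data frame `degree`, `count`),
#'   `lambda_hat`, `n_nodes`, `n_edges`.
#' @export
degree_stats <- function(net) {
  g <- as_undirected_igraph(net)
  deg <- igraph::degree(g)
  tab <- table(deg)
  list(degree_hist = data.frame(degree = as.integer(names(tab)),
                                count = as.integer(tab)),
       lambda_hat = mean(deg),
       n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g))
}

#' Power-law fit of the degree distribution
#'
#' Least-squares regression of `log(count)` on `log(degree)` over nonzero
#' histogram bins with positive degree; the exponent is minus the slope.
#' Scale-free networks emerge in the filtered inference output, with
#' exponents near 1 at moderate cutoffs.
#'
#' @param degree_hist data frame with `degree` and `count` columns (e.g.
#'   from [degree_stats()]).
#' @return list with `gamma_hat`, `gamma_r2`; both `NA` (flagged via
#'   `defined = FALSE`) with fewer than 3 distinct positive degrees.
#' @export
powerlaw_fit <- function(degree_hist) {
  d <- degree_hist[degree_hist$degree > 0 & degree_hist$count > 0, , drop = FALSE]
  if (nrow(d) < 3L) {
    return(list(gamma_hat = NA_real_, gamma_r2 = NA_real_, defined = FALSE))
  }
  fit <- lm(log(count) ~ log(degree), data = d)
  y <- log(d$count)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(gamma_hat = -unname(coef(fit)[2L]),
       gamma_r2 = max(0, min(1, r2)),
       defined = TRUE)
}

#' Clustering-coefficient scaling with inverse degree
#'
#' Computes the local clustering coefficient per node, averages it per
#' degree `C(k)` (degrees >= 2 only; below that the coefficient is
#' undefined), and fits `C(k) = c / k` through the origin. The coefficient
#' of determination of that fit (clipped to `[0, 1]`) quantifies how
#' hierarchical the network is: `C(k)` proportional to `1/k` is the
#' hierarchical-network signature, while flat `C(k)` gives a poor fit.
#'
#' @param net a `grn_network` or edge data frame.
#' @return list with `ck_points` (data frame `k`, `ck`), `ck_r2`, and
#'   `defined` (`FALSE` when fewer than 3 nodes have degree >= 2).
#' @export
clustering_scaling <- function(net) {
  g <- as_undirected_igraph(net)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  ok <- deg >= 2
  if (sum(ok) < 3L) {
    return(list(ck_points = data.frame(k = integer(), ck = numeric()),
                ck_r2 = NA_real_, defined = FALSE))
  }
  ck <- tapply(cc[ok], deg[ok], mean)
  pts <- data.frame(k = as.integer(names(ck)), ck = as.numeric(ck))
  fit <- lm(ck ~ 0 + I(1 / k), data = pts)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((pts$ck - mean(pts$ck))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(ck_points = pts, ck_r2 = max(0, min(1, r2)), defined = TRUE)
}

#' Full topology report
#'
#' Degree statistics, power-law and Poisson fits, and the hierarchy (C(k)
#' vs 1/k) fit for a filtered network. The handshake identity
#' `sum(k * N(k)) = 2E` holds exactly for every report.
#'
#' @param net a `grn_network` or edge data frame.
#' @return object of class `grn_topology`.
#' @export
topology_report <- function(net) {
  ds <- degree_stats(net)
  pl <- powerlaw_fit(ds$degree_hist)
  cs <- clustering_scaling(net)
  structure(
    list(n_nodes = ds$n_nodes, n_edges = ds$n_edges,
         degree_hist = ds$degree_hist, lambda_hat = ds$lambda_hat,
         gamma_hat = pl$gamma_hat, gamma_r2 = pl$gamma_r2,
         gamma_defined = pl$defined,
         ck_points = cs$ck_points, ck_r2 = cs$ck_r2,
         ck_defined = cs$defined),
    class = "grn_topology"
  )
}

#' @export
print.grn_topology <- function(x, ...) {
  cat(sprintf("<grn_topology> %d nodes, %d edges; lambda = %.2f; gamma = %s (R2 %s); C(k)~1/k R2 %s\n",
              x$n_nodes, x$n_edges, x$lambda_hat,
              format(x$gamma_hat, digits = 3), format(x$gamma_r2, digits = 2),
              format(x$ck_r2, digits = 2)))
  invisible(x)
}

#' Write a topology report as JSON
#'
#' @param rep a `grn_topology` from [topology_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(rep, path) {
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
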