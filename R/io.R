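# Network export: ranked edge tables (TSV), SIF and GraphML.

#' Write a scored edge table as TSV
#'
#' Edges are ranked by fidelity score descending when a `z_w` column is
#' present. A `# config_hash:` header line is prepended when a configuration
#' is supplied, so artifacts from different runs are distinguishable.
#'
#' @param records edge data frame.
#' @param path output path.
#' @param cfg optional [pipeline_config()] to stamp.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(records, path, cfg = NULL) {
  if ("z_w" %in% names(records)) {
    records <- records[order(-records$z_w, records$source, records$target), ,
                       drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(paste0("# config_hash: ", config_hash(cfg)), con)
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored edge table written by [write_edge_table()]
#'
#' @param path file path.
#' @param cfg optional configuration; when given and the file carries a
#'   `# config_hash:` stamp, a mismatch is an error.
#' @return edge data frame.
#' @export
read_edge_table <- function(path, cfg = NULL) {
  first <- readLines(path, n = 1L)
  has_hash <- startsWith(first, "# config_hash:")
  if (!is.null(cfg) && has_hash) {
    stamp <- trimws(sub("# config_hash:", "", first, fixed = TRUE))
    if (stamp != config_hash(cfg)) {
      stop("configuration hash mismatch: refusing to mix artifacts")
    }
  }
  read.delim(path, sep = "\t", skip = as.integer(has_hash),
             stringsAsFactors = FALSE)
}

#' Export a network in SIF format
#'
#' One line per edge: `source <relation> target`, with the sign call as the
#' relation (`activating` / `inhibiting` / `unclear`, or `interacts` when no
#' sign is available).
#'
#' @param net a `grn_network` or edge data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  edges <- if (inherits(net, "grn_network")) net$edges else net
  rel <- edges$sign_call %||% rep("interacts", nrow(edges))
  rel[is.na(rel)] <- "interacts"
  writeLines(paste(edges$source, rel, edges$target, sep = "\t"), path)
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' Edge attributes (confidence, jaccard, scores) are carried over.
#'
#' @param net a `grn_network` or edge data frame.
#' @param directed logical (default `TRUE`).
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net, directed = TRUE) {
  edges <- if (inherits(net, "grn_network")) net$edges else net
  first <- c("source", "target")
  igraph::graph_from_data_frame(
    edges[, c(first, setdiff(names(edges), first)), drop = FALSE],
    directed = directed
  )
}

#' Export a network as GraphML
#'
#' @param net a `grn_network` or edge data frame.
#' @param path output path.
#' @param directed logical (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, directed = TRUE) {
  igraph::write_graph(as_igraph(net, directed), path, format = "graphml")
  invisible(path)
}
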