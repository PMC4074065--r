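# Shared fixtures, all generated in code.

# small scored edge table with known structure
toy_records <- function() {
  data.frame(
    source = c("A", "B", "C", "A", "D"),
    target = c("B", "C", "D", "C", "A"),
    confidence = c(0.9, 0.45, 0.2, 0.6, 0.05),
    jaccard = c(0.5, 0.0, 0.25, 0.8, 0.0),
    sign_call = c("activating", "activating", "inhibiting", "unclear", "activating"),
    stringsAsFactors = FALSE
  )
}

toy_expr <- function(scaled = FALSE) {
  v <- rbind(
    g1 = c(2, 4, 6),
    g2 = c(1, 1, 1),
    g3 = c(0, 0.5, 1)
  )
  colnames(v) <- paste0("S", 1:3)
  grn_expr(v, scaled = scaled)
}

# deterministic partition over genes A..F: {A,B,C}, {D,E}, {F}
toy_partition <- function() {
  cc <- structure(list(
    genes = LETTERS[1:6],
    coincidence = diag(6),
    n_runs = 10L
  ), class = "grn_coclust")
  dimnames(cc$coincidence) <- list(cc$genes, cc$genes)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5))) {
    cc$coincidence[p[1], p[2]] <- cc$coincidence[p[2], p[1]] <- 0.9
  }
  partition_clusters(cc, 0.7)
}

expect_setequal_pairs <- function(df, keys) {
  expect_setequal(paste(pmin(df$source, df$target),
                        pmax(df$source, df$target)), keys)
}
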