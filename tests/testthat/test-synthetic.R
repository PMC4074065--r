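test_that("truth generator contracts: signs, determinism, no self-edges", {
  tr <- make_truth_network(5, 1, activation_fraction = 1, seed = 1)
  expect_true(all(tr$edges$sign == "activation"))
  tr2 <- make_truth_network(30, 2, seed = 7)
  tr3 <- make_truth_network(30, 2, seed = 7)
  expect_identical(tr2, tr3)
  expect_true(all(tr2$edges$source != tr2$edges$target))
  expect_true(all(c(tr2$edges$source, tr2$edges$target) %in% tr2$genes))
  expect_error(make_truth_network(4, 1), "at least 5")
})

test_that("degree distribution is heavy-tailed (max > 3x median) at n = 60", {
  hits <- vapply(1:20, function(s) {
    tr <- make_truth_network(60, 3, seed = s)
    deg <- table(c(tr$edges$source, tr$edges$target))
    deg <- as.numeric(deg[tr$genes]); deg[is.na(deg)] <- 0
    max(deg) > 3 * median(deg)
  }, logical(1))
  expect_true(all(hits))
})

test_that("timecourse: scaling bounds, root/non-root starts, decay example", {
  tr <- make_truth_network(12, 2, seed = 2)
  m <- simulate_timecourse(tr, n_stages = 9, noise_sd = 0, seed = 2)
  expect_equal(unname(apply(m$values, 1, min)), rep(0, 12))
  expect_equal(unname(apply(m$values, 1, max)), rep(1, 12))
  # roots decay from their maximum: scaled value 1 at stage 1
  expect_true(all(m$values[tr$roots, 1] == 1))
  # determinism
  m2 <- simulate_timecourse(tr, n_stages = 9, noise_sd = 0, seed = 2)
  expect_identical(m$values, m2$values)
  expect_error(simulate_timecourse(tr, n_stages = 2), "at least 3")
})

test_that("a regulator-free gene with zero basal decays monotonically", {
  # build a 5-gene truth and strip all edges into gene 5, zero its basal by
  # making it a root (roots have ~zero basal and start high)
  tr <- make_truth_network(6, 1, seed = 3)
  tr$edges <- tr$edges[tr$edges$target != "G001", , drop = FALSE]
  m <- simulate_timecourse(tr, n_stages = 9, noise_sd = 0, seed = 3)
  prof <- m$values["G001", ]  # G001 is a root: high start, no regulators
  expect_true(all(diff(prof) <= 1e-9))
})

test_that("noise calibration: residual SD vs noiseless run within [0.02, 0.10]", {
  res_sd <- vapply(1:12, function(s) {
    tr <- make_truth_network(10, 1.5, seed = s)
    noisy <- simulate_timecourse(tr, 9, noise_sd = 0.05, seed = 100 + s)
    clean <- attr(noisy, "noiseless")
    pop_sd(as.vector(noisy$values - clean))
  }, numeric(1))
  expect_true(mean(res_sd) > 0.02 && mean(res_sd) < 0.10)
  expect_true(all(res_sd > 0.015 & res_sd < 0.12))
})

test_that("planted modules correlate above 0.95 at noise 0.05", {
  # with nine stages the sample correlation of a truly co-expressed pair
  # fluctuates a few hundredths around its population value, so the 0.95
  # property is asserted across seeds with one excursion allowed (never
  # below 0.90)
  mins <- vapply(1:10, function(s) {
    ds <- make_synthetic_dataset(n_genes = 14, mean_degree = 1.5,
                                 module_sizes = 4, noise_sd = 0.05, seed = s)
    mod <- ds$modules[[1]]
    cm <- cor(t(ds$expression$values[mod, ]))
    min(cm[upper.tri(cm)])
  }, numeric(1))
  expect_gte(sum(mins > 0.95), 9)
  expect_true(all(mins > 0.90))
})

test_that("annotation generator honors forced overlap regimes", {
  tr <- make_truth_network(15, 2, seed = 4)
  # zero_overlap_target = 0: every true pair overlaps
  ann0 <- make_annotations(tr, zero_overlap_target = 0, vocab_size = 300,
                           seed = 4)
  keys <- undirected_truth(tr)
  ab <- strsplit(keys, "\r", fixed = TRUE)
  j0 <- vapply(ab, function(p) jaccard_index(ann0[[p[1]]], ann0[[p[2]]]),
               numeric(1))
  expect_true(all(j0 > 0))
  # share_prob = 0 with singleton clusters and disjoint blocks: all pairs 0
  annz <- make_annotations(tr, share_prob = 0, vocab_size = 300, seed = 4)
  jz <- vapply(ab, function(p) jaccard_index(annz[[p[1]]], annz[[p[2]]]),
               numeric(1))
  expect_true(all(jz == 0))
  expect_error(make_annotations(tr, vocab_size = 3), "vocab_size")
})

test_that("zero-overlap calibration lands near the target over seeds", {
  fr <- vapply(1:20, function(s) {
    tr <- make_truth_network(40, 2, seed = s)
    ann <- make_annotations(tr, zero_overlap_target = 0.37, vocab_size = 800,
                            seed = s)
    attr(ann, "zero_overlap_realized")
  }, numeric(1))
  expect_true(all(abs(fr - 0.37) <= 0.1))
})

test_that("reference composition: identity, disjoint decoys, bookkeeping", {
  tr <- make_truth_network(12, 2, seed = 5)
  und <- undirected_truth(tr)
  ref_full <- make_reference(tr, coverage = 1, n_decoys = 0, seed = 5)
  expect_setequal(paste(ref_full$gene_a, ref_full$gene_b),
                  sub("\r", " ", und, fixed = TRUE))
  ref_decoy <- make_reference(tr, coverage = 0, n_decoys = 3, seed = 5)
  expect_equal(nrow(ref_decoy), 3L)
  dk <- paste(ref_decoy$gene_a, ref_decoy$gene_b)
  expect_false(any(dk %in% sub("\r", " ", und, fixed = TRUE)))
  # recorded true-positive count equals the exact intersection
  ref <- make_reference(tr, coverage = 0.5, n_decoys = 4, seed = 6)
  keys <- with(ref, pmin(gene_a, gene_b) == gene_a)
  inter <- sum(paste(ref$gene_a, ref$gene_b) %in% sub("\r", " ", und, fixed = TRUE))
  expect_equal(attr(ref, "n_true"), inter)
  expect_equal(sum(ref$is_true), inter)
  expect_error(make_reference(tr, coverage = 0, n_decoys = 1e6), "non-edges")
})

test_that("enriched preset on a 50-gene truth lands near 283 reference pairs", {
  tr <- make_truth_network(50, 6, seed = 8)
  ref <- make_reference(tr, preset = "enriched", seed = 8)
  expect_gte(nrow(ref), 250)
  expect_lte(nrow(ref), 320)
  refd <- make_reference(tr, preset = "depleted", seed = 8)
  expect_equal(sum(refd$is_true), 3L)
})

test_that("datasets are byte-identical across reruns with one seed", {
  d1 <- make_synthetic_dataset(n_genes = 12, mean_degree = 2,
                               module_sizes = 3, seed = 99)
  d2 <- make_synthetic_dataset(n_genes = 12, mean_degree = 2,
                               module_sizes = 3, seed = 99)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$reference, d2$reference)
  # and writes regenerable artifacts
  dir <- tempfile()
  write_dataset(d1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("expression.tsv", "annotations.tsv", "truth_edges.tsv",
      "reference_edges.tsv", "config.json")))))
  m <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(m$values, d1$expression$values)
})
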