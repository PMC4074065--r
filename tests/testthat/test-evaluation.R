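# Exhaustive enumeration oracle for the hypergeometric upper tail.
enum_hyper_tail <- function(N, K, n, x) {
  pop <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= x)
}

test_that("hypergeometric upper tail equals exhaustive enumeration for N <= 12", {
  set.seed(5)
  cases <- 0
  for (N in c(5, 8, 10, 12)) {
    for (rep in 1:6) {
      K <- sample(1:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      x <- sample(0:min(n, K), 1)
      expect_equal(hypergeometric_significance(N, K, n, x),
                   enum_hyper_tail(N, K, n, x), tolerance = 1e-10)
      cases <- cases + 1
    }
  }
  expect_equal(cases, 24)
  # worked case from first principles
  expect_equal(hypergeometric_significance(10, 4, 5, 4),
               enum_hyper_tail(10, 4, 5, 4), tolerance = 1e-10)
})

test_that("hypergeometric boundary conventions", {
  expect_equal(hypergeometric_significance(20, 5, 7, 0), 1)  # P(X >= 0) = 1
  expect_equal(hypergeometric_significance(10, 4, 10, 4), 1) # n = N forces x = K
  expect_error(hypergeometric_significance(10, 12, 5, 2), "impossible")
  expect_error(hypergeometric_significance(10, 4, 5, 6), "impossible")
})

test_that("to_undirected keeps the max score across directions", {
  rec <- data.frame(source = c("A", "B", "C"), target = c("B", "A", "D"),
                    confidence = c(0.4, 0.7, 0.2))
  out <- to_undirected(rec, "confidence")
  expect_equal(nrow(out), 2L)
  ab <- out[out$source %in% c("A", "B") & out$target %in% c("A", "B"), ]
  expect_equal(ab$confidence, 0.7)
  expect_lte(nrow(out), nrow(rec))
})

test_that("curves: perfect ranking gives unit AUCs, baseline precision is K/N", {
  genes <- paste0("g", 1:8)
  ref <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"))
  rec <- data.frame(source = c("g1", "g2", "g4", "g5"),
                    target = c("g2", "g3", "g5", "g6"),
                    confidence = c(0.9, 0.8, 0.2, 0.1))
  cv <- evaluate_curves(rec, ref, genes, score = "confidence")
  expect_equal(cv$auroc, 1)
  expect_equal(cv$aupr, 1)
  expect_equal(cv$baseline_precision, 2 / choose(8, 2))
  # single-threshold call: precision at full recall equals baseline
  rec2 <- rec; rec2$confidence <- 0.5
  cv2 <- evaluate_curves(rec2, ref, genes, score = "confidence")
  expect_equal(cv2$pr_points$precision[nrow(cv2$pr_points)],
               cv2$baseline_precision)
})

test_that("random scores give AUROC near 0.5 and match pROC", {
  skip_if_not_installed("pROC")
  set.seed(9)
  genes <- sprintf("g%03d", 1:50)  # 1225 pairs
  pairs <- t(combn(genes, 2))
  truth <- sample(nrow(pairs), 100)
  ref <- data.frame(a = pairs[truth, 1], b = pairs[truth, 2])
  rec <- data.frame(source = pairs[, 1], target = pairs[, 2],
                    confidence = runif(nrow(pairs)))
  cv <- evaluate_curves(rec, ref, genes, score = "confidence")
  expect_gt(cv$auroc, 0.4); expect_lt(cv$auroc, 0.6)
  # independent oracle: pROC AUC on the same population
  lab <- seq_len(nrow(pairs)) %in% truth
  oracle <- as.numeric(pROC::auc(pROC::roc(lab, rec$confidence,
                                           quiet = TRUE, direction = "<")))
  expect_equal(cv$auroc, oracle, tolerance = 1e-9)
})

test_that("topk enrichment counts hits with deterministic tie-breaks", {
  rec <- data.frame(source = c("A", "B", "C", "D"),
                    target = c("B", "C", "D", "E"),
                    confidence = c(0.9, 0.9, 0.5, 0.1))
  ref <- data.frame(a = c("A", "C"), b = c("B", "D"))
  out <- topk_enrichment(rec, ref, ks = c(1, 2, 3, 4), score = "confidence")
  # ties at 0.9: A-B before B-C lexicographically
  expect_equal(out$fraction, c(1, 1 / 2, 2 / 3, 2 / 4))
  expect_error(topk_enrichment(rec, ref, ks = 10, score = "confidence"),
               "exceeds")
})

test_that("significance_vs_cutoff sweeps filters and flags empty sets", {
  rec <- score_fidelity(toy_records(), w = 1)
  ref <- data.frame(a = "A", b = "B")
  out <- significance_vs_cutoff(rec, ref, cutoffs = c(-Inf, 0, 100))
  expect_equal(nrow(out), 3L)
  expect_true(out$empty[3])
  expect_equal(out$p_value[3], 1)
  # retained counts are non-increasing along the sweep
  expect_true(all(diff(out$n_called) <= 0))
  # a cutoff retaining only true positives is near-minimal p
  rec2 <- rec
  rec2$z_w <- ifelse(paste(rec$source, rec$target) == "A B", 10, -10)
  out2 <- significance_vs_cutoff(rec2, ref, cutoffs = 5)
  expect_lt(out2$p_value, 0.2)  # 1 / choose(4,2) population draw
})

test_that("call fraction and recall helpers reproduce headline arithmetic", {
  expect_equal(edge_call_fraction(12084, 171), 12084 / 14535)
  expect_equal(reference_recall(323, 396), 323 / 396)
})
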