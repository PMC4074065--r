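test_that("pure decay matches the closed form exactly", {
  md <- dynamics_model("g", basal = 0, v_max = 0, decay = 0.7)
  tr <- simulate_dynamics(md, 1, 0:8)
  expect_equal(tr, exp(-0.7 * (0:8)), tolerance = 1e-12)
})

test_that("saturated production approaches v_max / d", {
  # large basal drive saturates the production term at v_max
  md <- dynamics_model("g", basal = 1e6, v_max = 1.2, decay = 0.6)
  tr <- simulate_dynamics(md, 0, seq(0, 20, by = 1))
  expect_equal(tr[21], 1.2 / 0.6, tolerance = 1e-4)
})

test_that("single constant activator matches the analytic linear ODE", {
  prof <- matrix(1, 1, 9, dimnames = list("r", paste0("S", 1:9)))
  md <- dynamics_model("g", activators = c(r = 2), basal = 0, v_max = 1.5,
                       decay = 0.9, hill = 1)
  tr <- simulate_dynamics(md, 0.1, 0:8, prof)
  kappa <- 1.5 * 2 / (1 + 2)
  analytic <- kappa / 0.9 + (0.1 - kappa / 0.9) * exp(-0.9 * (0:8))
  expect_equal(tr, analytic, tolerance = 1e-6)
})

test_that("weighted error definition and acceptance boundary", {
  obs <- c(0.1, 0.5, 0.9)
  expect_equal(weighted_error(obs, obs, 0.01), 0)
  # off by exactly 1 sigma everywhere: error 1.0 (> 0.75, rejected)
  sig <- 0.1
  expect_equal(weighted_error(obs + sig, obs, sig^2), 1)
  # off by 0.8 sigma everywhere: 0.64 (< 0.75, accepted)
  expect_equal(weighted_error(obs + 0.8 * sig, obs, sig^2), 0.64)
  # nonpositive variances replaced by the floor
  expect_message(e <- weighted_error(obs, obs + 0.1, c(0, 0.01, 0.01),
                                     var_floor = 0.01), "floor")
  expect_equal(e, 1)
  expect_error(weighted_error(1:3, 1:4), "mismatch")
})

test_that("model constructor enforces the regulator contract", {
  expect_error(dynamics_model("g", activators = c(r = 1), inhibitors = c(r = 1)),
               "both")
  expect_error(dynamics_model("g", decay = -1), "nonnegative")
})

test_that("ensemble members re-simulate below the acceptance threshold", {
  ds <- make_synthetic_dataset(n_genes = 10, mean_degree = 1.5,
                               feedback_fraction = 0, noise_sd = 0, seed = 3)
  m <- ds$expression
  cfg <- ensemble_config(k_max = 2, cap = 10, budget = 60, n_starts = 2)
  tgt <- setdiff(gene_ids(m), ds$truth$roots)[1]
  ens <- build_ensemble(tgt, m, cfg, seed = 11)
  skip_if(length(ens$members) == 0, "no accepted members for this target")
  for (j in seq_along(ens$members)) {
    rs <- resimulate_member(ens, j, m, cfg)
    expect_lt(rs$error, cfg$threshold)
    expect_equal(rs$error, ens$members[[j]]$error, tolerance = 1e-8)
  }
})

test_that("ensemble search is deterministic and respects cap/budget", {
  ds <- make_synthetic_dataset(n_genes = 8, mean_degree = 1.5, noise_sd = 0,
                               seed = 4)
  m <- ds$expression
  cfg <- ensemble_config(k_max = 2, cap = 5, budget = 40, n_starts = 2)
  tgt <- gene_ids(m)[5]
  e1 <- build_ensemble(tgt, m, cfg, seed = 2)
  e2 <- build_ensemble(tgt, m, cfg, seed = 2)
  expect_identical(e1, e2)
  expect_lte(length(e1$members), 5L)
  # zero budget: empty ensemble plus warning
  expect_warning(e0 <- build_ensemble(tgt, m, ensemble_config(budget = 0),
                                      seed = 2), "empty ensemble")
  expect_equal(length(e0$members), 0L)
})

test_that("network sampling: forced cases and pooled frequency consistency", {
  ds <- make_synthetic_dataset(n_genes = 8, mean_degree = 1.5, noise_sd = 0,
                               seed = 5)
  m <- ds$expression
  cfg <- ensemble_config(k_max = 2, cap = 8, budget = 60, n_starts = 2)
  ens <- suppressWarnings(build_ensembles(m, cfg, seed = 9))
  nonempty <- Filter(function(e) length(e$members) > 0, ens)
  skip_if(length(nonempty) < 2, "too few non-empty ensembles")
  # single-member ensembles make all sampled networks identical
  ens1 <- structure(lapply(nonempty, function(e) {
    e$members <- e$members[1]; e
  }), class = "grn_ensembles")
  nw1 <- sample_networks(ens1, 50, seed = 1)
  expect_true(all(nw1$draws == 1L))
  st1 <- edge_statistics(nw1)
  expect_true(all(st1$confidence == 1 | st1$confidence == 0))
  # pooled sampling frequency matches ensemble member frequency within
  # binomial error at n = 10,000 (3 SDs)
  nw <- sample_networks(structure(nonempty, class = "grn_ensembles"),
                        10000, seed = 2)
  st <- edge_statistics(nw)
  for (tgt in names(nonempty)[1:2]) {
    fr <- ensemble_frequencies(nonempty[[tgt]])
    agg <- tapply(fr$frequency, fr$regulator, sum)  # both signs pooled
    for (reg in names(agg)) {
      p <- agg[[reg]]
      got <- st$confidence[st$source == reg & st$target == tgt]
      got <- if (length(got)) got else 0
      expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-9)
    }
  }
  # all-empty ensembles are fatal
  empty <- structure(list(a = list(target = "a", members = list(), attempts = 0L)),
                     class = "grn_ensembles")
  expect_error(sample_networks(empty, 10, seed = 1), "empty")
})

test_that("edge statistics call signs by the 2/3 majority rule", {
  mk_member <- function(act = character(), inh = character()) {
    list(activators = setNames(rep(1, length(act)), act),
         inhibitors = setNames(rep(1, length(inh)), inh),
         basal = 0.1, v_max = 1, decay = 1, hill = 2, error = 0.1)
  }
  ens <- structure(list(
    T1 = structure(list(target = "T1",
                        members = list(mk_member(act = "R1"),
                                       mk_member(act = "R1"),
                                       mk_member(inh = "R1"),
                                       mk_member(inh = "R1"))),
                   class = "grn_ensemble")
  ), class = "grn_ensembles")
  nw <- sample_networks(ens, 400, seed = 3)
  st <- edge_statistics(nw)
  # 50/50 split: unclear
  expect_equal(st$sign_call[st$source == "R1"], "unclear")
  expect_equal(st$frac_activation + st$frac_inhibition, 1)
  # always-activating edge in every member: confidence 1, activating
  ens2 <- structure(list(
    T1 = structure(list(target = "T1",
                        members = list(mk_member(act = "R2"),
                                       mk_member(act = c("R2", "R3")))),
                   class = "grn_ensemble")
  ), class = "grn_ensembles")
  st2 <- edge_statistics(sample_networks(ens2, 200, seed = 4))
  r2 <- st2[st2$source == "R2", ]
  expect_equal(r2$confidence, 1)
  expect_equal(r2$sign_call, "activating")
})
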