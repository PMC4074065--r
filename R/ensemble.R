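# Ensemble subnetwork inference: for each target gene, search small regulator
# subsets whose fitted dynamics reproduce the observed profile within the
# acceptance threshold; sample whole putative networks from the per-gene
# ensembles and collect edge frequency / sign statistics.

#' Search configuration for ensemble inference
#'
#' @param k_max maximum regulators per subnetwork (default 3; nine stages
#'   cannot constrain many more).
#' @param cap maximum accepted members per ensemble (the study's ensembles
#'   ranged from 50 to 2,000).
#' @param budget maximum fit attempts per target.
#' @param threshold acceptance threshold on the variance-weighted error
#'   (default 0.75).
#' @param n_starts random optimizer starts per regulator subset.
#' @param hill Hill exponent, fixed (default 2).
#' @param n_sub integration substeps per stage interval.
#' @param var_floor variance floor for the weighted error (default 0.01,
#'   i.e. `(0.1 * dynamic range)^2` on row-scaled data).
#' @param variances optional per-stage variances overriding the floor.
#' @param allow_self allow self-regulation (default `FALSE`).
#' @param optim_maxit Nelder-Mead iteration cap per start.
#' @return a list of class `grn_search_config`.
#' @export
ensemble_config <- function(k_max = 3L, cap = 100L, budget = 500L,
                            threshold = 0.75, n_starts = 3L, hill = 2,
                            n_sub = 20L, var_floor = 0.01, variances = NULL,
                            allow_self = FALSE, optim_maxit = 120L) {
  structure(
    list(k_max = as.integer(k_max), cap = as.integer(cap),
         budget = as.integer(budget), threshold = threshold,
         n_starts = as.integer(n_starts), hill = hill,
         n_sub = as.integer(n_sub), var_floor = var_floor,
         variances = variances, allow_self = isTRUE(allow_self),
         optim_maxit = as.integer(optim_maxit)),
    class = "grn_search_config"
  )
}

# Random log-scale start for (a_1..a_k, c_..., b, vmax, d).
random_start <- function(n_act, n_inh) {
  c(log(runif(n_act, 0.2, 8)), log(runif(n_inh, 0.2, 8)),
    log(runif(1, 0.01, 1)), log(runif(1, 0.2, 2.5)), log(runif(1, 0.1, 2.5)))
}

fit_subset <- function(UA, UC, x0, dt, n_sub, obs, vars, cfg) {
  n_act <- ncol(UA); n_inh <- ncol(UC)
  obj <- function(theta) {
    p <- pmin(exp(theta), 1e3)
    fit_error_cpp(UA, UC,
                  p[seq_len(n_act)],
                  p[n_act + seq_len(n_inh)],
                  p[n_act + n_inh + 1L], p[n_act + n_inh + 2L],
                  p[n_act + n_inh + 3L],
                  x0, dt, n_sub, obs, vars)
  }
  best <- NULL
  for (s in seq_len(cfg$n_starts)) {
    th0 <- random_start(n_act, n_inh)
    fit <- optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = cfg$optim_maxit, reltol = 1e-6))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- pmin(exp(best$par), 1e3)
  list(a = p[seq_len(n_act)], c = p[n_act + seq_len(n_inh)],
       basal = p[n_act + n_inh + 1L], v_max = p[n_act + n_inh + 2L],
       decay = p[n_act + n_inh + 3L], error = best$value)
}

#' Build the subnetwork ensemble for one target gene
#'
#' Repeatedly draws a regulator subset (size uniform on `1..k_max`), draws a
#' sign (activator/inhibitor) for each regulator, fits the remaining model
#' parameters by bounded multi-start Nelder-Mead on the log scale, and
#' accepts the subnetwork when the variance-weighted error falls below the
#' threshold. Stops at the ensemble cap or the attempt budget. Deterministic
#' for a given seed.
#'
#' @param target target gene id.
#' @param m a row-scaled [grn_expr].
#' @param cfg an [ensemble_config()].
#' @param seed integer seed for this target's search stream.
#' @param grid optional precomputed regulator grid (internal; shared across
#'   targets by [build_ensembles()]).
#' @return an object of class `grn_ensemble`: list with `target`, `members`
#'   (each holding activators, inhibitors, parameters and error), `attempts`.
#'   An empty ensemble (with a warning) is returned when nothing is accepted
#'   within the budget.
#' @export
build_ensemble <- function(target, m, cfg = ensemble_config(), seed = 1L,
                           grid = NULL) {
  if (!target %in% gene_ids(m)) stop_invalid("unknown target gene: ", target)
  times <- seq_len(ncol(m$values)) - 1
  U <- grid %||% regulator_grid(m$values, times, cfg$hill, cfg$n_sub)
  obs <- m$values[target, ]
  vars <- rep_len(cfg$variances %||% cfg$var_floor, length(obs))
  vars[vars <= 0] <- cfg$var_floor
  pool <- if (cfg$allow_self) gene_ids(m) else setdiff(gene_ids(m), target)
  dt <- 1 / cfg$n_sub
  members <- list()
  attempts <- 0L
  with_seed(seed, {
    while (length(members) < cfg$cap && attempts < cfg$budget) {
      attempts <- attempts + 1L
      k <- sample.int(min(cfg$k_max, length(pool)), 1L)
      regs <- sample(pool, k)
      is_act <- runif(k) < 0.5
      acts <- regs[is_act]; inhs <- regs[!is_act]
      fit <- fit_subset(U[, acts, drop = FALSE], U[, inhs, drop = FALSE],
                        obs[1], dt, cfg$n_sub, obs, vars, cfg)
      if (is.finite(fit$error) && fit$error < cfg$threshold) {
        members[[length(members) + 1L]] <- list(
          activators = setNames(fit$a, acts),
          inhibitors = setNames(fit$c, inhs),
          basal = fit$basal, v_max = fit$v_max, decay = fit$decay,
          hill = cfg$hill, error = fit$error
        )
      }
    }
  })
  if (!length(members)) {
    warning("empty ensemble for ", target, ": no accepted subnetwork within budget")
  }
  structure(list(target = target, members = members, attempts = attempts),
            class = "grn_ensemble")
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat(sprintf("<grn_ensemble> target %s: %d accepted member(s) in %d attempt(s)\n",
              x$target, length(x$members), x$attempts))
  invisible(x)
}

#' Regulator frequencies within one ensemble
#'
#' The fraction of ensemble members containing each regulator, split by
#' sign — the per-target confidence bar of the inference output.
#'
#' @param ens a `grn_ensemble`.
#' @return data frame with `regulator`, `sign`, `frequency`.
#' @export
ensemble_frequencies <- function(ens) {
  n <- length(ens$members)
  if (!n) {
    return(data.frame(regulator = character(), sign = character(),
                      frequency = numeric()))
  }
  tab <- list()
  for (mem in ens$members) {
    for (r in names(mem$activators)) {
      key <- paste0(r, "+"); tab[[key]] <- (tab[[key]] %||% 0) + 1
    }
    for (r in names(mem$inhibitors)) {
      key <- paste0(r, "-"); tab[[key]] <- (tab[[key]] %||% 0) + 1
    }
  }
  keys <- names(tab)
  out <- data.frame(
    regulator = substr(keys, 1L, nchar(keys) - 1L),
    sign = ifelse(substring(keys, nchar(keys)) == "+", "activation", "inhibition"),
    frequency = unlist(tab, use.names = FALSE) / n,
    stringsAsFactors = FALSE
  )
  out[order(-out$frequency, out$regulator), , drop = FALSE]
}

#' Build ensembles for every gene in the matrix
#'
#' Per-gene search streams are derived from the master seed by gene rank, so
#' results are independent of execution order.
#'
#' @param m a row-scaled [grn_expr].
#' @param cfg an [ensemble_config()].
#' @param seed master seed.
#' @param targets genes to process (default: all).
#' @return named list of `grn_ensemble` objects, class `grn_ensembles`.
#' @export
build_ensembles <- function(m, cfg = ensemble_config(), seed = 1L,
                            targets = gene_ids(m)) {
  times <- seq_len(ncol(m$values)) - 1
  U <- regulator_grid(m$values, times, cfg$hill, cfg$n_sub)
  ord <- sort(gene_ids(m))
  out <- lapply(targets, function(g) {
    build_ensemble(g, m, cfg, seed = derive_seed(seed, match(g, ord)), grid = U)
  })
  names(out) <- targets
  structure(out, class = "grn_ensembles")
}

#' Sample whole putative networks from the ensembles
#'
#' Each putative network takes one uniformly drawn member from every
#' non-empty ensemble; the study sampled 1,000 such networks.
#'
#' @param ensembles a `grn_ensembles` list.
#' @param n_networks number of putative networks (default 1000).
#' @param seed integer seed.
#' @return object of class `grn_networks` holding the member draws.
#' @export
sample_networks <- function(ensembles, n_networks = 1000L, seed = 1L) {
  sizes <- vapply(ensembles, function(e) length(e$members), integer(1))
  if (all(sizes == 0L)) stop("all ensembles are empty; nothing to sample")
  draws <- with_seed(seed, {
    vapply(sizes, function(s) {
      if (s == 0L) rep(NA_integer_, n_networks) else sample.int(s, n_networks, replace = TRUE)
    }, integer(n_networks))
  })
  draws <- matrix(draws, nrow = n_networks,
                  dimnames = list(NULL, names(ensembles)))
  structure(list(draws = draws, ensembles = ensembles,
                 n_networks = as.integer(n_networks)),
            class = "grn_networks")
}

#' Edge statistics pooled over sampled putative networks
#'
#' For every directed regulator-target pair ever observed: `confidence` is
#' the fraction of sampled networks containing the edge; sign fractions are
#' computed over its appearances; `sign_call` is `"activating"` when the
#' activation fraction reaches `sign_majority` (default 2/3), `"inhibiting"`
#' symmetrically, `"unclear"` otherwise.
#'
#' @param networks a `grn_networks` from [sample_networks()].
#' @param sign_majority majority fraction required to call a sign.
#' @return data frame with `source`, `target`, `confidence`,
#'   `frac_activation`, `frac_inhibition`, `sign_call`.
#' @export
edge_statistics <- function(networks, sign_majority = 2 / 3) {
  stopifnot(inherits(networks, "grn_networks"))
  nn <- networks$n_networks
  rows <- list()
  for (tgt in colnames(networks$draws)) {
    ens <- networks$ensembles[[tgt]]
    if (!length(ens$members)) next
    cnt <- tabulate(networks$draws[, tgt], nbins = length(ens$members))
    act <- list(); inh <- list()
    for (j in seq_along(ens$members)) {
      if (cnt[j] == 0L) next
      mem <- ens$members[[j]]
      for (r in names(mem$activators)) act[[r]] <- (act[[r]] %||% 0) + cnt[j]
      for (r in names(mem$inhibitors)) inh[[r]] <- (inh[[r]] %||% 0) + cnt[j]
    }
    srcs <- union(names(act), names(inh))
    if (!length(srcs)) next
    a <- vapply(srcs, function(r) act[[r]] %||% 0, numeric(1))
    i <- vapply(srcs, function(r) inh[[r]] %||% 0, numeric(1))
    occ <- a + i
    rows[[tgt]] <- data.frame(
      source = srcs, target = tgt,
      confidence = occ / nn,
      frac_activation = a / occ, frac_inhibition = i / occ,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) {
    return(data.frame(source = character(), target = character(),
                      confidence = numeric(), frac_activation = numeric(),
                      frac_inhibition = numeric(), sign_call = character()))
  }
  out$sign_call <- ifelse(out$frac_activation >= sign_majority, "activating",
                   ifelse(out$frac_inhibition >= sign_majority, "inhibiting",
                          "unclear"))
  out <- out[order(out$target, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-simulate one stored ensemble member
#'
#' Rebuilds the dynamics model of a stored member and recomputes its
#' trajectory and variance-weighted error — the round-trip consistency check.
#'
#' @param ens a `grn_ensemble`.
#' @param j member index.
#' @param m the row-scaled [grn_expr] used for inference.
#' @param cfg the [ensemble_config()] used for inference.
#' @return list with `trajectory` and `error`.
#' @export
resimulate_member <- function(ens, j, m, cfg = ensemble_config()) {
  mem <- ens$members[[j]]
  model <- dynamics_model(ens$target, mem$activators, mem$inhibitors,
                          mem$basal, mem$v_max, mem$decay, mem$hill)
  times <- seq_len(ncol(m$values)) - 1
  tr <- simulate_dynamics(model, m$values[ens$target, 1], times,
                          m$values, n_sub = cfg$n_sub)
  vars <- rep_len(cfg$variances %||% cfg$var_floor, length(times))
  list(trajectory = tr,
       error = weighted_error(tr, m$values[ens$target, ], vars, cfg$var_floor))
}

#' Write ensembles as a TSV dump
#'
#' One row per accepted member: target, member id, signed regulators
#' (`+` activator, `-` inhibitor), fitted parameters and the
#' variance-weighted error.
#'
#' @param ensembles a `grn_ensembles` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensembles <- function(ensembles, path) {
  rows <- lapply(ensembles, function(ens) {
    if (!length(ens$members)) return(NULL)
    do.call(rbind, lapply(seq_along(ens$members), function(j) {
      mem <- ens$members[[j]]
      regs <- c(paste0(names(mem$activators), "+"),
                paste0(names(mem$inhibitors), "-"))
      weights <- c(mem$activators, mem$inhibitors)
      data.frame(
        target = ens$target, member_id = j,
        regulators = paste(regs, collapse = ","),
        weights = paste(signif(weights, 6), collapse = ","),
        basal = mem$basal, v_max = mem$v_max, decay = mem$decay,
        hill = mem$hill, error = mem$error,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, unname(rows))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
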