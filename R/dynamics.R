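# Single-target gene expression dynamics: saturable activation/inhibition
# competition with first-order decay, driven by interpolated regulator
# profiles. This is the model family used both for ensemble inference and
# (in coupled form) by the synthetic-data generator.

#' Construct a single-target dynamics model
#'
#' The target's production rate saturates in its regulators:
#' \deqn{dx/dt = v_{max}\frac{b + \sum_A a_j u_j(t)^h}
#'   {1 + b + \sum_A a_j u_j(t)^h + \sum_I c_j u_j(t)^h} - d\,x}
#' where \eqn{u_j(t)} are the (linearly interpolated) regulator profiles.
#' Activators and inhibitors compete through the shared denominator.
#'
#' @param target target gene id.
#' @param activators named nonnegative weights `a_j` (names are regulator ids).
#' @param inhibitors named nonnegative weights `c_j`.
#' @param basal basal production term `b >= 0`.
#' @param v_max production scale `>= 0`.
#' @param decay first-order decay rate `d >= 0`.
#' @param hill Hill exponent `h >= 1` applied to regulator profiles
#'   (fixed, not fitted; default 2).
#' @return an object of class `grn_model`.
#' @export
dynamics_model <- function(target, activators = numeric(), inhibitors = numeric(),
                           basal = 0, v_max = 1, decay = 1, hill = 2) {
  if (length(intersect(names(activators), names(inhibitors)))) {
    stop_invalid("a regulator cannot be both activator and inhibitor")
  }
  if (any(c(activators, inhibitors, basal, v_max, decay) < 0) || hill < 1) {
    stop_invalid("model parameters must be nonnegative (hill >= 1)")
  }
  structure(
    list(target = target, activators = activators, inhibitors = inhibitors,
         basal = basal, v_max = v_max, decay = decay, hill = hill),
    class = "grn_model"
  )
}

# Regulator signals u^h evaluated at substep midpoints by linear
# interpolation of the observed profiles. profiles: genes x stages matrix
# with times as column positions.
regulator_grid <- function(profiles, times, hill, n_sub) {
  n_int <- length(times) - 1L
  mids <- as.vector(vapply(seq_len(n_int), function(i) {
    times[i] + (seq_len(n_sub) - 0.5) * (times[i + 1L] - times[i]) / n_sub
  }, numeric(n_sub)))
  U <- vapply(seq_len(nrow(profiles)), function(g) {
    approx(times, profiles[g, ], xout = mids)$y
  }, numeric(length(mids)))
  colnames(U) <- rownames(profiles)
  U^hill
}

#' Simulate a target gene's trajectory
#'
#' Integrates the [dynamics_model()] ODE for one target, with all regulator
#' profiles linearly interpolated between observed stages. Integration uses
#' an exact linear update on substeps with production held constant per
#' substep (the equation is linear in `x` given the inputs), so pure-decay
#' and constant-input cases are reproduced to machine accuracy.
#'
#' @param model a [dynamics_model()].
#' @param initial expression value at `times[1]`.
#' @param times ordered pseudo-times of the observed stages.
#' @param regulator_profiles genes-by-stages matrix of regulator profiles
#'   (rownames must cover the model's regulators) evaluated at `times`.
#' @param n_sub integration substeps per stage interval (default 20).
#' @return numeric trajectory at `times`.
#' @export
simulate_dynamics <- function(model, initial, times, regulator_profiles = NULL,
                              n_sub = 20L) {
  if (is.unsorted(times, strictly = TRUE)) stop_invalid("`times` must be increasing")
  regs <- c(names(model$activators), names(model$inhibitors))
  if (length(regs)) {
    if (is.null(regulator_profiles) || !all(regs %in% rownames(regulator_profiles))) {
      stop_invalid("regulator profiles missing for: ",
                   paste(setdiff(regs, rownames(regulator_profiles)), collapse = ", "))
    }
    U <- regulator_grid(regulator_profiles[regs, , drop = FALSE], times,
                        model$hill, n_sub)
  } else {
    U <- matrix(0, nrow = (length(times) - 1L) * n_sub, ncol = 0L)
  }
  dt <- diff(times)[1] / n_sub
  if (any(abs(diff(times) - diff(times)[1]) > 1e-9)) {
    stop_invalid("stages must be equally spaced pseudo-times")
  }
  UA <- U[, names(model$activators), drop = FALSE]
  UC <- U[, names(model$inhibitors), drop = FALSE]
  tr <- sim_traj_cpp(UA, UC, unname(model$activators), unname(model$inhibitors),
                     model$basal, model$v_max, model$decay,
                     initial, dt, as.integer(n_sub), length(times))
  if (!all(is.finite(tr))) {
    attr(tr, "nonfinite") <- TRUE
  }
  tr
}

#' Variance-weighted least-squares error
#'
#' \deqn{E = \frac{1}{T}\sum_t (x_{sim}(t) - x_{obs}(t))^2 / \sigma_t^2}
#' A simulation is "data-consistent" when this error is below the acceptance
#' threshold (default 0.75). Nonpositive variances are replaced by
#' `var_floor` with a message.
#'
#' @param trajectory simulated values at the observed stages.
#' @param observed observed profile (same length).
#' @param variances per-stage variances `sigma_t^2`; a scalar is recycled.
#'   Defaults to the global floor.
#' @param var_floor variance floor, default `(0.1 * dynamic range)^2` on
#'   row-scaled data, i.e. 0.01.
#' @return scalar error.
#' @export
weighted_error <- function(trajectory, observed, variances = NULL,
                           var_floor = 0.01) {
  if (length(trajectory) != length(observed)) stop_invalid("length mismatch")
  v <- rep_len(variances %||% var_floor, length(observed))
  if (any(v <= 0)) {
    message("nonpositive variances replaced by floor ", var_floor)
    v[v <= 0] <- var_floor
  }
  mean((trajectory - observed)^2 / v)
}
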