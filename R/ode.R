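#' Deterministic drift of the frequency dynamics
#'
#' Time derivative of the genotype-phenotype frequency tensor in the
#' infinite-population limit: selection against the mean fitness, mutation
#' upon replication, spontaneous mutation (with phenotype re-drawn through the
#' new genotype's noise tensor), phenotype noise at birth, and stochastic
#' phenotype switching. Genetic drift is a finite-N effect and is realized only
#' through the serial-dilution simulator, never here.
#'
#' The replication terms collapse to a single flux
#' `sum_{h,k} X(k) f[h,k] mu[h,g] phi[g,k,p] - f[g,p] * Xbar`,
#' since the no-mutation diagonal of `repl_mutation` carries both the pure
#' selection and the phenotype-noise-at-birth terms.
#'
#' @param f G x P matrix of frequencies on the simplex (sum 1 within 1e-8).
#' @param model a [prgp_model()].
#' @return G x P matrix of time derivatives; entries sum to 0.
#' @export
propgen_rhs <- function(f, model) {
  f <- as_freq_matrix(f, model)
  s <- sum(f)
  if (abs(s - 1) > 1e-8) {
    stop(sprintf("frequency state off the simplex: sum = %.12g", s), call. = FALSE)
  }
  X <- model$fitness
  MU <- model$repl_mutation
  PHI <- model$phenotype_noise
  G <- n_genotypes(model)
  P <- n_phenotypes(model)

  xbar <- sum(sweep(f, 2, X, `*`))
  # W[g, k] = X(k) * sum_h mu[h, g] f[h, k]
  W <- sweep(crossprod(MU, f), 2, X, `*`)
  out <- matrix(0, G, P)
  for (g in seq_len(G)) out[g, ] <- W[g, ] %*% PHI[g, , ]
  out <- out - f * xbar

  if (any(model$spont_rate > 0)) {
    R <- model$spont_rate
    Mm <- model$spont_mutation
    V <- sweep(crossprod(Mm, f), 2, R, `*`) # V[g,k] = R(k) sum_{h!=g} m[h,g] f[h,k]
    sp <- matrix(0, G, P)
    for (g in seq_len(G)) sp[g, ] <- V[g, ] %*% PHI[g, , ]
    out <- out + sp - sweep(f, 2, R, `*`)
  }
  if (any(model$sps_rate > 0)) {
    S <- model$sps_rate
    SIG <- model$sps_matrix
    sw <- matrix(0, G, P)
    fs <- sweep(f, 2, S, `*`)
    for (g in seq_len(G)) sw[g, ] <- fs[g, ] %*% SIG[g, , ]
    out <- out + sw - fs
  }
  dimnames(out) <- list(model$genotypes, model$phenotypes)
  out
}

as_freq_matrix <- function(f, model) {
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  if (is.matrix(f)) {
    stopifnot(nrow(f) == G, ncol(f) == P)
    f
  } else {
    stopifnot(length(f) == G * P)
    matrix(as.numeric(f), G, P)
  }
}

#' Frequency-weighted mean fitness
#'
#' @param f G x P frequency matrix on the simplex.
#' @param model a [prgp_model()].
#' @return scalar `sum_{g,p} f[g,p] X(p)`.
#' @export
mean_fitness <- function(f, model) {
  f <- as_freq_matrix(f, model)
  sum(sweep(f, 2, model$fitness, `*`))
}

#' Integrate the deterministic frequency dynamics
#'
#' Adaptive high-order integration (lsoda, relative tolerance 1e-10) of
#' [propgen_rhs()] from an initial state on the simplex. Recorded states are
#' renormalized onto the simplex; the accumulated normalization drift is
#' asserted to stay below 1e-9 per unit time. The mean fitness is recorded
#' alongside the frequencies.
#'
#' @param model a [prgp_model()].
#' @param f0 initial G x P frequency matrix (or vector of length G*P).
#' @param t_max final time, > 0.
#' @param record_every spacing of recorded times (default `t_max / 400`).
#' @param rtol,atol solver tolerances.
#' @return a `propgen_trajectory` (see [new_trajectory()]) with
#'   `trial = "ode"`.
#' @export
propgen_integrate <- function(model, f0, t_max, record_every = t_max / 400,
                              rtol = 1e-10, atol = 1e-12) {
  stopifnot(t_max > 0)
  f0 <- as_freq_matrix(f0, model)
  if (abs(sum(f0) - 1) > 1e-8) stop("`f0` must lie on the simplex", call. = FALSE)
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  times <- unique(c(seq(0, t_max, by = record_every), t_max))
  deriv <- function(t, y, parms) {
    # renormalize the solver's internal state: the dynamics conserve the sum,
    # so this only removes accumulated roundoff drift
    s <- sum(y)
    if (abs(s - 1) > 1e-4) {
      stop(sprintf("solver state left the simplex (sum %.6g)", s), call. = FALSE)
    }
    list(as.vector(propgen_rhs(matrix(y / s, G, P), model)))
  }
  sol <- deSolve::ode(
    y = as.vector(f0), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf(
      "integration failed at t = %.6g (last good state retained in message attr)",
      sol[nrow(sol), 1]
    ), call. = FALSE)
  }
  states <- sol[, -1, drop = FALSE]
  sums <- rowSums(states)
  drift <- max(abs(sums - 1)) / (t_max + 1)
  if (drift > 1e-9) {
    stop(sprintf("simplex drift %.3g per unit time exceeds 1e-9", drift), call. = FALSE)
  }
  states <- states / sums
  nt <- nrow(states)
  freq <- array(states, c(nt, G, P))
  xbar <- as.vector(states %*% as.vector(matrix(rep(model$fitness, each = G), G, P)))
  new_trajectory(
    time = sol[, 1], dilution = rep(NA_integer_, nt), freq = freq,
    mean_fitness = xbar, trial = "ode", model = model, dt = NA_real_,
    N = NA_real_, seed = NA_integer_
  )
}

#' Deterministic equilibrium by integration plus fixed-point polish
#'
#' Integrates the dynamics to `t_max` and then applies a damped Picard
#' iteration `f <- normalize(f + eta * rhs(f))` until the residual norm drops
#' below `tol`.
#'
#' @param model a [prgp_model()].
#' @param f0 initial state (default uniform).
#' @param t_max integration horizon before polishing.
#' @param tol residual sup-norm target.
#' @param eta damping step of the polish.
#' @param max_iter iteration cap for the polish.
#' @return list with `f` (G x P equilibrium matrix), `mean_fitness`, and
#'   `residual`.
#' @export
propgen_equilibrium <- function(model, f0 = NULL, t_max = 2000, tol = 1e-13,
                                eta = NULL, max_iter = 200000) {
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  if (is.null(f0)) f0 <- matrix(1 / (G * P), G, P)
  traj <- propgen_integrate(model, f0, t_max, record_every = t_max / 4)
  f <- traj$freq[dim(traj$freq)[1], , ]
  f <- matrix(f, G, P)
  f <- f / sum(f)
  rate_scale <- max(model$fitness, model$spont_rate, model$sps_rate, 1e-12)
  if (is.null(eta)) eta <- 0.5 / rate_scale
  for (i in seq_len(max_iter)) {
    r <- propgen_rhs(f, model)
    if (max(abs(r)) < tol) break
    f <- f + eta * r
    f[f < 0] <- 0
    f <- f / sum(f)
  }
  r <- propgen_rhs(f, model)
  list(f = f, mean_fitness = mean_fitness(f, model), residual = max(abs(r)))
}
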