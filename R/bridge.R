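#' Bridge parameters for the fitness-valley model
#'
#' Parameter bundle for the four-node valley system: starting node `s`
#' (genotype 0, peak phenotype), bridge node `b` (genotype 1 on the peak
#' phenotype, reached with probability `pi`), valley node `v` (genotype 1 on
#' the valley phenotype, fitness ratio `gamma`), and ending node `e`
#' (genotype 2, peak phenotype). The derived quantity
#' `theta = pi + gamma * (1 - pi)` is the mean replication output of genotype
#' 1 relative to the peak fitness; `theta = gamma` at `pi = 0` and `theta = 1`
#' at `gamma = 1`.
#'
#' @param pi bridge mapping probability in `[0, 1]`.
#' @param gamma valley depth ratio in `(0, 1]`.
#' @param mu per-replication mutation probability.
#' @return object of class `bridge_params` with fields `pi`, `gamma`, `mu`,
#'   `theta`.
#' @export
bridge_params <- function(pi, gamma, mu) {
  check_prob(pi, "pi"); check_prob(mu, "mu")
  if (gamma <= 0 || gamma > 1) stop("`gamma` must be in (0, 1]", call. = FALSE)
  structure(
    list(pi = pi, gamma = gamma, mu = mu, theta = pi + gamma * (1 - pi)),
    class = "bridge_params"
  )
}

bridge_state_names <- function() c("s", "b", "v", "e")

#' Time derivatives of the four-node valley system
#'
#' The deterministic frequency dynamics restricted to the four nodes with
#' nonzero mapping probability, in the order `(s, b, v, e)`. The `s` and `e`
#' equations are identical in form (the system is symmetric under s <-> e
#' exchange); genotype 1 feeds both its nodes in the ratio `pi : (1 - pi)`.
#' Matches [propgen_rhs()] on the corresponding [build_bridge()] model.
#'
#' @param state 4-vector `(f_s, f_b, f_v, f_e)` on the simplex.
#' @param params a [bridge_params()].
#' @param X0 peak fitness setting the clock (default 1: dimensionless time).
#' @return 4-vector of derivatives summing to 0.
#' @export
bridge_rhs <- function(state, params, X0 = 1) {
  stopifnot(length(state) == 4)
  if (abs(sum(state) - 1) > 1e-8) {
    stop("bridge state off the simplex", call. = FALSE)
  }
  pi <- params$pi; gam <- params$gamma; mu <- params$mu
  fs <- state[1]; fb <- state[2]; fv <- state[3]; fe <- state[4]
  w <- X0 * fb + gam * X0 * fv
  xbar <- X0 * (fs + fb + fe) + gam * X0 * fv
  ds <- fs * (X0 - xbar) + mu / 2 * w - mu * X0 * fs
  de <- fe * (X0 - xbar) + mu / 2 * w - mu * X0 * fe
  db <- pi * w - fb * xbar + pi * mu * X0 * (fs + fe) - pi * mu * w
  dv <- (1 - pi) * w - fv * xbar + (1 - pi) * mu * X0 * (fs + fe) - (1 - pi) * mu * w
  stats::setNames(c(ds, db, dv, de), bridge_state_names())
}

#' Exact equilibrium of the valley system
#'
#' The equilibrium genotype-1 mass `z = f_b + f_v` solves the quadratic
#' `(1 - theta) z^2 - ((1 - theta) + mu (1 + theta)) z + mu = 0` (smaller
#' root), from which `f_b = pi z`, `f_v = (1 - pi) z`, and
#' `f_s = f_e = (1 - z) / 2` by the s <-> e symmetry. The returned state is
#' verified to satisfy `||bridge_rhs|| < 1e-12`.
#'
#' @param params a [bridge_params()] with `mu > 0` or `pi > 0` (otherwise the
#'   equilibrium reached from confined starts is not unique).
#' @return named 4-vector `(s, b, v, e)`.
#' @export
bridge_equilibrium <- function(params) {
  if (params$mu <= 0 && params$pi <= 0) {
    stop("equilibrium not unique when mu = 0 and pi = 0", call. = FALSE)
  }
  th <- params$theta; mu <- params$mu
  if (1 - th < 1e-14) {
    z <- if (mu > 0) 0.5 else 1 # flat landscape: genotype flux balance
  } else if (mu == 0) {
    z <- 0
  } else {
    b <- (1 - th) + mu * (1 + th)
    z <- (b - sqrt(b^2 - 4 * mu * (1 - th))) / (2 * (1 - th))
  }
  st <- stats::setNames(
    c((1 - z) / 2, params$pi * z, (1 - params$pi) * z, (1 - z) / 2),
    bridge_state_names()
  )
  res <- max(abs(bridge_rhs(st, params)))
  if (res > 1e-12) {
    stop(sprintf("equilibrium residual %.3g exceeds 1e-12", res), call. = FALSE)
  }
  st
}

#' Analytical bridge equilibration time constant
#'
#' Exact reciprocal of the slowest relaxation rate toward the valley-system
#' equilibrium, in units where `X0 = 1`:
#' `tau = 2 / (sqrt((1 + theta)^2 (1 - mu)^2 - 4 theta (1 - 2 mu))
#'             - (1 - theta)(1 - mu))`.
#' The slow mode is the antisymmetric `f_s - f_e` imbalance, whose decay rate
#' is `Xbar_eq - (1 - mu)`; at `mu = 0` the denominator vanishes and
#' `tau = Inf` (no crossing in the deterministic infinite-population limit),
#' and at `gamma = 1` (`theta = 1`) the formula reduces to `tau = 1 / mu`.
#'
#' @param params a [bridge_params()] with `mu` in `[0, 0.5)`.
#' @return time constant (dimensionless; divide by `X0` for model time, or by
#'   `X0 * dt` for dilution counts).
#' @export
tau_theory <- function(params) {
  th <- params$theta; mu <- params$mu
  if (mu == 0 && th < 1) return(Inf) # denominator vanishes algebraically
  disc <- (1 + th)^2 * (1 - mu)^2 - 4 * th * (1 - 2 * mu)
  if (disc < 0) {
    stop(sprintf("negative discriminant %.3g: parameters outside valid range", disc),
         call. = FALSE)
  }
  den <- sqrt(disc) - (1 - th) * (1 - mu)
  if (den <= 0) return(Inf)
  2 / den
}

#' Bridge time constant from the linearized dynamics
#'
#' Independent numerical route: central-difference Jacobian of [bridge_rhs()]
#' at [bridge_equilibrium()], projected onto the tangent space of the simplex
#' (the zero mode along the normalization constraint is removed by the
#' projection), eigendecomposed; returns the reciprocal of the
#' smallest-magnitude decaying rate.
#'
#' @param params a [bridge_params()].
#' @param h finite-difference step.
#' @return time constant in units where `X0 = 1`.
#' @export
tau_jacobian <- function(params, h = 1e-7) {
  feq <- bridge_equilibrium(params)
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    ep <- feq; em <- feq
    ep[j] <- ep[j] + h
    em[j] <- em[j] - h
    # off-simplex by h: evaluate the algebraic rhs without the simplex guard
    J[, j] <- (bridge_rhs_raw(ep, params) - bridge_rhs_raw(em, params)) / (2 * h)
  }
  V <- qr.Q(qr(cbind(rep(1, 4), diag(4)[, 1:3])))[, 2:4]
  ev <- eigen(t(V) %*% J %*% V, only.values = TRUE)$values
  if (any(abs(Im(ev)) > 1e-8 * (abs(Re(ev)) + 1e-12))) {
    stop("complex slow mode encountered in bridge Jacobian", call. = FALSE)
  }
  re <- Re(ev)
  if (all(re >= 0)) return(Inf)
  1 / min(abs(re[re < 0]))
}

bridge_rhs_raw <- function(state, params, X0 = 1) {
  pi <- params$pi; gam <- params$gamma; mu <- params$mu
  fs <- state[1]; fb <- state[2]; fv <- state[3]; fe <- state[4]
  w <- X0 * fb + gam * X0 * fv
  xbar <- X0 * (fs + fb + fe) + gam * X0 * fv
  c(
    fs * (X0 - xbar) + mu / 2 * w - mu * X0 * fs,
    pi * w - fb * xbar + pi * mu * X0 * (fs + fe) - pi * mu * w,
    (1 - pi) * w - fv * xbar + (1 - pi) * mu * X0 * (fs + fe) - (1 - pi) * mu * w,
    fe * (X0 - xbar) + mu / 2 * w - mu * X0 * fe
  )
}

#' Integrate the valley system
#'
#' Convenience wrapper integrating [bridge_rhs()] with lsoda at tight
#' tolerances, starting by default from a population confined to node `s`.
#'
#' @param params a [bridge_params()].
#' @param t_max final dimensionless time.
#' @param f0 initial 4-vector (default `(1, 0, 0, 0)`).
#' @param n_record number of recorded times.
#' @return data frame with columns `time, s, b, v, e`.
#' @export
bridge_integrate <- function(params, t_max, f0 = c(1, 0, 0, 0), n_record = 400) {
  times <- seq(0, t_max, length.out = n_record)
  sol <- deSolve::ode(
    y = f0, times = times,
    # renormalize the solver state: the flow conserves the sum, so this only
    # strips accumulated roundoff drift
    func = function(t, y, p) list(bridge_rhs_raw(y / sum(y), params)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  out <- as.data.frame(sol)
  names(out) <- c("time", bridge_state_names())
  out
}

#' Empirical bridge time constant from a trajectory
#'
#' Fits the rising occupancy of the ending node,
#' `f_e(t) = f_eq * (1 - A * exp(-t / tau))`, by nonlinear least squares. The
#' asymptote is taken from [bridge_equilibrium()] by default (it is fully
#' determined by the parameters, not fitted); `fit_asymptote = TRUE` frees it.
#' The amplitude `A` is free by default so the fit tracks the slow eigenmode
#' despite the early multi-mode transient (`f_e` leaves 0 with zero slope);
#' `fix_amplitude = TRUE` pins `A = 1`, the pure single-exponential form.
#'
#' @param time numeric vector of times.
#' @param fe ending-node frequency at those times (must rise from near 0).
#' @param params a [bridge_params()] used for the asymptote (ignored when
#'   `feq_e` is given).
#' @param feq_e optional explicit asymptote.
#' @param fix_amplitude pin the amplitude at 1 (default FALSE).
#' @param fit_asymptote free the asymptote (default FALSE).
#' @return list with `tau`, `se` (standard error), `ci` (95% interval),
#'   `amplitude`, `feq_e`, `resid_norm`, and the `nls` fit object.
#' @export
tau_empirical <- function(time, fe, params = NULL, feq_e = NULL,
                          fix_amplitude = FALSE, fit_asymptote = FALSE) {
  stopifnot(length(time) == length(fe))
  if (is.null(feq_e)) {
    if (is.null(params)) stop("provide `params` or `feq_e`", call. = FALSE)
    feq_e <- unname(bridge_equilibrium(params)["e"])
  }
  if (diff(range(fe)) < 1e-8 || stats::cor(time, fe) < 0.5) {
    stop("trajectory is flat or non-increasing: cannot fit a rise time",
         call. = FALSE)
  }
  df <- data.frame(t = time, y = fe)
  sub <- df[df$y < 0.999 * feq_e & df$t > 0, ]
  ini <- stats::coef(stats::lm(log(pmax(1 - y / feq_e, 1e-12)) ~ t, data = sub))
  tau0 <- max(-1 / ini[2], diff(range(time)) / 20)
  fit <- if (fit_asymptote) {
    minpack.lm::nlsLM(
      y ~ F * (1 - A * exp(-t / tau)), data = df,
      start = list(tau = tau0, A = min(exp(ini[1]), 2), F = feq_e)
    )
  } else if (fix_amplitude) {
    minpack.lm::nlsLM(y ~ feq_e * (1 - exp(-t / tau)), data = df,
                      start = list(tau = tau0))
  } else {
    minpack.lm::nlsLM(
      y ~ feq_e * (1 - A * exp(-t / tau)), data = df,
      start = list(tau = tau0, A = min(exp(ini[1]), 2))
    )
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["tau"]], error = function(e) NA_real_)
  list(
    tau = unname(cf[["tau"]]),
    se = se,
    ci = unname(cf[["tau"]]) + c(-1, 1) * 1.96 * se,
    amplitude = if (fix_amplitude) 1 else unname(cf[["A"]]),
    feq_e = if (fit_asymptote) unname(cf[["F"]]) else feq_e,
    resid_norm = sqrt(sum(stats::resid(fit)^2)),
    fit = fit
  )
}

#' Ending-node frequency from a general bridge-model trajectory
#'
#' Maps a trajectory of the [build_bridge()] model (3 genotypes x 2
#' phenotypes) onto one of the four live valley-system nodes.
#'
#' @param traj a `propgen_trajectory` of a bridge model.
#' @param node one of `"s"`, `"b"`, `"v"`, `"e"`.
#' @return numeric vector of that node's frequency over time.
#' @export
bridge_node_freq <- function(traj, node = c("e", "s", "b", "v")) {
  node <- match.arg(node)
  idx <- switch(node, s = c(1, 1), b = c(2, 1), v = c(2, 2), e = c(3, 1))
  traj$freq[, idx[1], idx[2]]
}
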