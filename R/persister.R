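#' Persister resuscitation parameters
#'
#' Parameters of the four-compartment resuscitation model: dormant persisters
#' (P) wake at the time-varying rate `S(t) = alpha * exp(beta * t)` and switch
#' into one of three resuscitated phenotypes with probabilities `sigma` —
#' damaged-but-replicating (D), failed (F), or healthy (H). Damaged cells
#' replicate at rate `X_D` and each offspring is healthy with probability
#' `phi_DH` (phenotype noise at birth riding on replication, as opposed to the
#' lifetime switching `S(t)` which is fitness-independent); healthy cells
#' replicate at rate `X_H`. No bottleneck is imposed, so dynamics are written
#' for absolute abundances and there is no mean-fitness term.
#'
#' @param alpha,beta resuscitation-rate parameters, both > 0.
#' @param sigma length-3 probability vector `c(D, F, H)` of switching targets,
#'   summing to 1.
#' @param X_D,X_H Malthusian fitnesses of damaged and healthy cells
#'   (`X_H > 0`, `X_D >= 0`).
#' @param phi_DH probability that a damaged cell's offspring is healthy.
#' @param n0 initial abundances `c(P, D, F, H)`.
#' @return object of class `persister_params`.
#' @export
persister_params <- function(alpha, beta, sigma, X_D, X_H, phi_DH,
                             n0 = c(P = 1, D = 0, F = 0, H = 0)) {
  stopifnot(alpha > 0, beta > 0, X_H > 0, X_D >= 0)
  check_prob(phi_DH, "phi_DH")
  sigma <- as.numeric(sigma)
  if (length(sigma) != 3 || any(sigma < 0) || abs(sum(sigma) - 1) > 1e-12) {
    stop("`sigma` must be 3 probabilities (D, F, H) summing to 1", call. = FALSE)
  }
  n0 <- as.numeric(n0)
  if (length(n0) != 4 || any(n0 < 0)) {
    stop("`n0` must be 4 non-negative abundances (P, D, F, H)", call. = FALSE)
  }
  structure(
    list(
      alpha = alpha, beta = beta,
      sigma_PD = sigma[1], sigma_PF = sigma[2], sigma_PH = sigma[3],
      X_D = X_D, X_H = X_H, phi_DH = phi_DH,
      n0 = stats::setNames(n0, c("P", "D", "F", "H"))
    ),
    class = "persister_params"
  )
}

#' Derived shorthand quantities of the persister solution
#'
#' @param params a [persister_params()].
#' @return list with `a = X_D (1 - phi_DH)` (net damaged growth rate),
#'   `c = alpha / beta`, `q_D = 1 - a / beta`, `q_H = 1 - X_H / beta`,
#'   `k = X_D phi_DH / (X_H - a)` (infinite at the removable `X_H = a`
#'   point), and `B = sigma_PH + k * sigma_PD`.
#' @export
persister_derived <- function(params) {
  a <- params$X_D * (1 - params$phi_DH)
  k <- params$X_D * params$phi_DH / (params$X_H - a)
  list(
    a = a, c = params$alpha / params$beta,
    q_D = 1 - a / params$beta, q_H = 1 - params$X_H / params$beta,
    k = k, B = params$sigma_PH + k * params$sigma_PD
  )
}

#' Time derivatives of the persister system
#'
#' The four coupled rates: `dP/dt = -S(t) P` (always <= 0),
#' `dD/dt = a D + S(t) sigma_PD P`, `dF/dt = S(t) sigma_PF P` (always >= 0),
#' `dH/dt = X_H H + X_D phi_DH D + S(t) sigma_PH P`, with
#' `S(t) = alpha exp(beta t)` and `a = X_D (1 - phi_DH)`.
#'
#' @param t time.
#' @param n 4-vector of abundances `(P, D, F, H)`, componentwise >= 0.
#' @param params a [persister_params()].
#' @return named 4-vector of derivatives.
#' @export
persister_rhs <- function(t, n, params) {
  if (any(n < -1e-8)) stop("negative abundance", call. = FALSE)
  n <- pmax(n, 0) # absorb solver-level rounding below the error threshold
  S <- params$alpha * exp(params$beta * t)
  a <- params$X_D * (1 - params$phi_DH)
  stats::setNames(c(
    -S * n[1],
    a * n[2] + S * params$sigma_PD * n[1],
    S * params$sigma_PF * n[1],
    params$X_H * n[4] + params$X_D * params$phi_DH * n[2] + S * params$sigma_PH * n[1]
  ), c("P", "D", "F", "H"))
}

# Difference of lower incomplete gamma functions gamma(q, x2) - gamma(q, x1),
# valid for any real q as long as 0 < x1 <= x2 (the integral
# int_{x1}^{x2} t^{q-1} e^{-t} dt converges for all real q). For q
# comfortably positive the regularized-gamma route is used; otherwise adaptive
# quadrature of the log-domain integrand.
inc_gamma_diff <- function(q, x1, x2) {
  stopifnot(x1 > 0, x2 >= x1)
  if (x2 == x1) return(0)
  if (q > 0.01) {
    # upper-tail form is accurate when both regularized values are near 1
    exp(lgamma(q)) * (stats::pgamma(x1, q, lower.tail = FALSE) -
                        stats::pgamma(x2, q, lower.tail = FALSE))
  } else {
    upper <- min(x2, max(x1, 1) + 800) # integrand underflows beyond e^-800
    if (upper <= x1) return(0)
    stats::integrate(
      function(x) exp((q - 1) * log(x) - x), x1, upper,
      rel.tol = 1e-11, abs.tol = 0, subdivisions = 400L
    )$value
  }
}

# I_r(t) = int_0^t exp(-r s) S(s) nP(s)/nP(0) ds
#        = alpha/beta * e^c * c^{-q} * [gamma(q, c e^{bt}) - gamma(q, c)]
# with q = 1 - r/beta; evaluated through inc_gamma_diff.
persister_switch_integral <- function(r, t, params) {
  b <- params$beta
  cc <- params$alpha / b
  q <- 1 - r / b
  pref <- cc^(1 - q) * exp(cc) # alpha/beta * c^{-q}
  pref * inc_gamma_diff(q, cc, cc * exp(b * t))
}

#' Closed-form persister trajectories
#'
#' Exact solution of the persister system: `n_P(t) = n_P(0) exp(-c (e^{beta
#' t} - 1))` with `c = alpha / beta`; `n_F(t) = n_F(0) + sigma_PF (n_P(0) -
#' n_P(t))`; `n_D` and `n_H` combine exponentials with differences of lower
#' incomplete gamma functions `gamma(q, c e^{beta t}) - gamma(q, c)`,
#' evaluated stably for any real order (including q <= 0) as definite
#' integrals. The removable singularity at `X_H = a = X_D (1 - phi_DH)` is
#' handled by evaluating `n_H` through its exact variation-of-constants
#' integral (the analytic limit), not by perturbing parameters.
#'
#' @param t_grid non-negative times at which to evaluate.
#' @param params a [persister_params()].
#' @return object of class `persister_solution`: data frame with columns
#'   `time, nP, nD, nF, nH`.
#' @export
persister_closed_form <- function(t_grid, params) {
  stopifnot(all(t_grid >= 0))
  d <- persister_derived(params)
  a <- d$a
  cc <- d$c
  b <- params$beta
  n0 <- params$n0
  sPD <- params$sigma_PD; sPF <- params$sigma_PF; sPH <- params$sigma_PH

  nP <- n0[["P"]] * exp(-cc * (exp(b * t_grid) - 1))
  nF <- n0[["F"]] + sPF * (n0[["P"]] - nP)
  ID <- vapply(t_grid, function(t) persister_switch_integral(a, t, params), numeric(1))
  nD <- exp(a * t_grid) * (n0[["D"]] + sPD * n0[["P"]] * ID)

  if (abs(params$X_H - a) > 1e-8 * max(params$X_H, a, b)) {
    k <- d$k
    IH <- vapply(t_grid, function(t) persister_switch_integral(params$X_H, t, params),
                 numeric(1))
    nH <- exp(params$X_H * t_grid) * (n0[["H"]] + k * n0[["D"]] + d$B * n0[["P"]] * IH) -
      k * nD
  } else {
    # X_H -> a limit: n_H(t) = e^{X_H t} [n_H(0) + int_0^t e^{-X_H s}
    #   (X_D phi_DH n_D(s) + S(s) sigma_PH n_P(s)) ds]
    nD_of <- function(s) {
      exp(a * s) * (n0[["D"]] + sPD * n0[["P"]] *
                      persister_switch_integral(a, s, params))
    }
    integrand <- function(s) {
      exp(-params$X_H * s) * (
        params$X_D * params$phi_DH * nD_of(s) +
          params$alpha * exp(b * s) * sPH * n0[["P"]] * exp(-cc * (exp(b * s) - 1))
      )
    }
    nH <- vapply(t_grid, function(t) {
      if (t == 0) return(n0[["H"]])
      I <- stats::integrate(Vectorize(integrand), 0, t, rel.tol = 1e-10,
                            subdivisions = 400L)$value
      exp(params$X_H * t) * (n0[["H"]] + I)
    }, numeric(1))
  }
  structure(
    data.frame(time = t_grid, nP = nP, nD = nD, nF = nF, nH = nH),
    class = c("persister_solution", "data.frame")
  )
}

#' Integrate the persister system numerically
#'
#' Adaptive lsoda integration of [persister_rhs()]; the independent check on
#' the closed form.
#'
#' @param t_grid times at which to record.
#' @param params a [persister_params()].
#' @return data frame with columns `time, nP, nD, nF, nH`.
#' @export
persister_integrate <- function(t_grid, params) {
  sol <- deSolve::ode(
    y = unname(params$n0), times = t_grid,
    func = function(t, y, p) list(unname(persister_rhs(t, y, params))),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-16
  )
  out <- as.data.frame(sol)
  names(out) <- c("time", "nP", "nD", "nF", "nH")
  out
}

#' Normalize persister abundances to population fractions
#'
#' Divides each compartment by the instantaneous total (all four compartments
#' are counted in the denominator).
#'
#' @param sol a [persister_closed_form()] result or any data frame with
#'   columns `time, nP, nD, nF, nH`.
#' @return data frame with columns `time, fP, fD, fF, fH`, each row summing
#'   to 1.
#' @export
normalize_trajectories <- function(sol) {
  tot <- sol$nP + sol$nD + sol$nF + sol$nH
  if (any(tot <= 0)) stop("zero total abundance: cannot normalize", call. = FALSE)
  data.frame(
    time = sol$time,
    fP = sol$nP / tot, fD = sol$nD / tot, fF = sol$nF / tot, fH = sol$nH / tot
  )
}
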