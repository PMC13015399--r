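test_that("theta combines bridge probability and valley depth", {
  expect_equal(bridge_params(0, 0.3, 0.01)$theta, 0.3)
  expect_equal(bridge_params(0.7, 1, 0.01)$theta, 1)
  expect_equal(bridge_params(0.05, 0.5, 0.01)$theta, 0.05 + 0.5 * 0.95)
})

test_that("the four-node flow matches the general drift on the bridge model", {
  set.seed(301)
  for (i in 1:30) {
    pars <- bridge_params(runif(1), runif(1, 0.05, 1), runif(1, 0, 0.5))
    X0 <- runif(1, 0.05, 0.5)
    st <- rgamma(4, 1); st <- st / sum(st)
    r1 <- bridge_rhs(st, pars, X0 = X0)
    m <- build_bridge(pars$pi, pars$gamma, pars$mu, X0)
    r2 <- propgen_rhs(bridge_to_matrix(st), m)
    expect_lt(max(abs(unname(r1) -
                        c(r2[1, 1], r2[2, 1], r2[2, 2], r2[3, 1]))), 1e-12)
    expect_lt(abs(sum(r1)), 1e-14)
  }
})

test_that("a frozen system without mutation or bridge stays put", {
  pars <- bridge_params(0, 0.5, 0)
  r <- bridge_rhs(c(1, 0, 0, 0), pars)
  expect_equal(max(abs(r)), 0)
})

test_that("the flow preserves the start/end exchange symmetry", {
  pars <- bridge_params(0.1, 0.4, 0.05)
  st <- c(0.3, 0.15, 0.25, 0.3) # f_s = f_e
  r <- bridge_rhs(st, pars)
  expect_equal(r[["s"]], r[["e"]])
})

test_that("equilibrium satisfies the flow and the phi-ratio small-mu limit", {
  pars <- bridge_params(0.4, 0.6, 0.1)
  eq <- bridge_equilibrium(pars)
  expect_lt(max(abs(bridge_rhs(eq, pars))), 1e-12)
  expect_equal(eq[["s"]], eq[["e"]])
  # mu -> 0+: within the genotype-1 block mass splits as pi : (1 - pi)
  eq2 <- bridge_equilibrium(bridge_params(0.4, 0.6, 1e-8))
  expect_equal(eq2[["b"]] / (eq2[["b"]] + eq2[["v"]]), 0.4, tolerance = 1e-9)
  # gamma = 1: flat landscape, genotype flux balance with f_s = f_e
  eq3 <- bridge_equilibrium(bridge_params(0.3, 1, 0.05))
  expect_equal(eq3[["s"]], eq3[["e"]])
  expect_equal(sum(eq3), 1, tolerance = 1e-12)
})

test_that("analytical and Jacobian time constants agree on a parameter lattice", {
  pis <- seq(0, 0.8, length.out = 10)
  gammas <- seq(0.15, 1, length.out = 10)
  mus <- seq(0.02, 0.45, length.out = 10)
  worst <- 0
  for (pi in pis) for (gam in gammas) for (mu in mus) {
    pars <- bridge_params(pi, gam, mu)
    t1 <- tau_theory(pars)
    t2 <- tau_jacobian(pars)
    worst <- max(worst, abs(t1 - t2) / t2)
  }
  expect_lt(worst, 1e-6)
})

test_that("the no-mutation and flat-landscape limits are exact", {
  expect_identical(tau_theory(bridge_params(0.3, 0.5, 0)), Inf)
  for (mu in c(0.01, 0.1, 0.3)) {
    expect_equal(tau_theory(bridge_params(0.2, 1, mu)), 1 / mu,
                 tolerance = 1e-12)
    expect_equal(tau_jacobian(bridge_params(0.2, 1, mu)), 1 / mu,
                 tolerance = 1e-5)
  }
})

test_that("tau falls with bridge probability and rises in deeper valleys", {
  mu <- 0.05
  for (gam in c(0.2, 0.5, 0.8)) {
    taus <- vapply(c(0, 0.05, 0.1, 0.15, 0.4),
                   function(p) tau_theory(bridge_params(p, gam, mu)), numeric(1))
    expect_true(all(diff(taus) < 0))
  }
  for (p in c(0, 0.1, 0.4)) {
    taus <- vapply(c(0.8, 0.5, 0.2),
                   function(g) tau_theory(bridge_params(p, g, mu)), numeric(1))
    expect_true(all(diff(taus) > 0)) # smaller gamma -> slower crossing
  }
  # and the relative speed-up from a bridge is larger for deeper valleys
  gain <- function(g) tau_theory(bridge_params(0, g, mu)) /
    tau_theory(bridge_params(0.1, g, mu))
  expect_gt(gain(0.2), gain(0.8))
})

test_that("the fit recovers an exact exponential and flags flat input", {
  tt <- seq(0, 2000, by = 5)
  fe <- 0.35 * (1 - exp(-tt / 400))
  r <- tau_empirical(tt, fe, feq_e = 0.35)
  expect_equal(r$tau, 400, tolerance = 1e-6)
  expect_equal(r$amplitude, 1, tolerance = 1e-6)
  expect_error(tau_empirical(tt, rep(0.1, length(tt)), feq_e = 0.35), "flat")
})

test_that("trajectory fits of the integrated flow match theory within 2%", {
  for (gam in c(0.3, 0.5, 0.7)) for (pi in c(0, 0.05, 0.1, 0.15, 0.4)) {
    pars <- bridge_params(pi, gam, 0.05)
    tt <- tau_theory(pars)
    sol <- bridge_integrate(pars, t_max = 2.2 * tt, n_record = 300)
    fit <- tau_empirical(sol$time, sol$e, params = pars)
    expect_lt(abs(fit$tau - tt) / tt, 0.02)
  }
})
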