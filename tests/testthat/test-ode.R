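test_that("the drift conserves total frequency on random models and states", {
  set.seed(41)
  worst <- 0
  for (i in 1:1000) {
    G <- sample(1:4, 1); P <- sample(1:4, 1)
    m <- random_model(G, P, seed = 1e5 + i, spont = i %% 2 == 0, sps = i %% 3 == 0)
    f <- matrix(rgamma(G * P, 1), G, P)
    f <- f / sum(f)
    worst <- max(worst, abs(sum(propgen_rhs(f, m))))
  }
  expect_lt(worst, 1e-12)
})

test_that("a fixed neutral landscape has zero drift", {
  phi <- array(0, c(2, 2, 2))
  phi[1, 1, ] <- phi[1, 2, ] <- c(1, 0)
  phi[2, 1, ] <- phi[2, 2, ] <- c(0, 1)
  m <- prgp_model(c("0", "1"), c("0", "1"), fitness = c(0.1, 0.1),
                  repl_mutation = diag(2), phenotype_noise = phi)
  f <- matrix(c(0.3, 0, 0, 0.7), 2, 2)
  expect_equal(max(abs(propgen_rhs(f, m))), 0)
})

test_that("off-simplex states are rejected", {
  m <- buoy_model()
  expect_error(propgen_rhs(matrix(0.3, 2, 2), m), "off the simplex")
})

test_that("the exact 2x2 equilibrium is a fixed point of the general drift", {
  set.seed(42)
  for (i in 1:50) {
    pi0 <- runif(1); pi1 <- runif(1); mu <- runif(1)
    X0 <- runif(1, 0.02, 0.5); X1 <- runif(1, 0.01, 1) * X0
    eq <- equilibrium_2x2(pi0, pi1, mu, X0, X1)
    m <- build_two_by_two(pi0, pi1, mu, X0, X1)
    expect_lt(max(abs(propgen_rhs(as_f2x2(eq$feq), m))), 1e-10)
  }
})

test_that("integration converges to the exact equilibrium from interior starts", {
  m <- buoy_model(pi1 = 0.9)
  eq <- equilibrium_2x2(0.4, 0.9, 0.05, 0.1, 0.05)
  for (f0 in list(matrix(0.25, 2, 2), as_f2x2(c(0.7, 0.1, 0.1, 0.1)))) {
    tr <- propgen_integrate(m, f0, t_max = 1500, record_every = 50)
    fin <- tr$freq[dim(tr$freq)[1], , ]
    expect_lt(max(abs(fin - as_f2x2(eq$feq))), 1e-6)
  }
})

test_that("mutation-free deterministic selection matches the two-type closed form", {
  # each genotype locked to one phenotype: classical logistic takeover
  phi <- array(0, c(2, 2, 2))
  phi[1, 1, ] <- phi[1, 2, ] <- c(1, 0)
  phi[2, 1, ] <- phi[2, 2, ] <- c(0, 1)
  m <- prgp_model(c("0", "1"), c("0", "1"), fitness = c(0.12, 0.07),
                  repl_mutation = diag(2), phenotype_noise = phi)
  f0 <- matrix(c(0.2, 0, 0, 0.8), 2, 2)
  tr <- propgen_integrate(m, f0, t_max = 120, record_every = 2)
  expected <- 0.2 * exp(0.12 * tr$time) /
    (0.2 * exp(0.12 * tr$time) + 0.8 * exp(0.07 * tr$time))
  expect_lt(max(abs(tr$freq[, 1, 1] - expected)), 1e-8)
})

test_that("mean fitness is the frequency-weighted fitness", {
  m <- buoy_model()
  f <- as_f2x2(c(1, 0, 0, 0))
  expect_equal(mean_fitness(f, m), 0.1)
  # printed starting state of the transient mean-fitness-decrease example
  sc <- make_scenario("mean_fitness_decrease")
  expect_equal(mean_fitness(sc$init, sc$model),
               0.4 * 0.09 + 0.1 * 0.02 + 0.05 * 0.09 + 0.45 * 0.02)
  eq <- equilibrium_2x2(0.3, 0.8, 0.02, 0.2, 0.06)
  m2 <- build_two_by_two(0.3, 0.8, 0.02, 0.2, 0.06)
  expect_lt(abs(mean_fitness(as_f2x2(eq$feq), m2) - eq$Xbar_eq), 1e-10)
})

test_that("recorded trajectories stay on the simplex and track mean fitness", {
  m <- random_model(3, 2, seed = 7, spont = TRUE, sps = TRUE)
  f0 <- matrix(1 / 6, 3, 2)
  tr <- propgen_integrate(m, f0, t_max = 100, record_every = 5)
  expect_lt(max(abs(apply(tr$freq, 1, sum) - 1)), 1e-12)
  i <- length(tr$time)
  expect_equal(tr$mean_fitness[i],
               mean_fitness(matrix(tr$freq[i, , ], 3, 2), m), tolerance = 1e-9)
})
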