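# Shared fixtures built in code.

buoy_model <- function(pi1 = 0.5, mu = 0.05) {
  build_two_by_two(0.4, pi1, mu, 0.1, 0.05, N = 1e4)
}

# frequency matrix [g, p] from the 4-vector (g0p0, g0p1, g1p0, g1p1)
as_f2x2 <- function(v) matrix(v, 2, 2, byrow = TRUE)

# 4-vector (s, b, v, e) -> 3x2 frequency matrix of the bridge model
bridge_to_matrix <- function(st) {
  f <- matrix(0, 3, 2)
  f[1, 1] <- st[1]; f[2, 1] <- st[2]; f[2, 2] <- st[3]; f[3, 1] <- st[4]
  f
}

random_persister <- function() {
  s <- stats::rgamma(3, 1); s <- s / sum(s)
  persister_params(
    alpha = stats::runif(1, 0.2, 2), beta = stats::runif(1, 0.1, 2),
    sigma = s, X_D = stats::runif(1, 0, 1.5), X_H = stats::runif(1, 0.2, 2),
    phi_DH = stats::runif(1), n0 = c(stats::runif(1, 0.5, 2), 0, 0, 0)
  )
}

# componentwise relative error with a floor at 1e-9 of the instantaneous
# total, below which the reference integrator is at its own noise floor
rel_err_traj <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  tot <- rowSums(abs(b))
  max(abs(a - b) / pmax(abs(b), 1e-9 * tot))
}
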