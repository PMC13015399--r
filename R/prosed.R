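#' Probabilistic Serial Dilution simulation
#'
#' Discrete-time, agent-based simulation of evolutionary dynamics with
#' overlapping generations. Within each step of length `dt`, in order:
#' reproduction (each individual of phenotype `p` spawns one offspring with
#' probability `dt * X(p)`; parents persist), offspring genotype mutation
#' (`repl_mutation`), offspring phenotype assignment (`phenotype_noise`,
#' conditioned on the parental phenotype), spontaneous mutation of any
#' individual (probability `dt * R(p)`, new genotype from `spont_mutation`,
#' phenotype re-drawn through the new genotype's noise tensor), stochastic
#' phenotype switching (probability `dt * S(p)`, target from `sps_matrix`),
#' and finally dilution back to exactly `N` individuals by uniform sampling
#' without replacement (multivariate hypergeometric). At `dt -> 0` the
#' within-step event order is immaterial; it is fixed as listed for
#' reproducibility.
#'
#' @name prosed
NULL

#' One serial-dilution step
#'
#' Advances a population one reproduction-mutation-switching-dilution cycle.
#' Uses R's global RNG stream; seed it with [set.seed()] for reproducibility.
#'
#' @param state G x P matrix of non-negative integer counts with at least one
#'   individual.
#' @param model a [prgp_model()] with `pop_size` set (the dilution target N).
#' @param dt time step; `dt * max(fitness)`, `dt * max(spont_rate)` and
#'   `dt * max(sps_rate)` must all be <= 1.
#' @return G x P integer matrix of counts summing to `N` (or to the input
#'   total when it is below `N`).
#' @export
prosed_step <- function(state, model, dt) {
  state <- as_count_matrix(state, model)
  if (sum(state) < 1) stop("empty population", call. = FALSE)
  if (is.na(model$pop_size)) {
    stop("model has no `pop_size`; set N for simulation", call. = FALSE)
  }
  check_dt(model, dt)
  st <- prosed_step_batch(matrix(as.integer(state), ncol = 1), model, dt,
                          as.integer(model$pop_size))
  matrix(st, n_genotypes(model), n_phenotypes(model),
         dimnames = list(model$genotypes, model$phenotypes))
}

check_dt <- function(model, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  if (dt * max(model$fitness) > 1 || dt * max(model$spont_rate) > 1 ||
      dt * max(model$sps_rate) > 1) {
    stop("`dt` too large: per-step event probabilities dt*rate must be <= 1",
         call. = FALSE)
  }
  invisible(dt)
}

as_count_matrix <- function(state, model) {
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  if (is.matrix(state)) {
    stopifnot(nrow(state) == G, ncol(state) == P)
  } else {
    stopifnot(length(state) == G * P)
    state <- matrix(state, G, P)
  }
  if (any(state < 0) || any(state != round(state))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  state
}

# Core engine: columns are independent trials advanced in lock-step.
# counts: (G*P) x n_trials integer matrix, cell index (g-1)*P + p... we use
# column-major (p-1)*G + g so that matrix(v, G, P) reshapes directly.
prosed_step_batch <- function(counts, model, dt, N) {
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  Tt <- ncol(counts)
  X <- model$fitness
  MU <- model$repl_mutation
  PHI <- model$phenotype_noise
  pcell <- rep(seq_len(P), each = G) # phenotype of each cell

  # 1-3: reproduction with genotype mutation and phenotype assignment
  pvec <- dt * X[pcell]
  nb <- matrix(rbinom(length(counts), as.vector(counts), rep(pvec, Tt)),
               nrow = G * P)
  off <- matrix(0L, G * P, Tt)
  for (g in seq_len(G)) for (p in seq_len(P)) {
    ci <- (p - 1) * G + g
    rem <- nb[ci, ]
    if (all(rem == 0L)) next
    off <- scatter_offspring(off, rem, MU[g, ], PHI, p, G, P, Tt)
  }
  pool <- counts + off

  # 4: spontaneous mutation (parents and offspring alike)
  if (any(model$spont_rate > 0)) {
    R <- model$spont_rate
    Mm <- model$spont_mutation
    nm <- matrix(rbinom(length(pool), as.vector(pool), rep(dt * R[pcell], Tt)),
                 nrow = G * P)
    pool <- pool - nm
    for (g in seq_len(G)) for (p in seq_len(P)) {
      ci <- (p - 1) * G + g
      rem <- nm[ci, ]
      if (all(rem == 0L)) next
      pool <- scatter_offspring(pool, rem, Mm[g, ], PHI, p, G, P, Tt)
    }
  }

  # 5: stochastic phenotype switching
  if (any(model$sps_rate > 0)) {
    S <- model$sps_rate
    SIG <- model$sps_matrix
    ns <- matrix(rbinom(length(pool), as.vector(pool), rep(dt * S[pcell], Tt)),
                 nrow = G * P)
    pool <- pool - ns
    for (g in seq_len(G)) for (p in seq_len(P)) {
      ci <- (p - 1) * G + g
      rem <- ns[ci, ]
      if (all(rem == 0L)) next
      qtot <- 1
      for (pp in seq_len(P)) {
        q <- SIG[g, p, pp]
        if (q <= 0) next
        y <- if (qtot - q <= 1e-12) rem else rbinom(Tt, rem, q / qtot)
        rem <- rem - y
        qtot <- qtot - q
        cj <- (pp - 1) * G + g
        pool[cj, ] <- pool[cj, ] + y
      }
    }
  }

  # 6: dilution to N (uniform without replacement over individuals)
  tot <- colSums(pool)
  k <- pmin.int(tot, N)
  out <- matrix(0L, G * P, Tt)
  rem <- tot
  for (ci in seq_len(G * P)) {
    rem <- rem - pool[ci, ]
    x <- rhyper(Tt, pool[ci, ], rem, k)
    out[ci, ] <- x
    k <- k - x
  }
  out
}

# Distribute `rem` reproducing/mutating individuals of parent cell
# (genotype row `wg`, parental phenotype p) over offspring genotypes (weights
# `gw`) and phenotypes (PHI of the offspring genotype), vectorized over trials.
scatter_offspring <- function(off, rem, gw, PHI, p, G, P, Tt) {
  ptot <- 1
  for (h in seq_len(G)) {
    w <- gw[h]
    if (w <= 0) next
    x <- if (ptot - w <= 1e-12) rem else rbinom(Tt, rem, w / ptot)
    rem <- rem - x
    ptot <- ptot - w
    if (all(x == 0L)) next
    remp <- x
    qtot <- 1
    for (pp in seq_len(P)) {
      q <- PHI[h, p, pp]
      if (q <= 0) next
      y <- if (qtot - q <= 1e-12) remp else rbinom(Tt, remp, q / qtot)
      remp <- remp - y
      qtot <- qtot - q
      cj <- (pp - 1) * G + h
      off[cj, ] <- off[cj, ] + y
    }
  }
  off
}

#' Initial counts from frequencies
#'
#' Multinomially samples `N` individuals onto the genotype-phenotype cells
#' according to a frequency tensor, or passes through an integer count matrix
#' unchanged.
#'
#' @param model a [prgp_model()].
#' @param init G x P matrix of frequencies (summing to 1) or of integer counts
#'   (summing to N).
#' @param N population size.
#' @return G x P integer count matrix.
#' @export
init_counts <- function(model, init, N) {
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  init <- if (is.matrix(init)) init else matrix(init, G, P)
  if (abs(sum(init) - 1) < 1e-8) {
    matrix(as.vector(rmultinom(1, N, as.vector(init))), G, P)
  } else {
    if (sum(init) != N) stop("count init must sum to N", call. = FALSE)
    as_count_matrix(init, model)
  }
}

#' Run ProSeD trials
#'
#' Simulates `n_trials` independent serial-dilution trajectories. With
#' `engine = "serial"` (default) each trial runs on its own RNG substream with
#' a per-trial seed derived deterministically from `base_seed`, so individual
#' trials are reproducible in isolation. With `engine = "batch"` all trials
#' advance in lock-step through one vectorized stream, which is much faster
#' for large ensembles and still bitwise reproducible given `base_seed`, but
#' trials cannot be re-run individually.
#'
#' @param model a [prgp_model()] with `pop_size` set (N), unless `N` is given.
#' @param init initial state: frequency tensor (multinomially sampled to
#'   counts, independently per trial) or integer count matrix used for every
#'   trial.
#' @param n_dilutions number of dilution cycles (>= 1).
#' @param dt time step; default `1 / (2 * max(fitness))` keeps per-step
#'   reproduction probabilities below 0.5.
#' @param n_trials number of trials (>= 1).
#' @param base_seed integer seed for the whole ensemble.
#' @param record_every record the state every this many dilutions (default 1).
#' @param engine `"serial"` or `"batch"` (see Details).
#' @return list of `propgen_trajectory` objects, one per trial. Continuous
#'   time is `dilution * dt`.
#' @export
run_prosed <- function(model, init, n_dilutions, dt = NULL, n_trials = 1,
                       base_seed = 1, record_every = 1,
                       engine = c("serial", "batch")) {
  engine <- match.arg(engine)
  if (n_dilutions < 1) stop("`n_dilutions` must be >= 1", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  N <- model$pop_size
  if (is.na(N)) stop("model has no `pop_size`; set N for simulation", call. = FALSE)
  N <- as.integer(N)
  if (is.null(dt)) dt <- 1 / (2 * max(model$fitness))
  check_dt(model, dt)
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  rec_idx <- seq(0, n_dilutions, by = record_every)
  if (rec_idx[length(rec_idx)] != n_dilutions) rec_idx <- c(rec_idx, n_dilutions)
  nrec <- length(rec_idx)

  X_by_cell <- rep(model$fitness, each = G)
  make_traj <- function(counts_rec, trial, seed) {
    freq <- counts_rec / N
    xbar <- apply(sweep(counts_rec, c(2, 3), matrix(X_by_cell, G, P), `*`), 1, sum) / N
    new_trajectory(
      time = rec_idx * dt, dilution = as.integer(rec_idx), freq = freq,
      mean_fitness = xbar, trial = trial, model = model, dt = dt, N = N,
      seed = seed, counts = counts_rec
    )
  }

  if (engine == "serial") {
    set.seed(as.integer(base_seed))
    trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
    out <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      set.seed(trial_seeds[k])
      n <- init_counts(model, init, N)
      cnt <- matrix(as.integer(n), ncol = 1)
      rec <- array(0, c(nrec, G, P))
      ri <- 1
      if (rec_idx[1] == 0) { rec[1, , ] <- matrix(cnt, G, P); ri <- 2 }
      for (d in seq_len(n_dilutions)) {
        cnt <- prosed_step_batch(cnt, model, dt, N)
        if (ri <= nrec && rec_idx[ri] == d) {
          rec[ri, , ] <- matrix(cnt, G, P)
          ri <- ri + 1
        }
      }
      out[[k]] <- make_traj(rec, k, trial_seeds[k])
    }
    out
  } else {
    set.seed(as.integer(base_seed))
    cnt <- matrix(0L, G * P, n_trials)
    for (k in seq_len(n_trials)) cnt[, k] <- as.integer(init_counts(model, init, N))
    rec <- array(0, c(nrec, G * P, n_trials))
    ri <- 1
    if (rec_idx[1] == 0) { rec[1, , ] <- cnt; ri <- 2 }
    for (d in seq_len(n_dilutions)) {
      cnt <- prosed_step_batch(cnt, model, dt, N)
      if (ri <= nrec && rec_idx[ri] == d) {
        rec[ri, , ] <- cnt
        ri <- ri + 1
      }
    }
    lapply(seq_len(n_trials), function(k) {
      make_traj(array(rec[, , k], c(nrec, G, P)), k, NA_integer_)
    })
  }
}
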