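#' Scenario catalog
#'
#' Fully parameterized, runnable study configurations for the phenomena the
#' package models. Where the literature motivating a scenario does not pin a
#' number (fitness scale, mutation rate, time step, population size), the
#' catalog fills a documented default and marks the field as `"defaulted"` in
#' the scenario metadata.
#'
#' Catalog names:
#' \describe{
#'   \item{`buoy`}{two-genotype/two-phenotype competition with `pi0 = 0.4`;
#'     variant parameter `one_minus_pi1` in `{0.5, 0.4, 0.3, 0.2, 0.1}` sweeps
#'     the mapping probability of the low-fitness pair. Defaults: `X = (0.1,
#'     0.05)`, `mu = 0.05`, `dt = 1`, `N = 1e4`, 250 dilutions, 10 trials.}
#'   \item{`phase`}{phase-diagram grid at `pi0` in `{0.4, 0.5, 0.6}`.}
#'   \item{`bridge`}{fitness-valley crossing; variant parameter `pi` in
#'     `{0, 0.05, 0.1, 0.15, 0.4}`. Defaults: `gamma = 0.5`, `mu = 0.05`,
#'     `X0 = 0.1`, `dt = 0.1` (small per-step reproduction probability so the
#'     discrete-time relaxation rate matches continuous-time theory),
#'     `N = 1e4`, 100 trials.}
#'   \item{`absolute_fitness`}{deterministic vs probabilistic map under a
#'     global fitness shift `A`; variant parameter `map` in
#'     `{"deterministic", "probabilistic"}`. Defaults: `X = (0.1, 0.05)`,
#'     `A = 0.05`, `mu = 0`, `dt = 0.05`, `N = 1e4`, 50 trials.}
#'   \item{`mean_fitness_decrease`}{the mutation-free 2x2 construction in
#'     which phenotypic noise alone drives the mean fitness down transiently:
#'     `X = (0.09, 0.02)`, `phi_0(0) = 0.1`, `phi_1(0) = 0.8`, initial
#'     frequencies `(0.4, 0.1, 0.05, 0.45)`.}
#'   \item{`persister`}{reference resuscitation parameterization
#'     `alpha = 1, beta = 0.5, sigma = (0.2, 0.3, 0.5), X_D = 0.3, X_H = 1,
#'     phi_DH = 0.4, n0 = (1, 0, 0, 0)` producing the transient
#'     damaged/failed peaks.}
#' }
#'
#' @param name catalog name.
#' @param ... variant parameters (see Details).
#' @return object of class `propgen_scenario`: list with `name`, `model` (a
#'   [prgp_model()] or [persister_params()]), `init`, `dt`, `n_dilutions`,
#'   `t_max`, `n_trials`, `defaulted` (character vector naming filled-in
#'   values), and `predicates` (named list of machine-checkable functions of
#'   a result list, see [run_scenario()]).
#' @export
make_scenario <- function(name, ...) {
  args <- list(...)
  sc <- switch(
    name,
    buoy = scenario_buoy(args),
    phase = scenario_phase(args),
    bridge = scenario_bridge(args),
    absolute_fitness = scenario_absolute_fitness(args),
    mean_fitness_decrease = scenario_mean_fitness_decrease(),
    persister = scenario_persister(),
    stop(sprintf(
      "unknown scenario '%s'; catalog: %s", name,
      paste(scenario_names(), collapse = ", ")
    ), call. = FALSE)
  )
  sc$name <- name
  class(sc) <- "propgen_scenario"
  sc
}

#' @describeIn make_scenario names available in the catalog.
#' @export
scenario_names <- function() {
  c("buoy", "phase", "bridge", "absolute_fitness", "mean_fitness_decrease",
    "persister")
}

scenario_buoy <- function(args) {
  om <- args$one_minus_pi1 %||% 0.5
  stopifnot(om > 0, om < 1)
  model <- build_two_by_two(0.4, 1 - om, 0.05, 0.1, 0.05, N = 1e4)
  eq <- equilibrium_2x2(0.4, 1 - om, 0.05, 0.1, 0.05)
  list(
    model = model, init = matrix(0.25, 2, 2), dt = 1, n_dilutions = 250,
    n_trials = 10, equilibrium = eq,
    defaulted = c("X0=0.1", "X1=0.05", "mu=0.05", "dt=1", "N=1e4"),
    predicates = list(
      equilibrates_within_250 = function(res) {
        ref <- matrix(res$scenario$equilibrium$feq, 2, 2, byrow = TRUE)
        d <- detect_equilibration(res$ensemble, ref, 0.02)
        !is.na(d) && d <= 250
      },
      red_vs_blue = if (abs(om - 0.1) < 1e-9) {
        # only at 1 - pi1 = 0.1 do the red (g1p1) and blue (g0p0) pairs
        # approach each other
        function(res) {
          feq <- res$scenario$equilibrium$feq
          abs(feq[["g1p1"]] - feq[["g0p0"]]) < 0.05
        }
      } else {
        # the red pair beats blue despite lower fitness (phenotypic buoying)
        function(res) {
          feq <- res$scenario$equilibrium$feq
          feq[["g1p1"]] > feq[["g0p0"]]
        }
      }
    )
  )
}

scenario_phase <- function(args) {
  pi0 <- args$pi0 %||% 0.4
  n_grid <- args$n_grid %||% 201
  list(
    model = build_two_by_two(pi0, 0.5, 0.05, 0.1, 0.05, N = 1e4),
    init = matrix(0.25, 2, 2), dt = 1, n_dilutions = 250, n_trials = 3,
    pi0 = pi0, n_grid = n_grid,
    defaulted = c("X0=0.1", "X1=0.05", "grid offsets"),
    predicates = list(
      sector_count_bounded = function(res) count_sectors(res$diagram) <= 12
    )
  )
}

scenario_bridge <- function(args) {
  pi <- args$pi %||% 0.05
  gamma <- args$gamma %||% 0.5
  mu <- args$mu %||% 0.05
  X0 <- 0.1
  dt <- 0.05 # keeps dt * X0 = 0.005: discrete-time rate bias well below noise
  pars <- bridge_params(pi, gamma, mu)
  tau <- tau_theory(pars)
  tau_ref <- tau_theory(bridge_params(0, gamma, mu)) # slowest of the sweep
  n_dil <- ceiling(2.2 * tau / X0 / dt)
  init <- matrix(0, 3, 2)
  init[1, 1] <- 1
  list(
    model = build_bridge(pi, gamma, mu, X0, N = 1e4),
    init = init, dt = dt, n_dilutions = n_dil, n_trials = 100,
    params = pars, tau_theory = tau,
    defaulted = c("gamma=0.5", "mu=0.05", "X0=0.1", "dt=0.05", "N=1e4"),
    predicates = list(
      crossing_no_slower_than_no_bridge = function(res) {
        res$tau_hat <= tau_ref / X0 * 1.1
      }
    )
  )
}

scenario_absolute_fitness <- function(args) {
  map <- args$map %||% "probabilistic"
  A <- args$A %||% 0.05
  stopifnot(map %in% c("deterministic", "probabilistic"))
  if (map == "deterministic") {
    phi <- array(0, c(2, 2, 2))
    phi[1, 1, ] <- phi[1, 2, ] <- c(1, 0)
    phi[2, 1, ] <- phi[2, 2, ] <- c(0, 1)
    init <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  } else {
    phi <- array(0, c(2, 2, 2))
    phi[1, 1, ] <- phi[1, 2, ] <- c(0.8, 0.2)
    phi[2, 1, ] <- phi[2, 2, ] <- c(0.2, 0.8)
    init <- matrix(0.25, 2, 2)
  }
  model <- prgp_model(
    genotypes = c("0", "1"), phenotypes = c("0", "1"), fitness = c(0.1, 0.05),
    repl_mutation = diag(2), phenotype_noise = phi, pop_size = 1e4
  )
  list(
    model = model, init = init, dt = 0.05, t_max = 100,
    n_dilutions = 100 / 0.05, n_trials = 50, shift = A, map = map,
    defaulted = c("X0=0.1", "X1=0.05", "A=0.05", "phi=0.8/0.2", "dt=0.05",
                  "N=1e4"),
    predicates = list(
      shift_effect = if (map == "deterministic") {
        function(res) res$shift_supnorm < 1e-10 # ODE route: exact invariance
      } else {
        function(res) res$shift_supnorm > 1e-3
      }
    )
  )
}

scenario_mean_fitness_decrease <- function() {
  phi <- array(0, c(2, 2, 2))
  phi[1, 1, ] <- phi[1, 2, ] <- c(0.1, 0.9)
  phi[2, 1, ] <- phi[2, 2, ] <- c(0.8, 0.2)
  model <- prgp_model(
    genotypes = c("0", "1"), phenotypes = c("0", "1"), fitness = c(0.09, 0.02),
    repl_mutation = diag(2), phenotype_noise = phi, pop_size = 1e4
  )
  init <- matrix(c(0.4, 0.05, 0.1, 0.45), 2, 2) # (g0p0, g0p1; g1p0, g1p1)
  list(
    model = model, init = init, dt = 1, t_max = 400, n_dilutions = 400,
    n_trials = 10,
    defaulted = c("t_max=400"),
    predicates = list(
      mean_fitness_drops_then_recovers = function(res) {
        xb <- res$trajectory$mean_fitness
        xb[2] < xb[1] && max(xb) > xb[1] && which.min(xb) > 1 &&
          which.min(xb) < length(xb)
      },
      orange_pair_transiently_rises = function(res) {
        f01 <- res$trajectory$freq[, 1, 2]
        which.max(f01) > 1 && utils::tail(f01, 1) < max(f01)
      }
    )
  )
}

scenario_persister <- function() {
  params <- persister_params(
    alpha = 1, beta = 0.5, sigma = c(0.2, 0.3, 0.5),
    X_D = 0.3, X_H = 1, phi_DH = 0.4, n0 = c(1, 0, 0, 0)
  )
  list(
    model = params, init = params$n0, t_max = 10, dt = NA, n_dilutions = NA,
    n_trials = 1,
    defaulted = c("alpha=1", "beta=0.5", "sigma=(0.2,0.3,0.5)", "X_D=0.3",
                  "X_H=1", "phi_DH=0.4"),
    predicates = list(
      damaged_and_failed_fractions_peak = function(res) {
        fr <- res$fractions
        peaked <- function(v) {
          i <- which.max(v)
          i > 1 && i < length(v) && utils::tail(v, 1) < max(v) / 2
        }
        peaked(fr$fD) && peaked(fr$fF)
      },
      healthy_takes_over = function(res) utils::tail(res$fractions$fH, 1) > 0.9
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.propgen_scenario <- function(x, ...) {
  cat(sprintf("<propgen_scenario> %s\n", x$name))
  if (length(x$defaulted)) {
    cat("  defaulted:", paste(x$defaulted, collapse = ", "), "\n")
  }
  cat("  predicates:", paste(names(x$predicates), collapse = ", "), "\n")
  invisible(x)
}

#' Run a catalog scenario end to end
#'
#' Executes a scenario through the requested engine and returns a result list
#' that the scenario's predicates accept. ODE results carry `trajectory`;
#' ProSeD results carry `trials` and their `ensemble` statistics; the phase
#' scenario carries `diagram`; the bridge scenario carries the fitted
#' `tau_hat`; the persister scenario carries the closed-form `solution` and
#' normalized `fractions`.
#'
#' @param scenario a [make_scenario()] result.
#' @param engine `"ode"` or `"prosed"` (ignored for `phase` and `persister`,
#'   which are analytical).
#' @param seed base seed for ProSeD runs.
#' @param n_trials optional override of the scenario's trial count.
#' @return named result list (always includes `scenario`).
#' @export
run_scenario <- function(scenario, engine = c("ode", "prosed"), seed = 1,
                         n_trials = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(scenario, "propgen_scenario"))
  res <- list(scenario = scenario)
  nt <- n_trials %||% scenario$n_trials

  if (scenario$name == "persister") {
    tg <- seq(0, scenario$t_max, length.out = 400)
    sol <- if (engine == "ode") persister_integrate(tg, scenario$model) else
      persister_closed_form(tg, scenario$model)
    res$solution <- sol
    res$fractions <- normalize_trajectories(sol)
    return(res)
  }
  if (scenario$name == "phase") {
    res$diagram <- phase_diagram(scenario$pi0, n_grid = scenario$n_grid)
    return(res)
  }

  t_max <- scenario$t_max %||% (scenario$n_dilutions * scenario$dt)
  if (scenario$name == "absolute_fitness") {
    shifted <- shift_fitness(scenario$model, scenario$shift)
    if (engine == "ode") {
      tr0 <- propgen_integrate(scenario$model, scenario$init, t_max)
      tr1 <- propgen_integrate(shifted, scenario$init, t_max)
      res$trajectory <- tr0
      res$shift_supnorm <- max(abs(tr0$freq - tr1$freq))
    } else {
      e0 <- ensemble_stats(run_prosed(scenario$model, scenario$init,
                                      scenario$n_dilutions, scenario$dt,
                                      nt, seed, record_every = 20,
                                      engine = "batch"))
      e1 <- ensemble_stats(run_prosed(shifted, scenario$init,
                                      scenario$n_dilutions, scenario$dt,
                                      nt, seed + 1, record_every = 20,
                                      engine = "batch"))
      res$ensemble <- e0
      res$shift_supnorm <- max(abs(e0$mean - e1$mean))
      res$shift_se <- sqrt(e0$se^2 + e1$se^2)
    }
    return(res)
  }

  if (engine == "ode") {
    res$trajectory <- propgen_integrate(scenario$model, scenario$init, t_max)
    res$ensemble <- list(
      time = res$trajectory$time,
      # equivalent dilution count of the simulator clock
      dilution = if (is.na(scenario$dt)) res$trajectory$dilution else
        res$trajectory$time / scenario$dt,
      mean = res$trajectory$freq, se = array(0, dim(res$trajectory$freq)),
      mean_fitness = res$trajectory$mean_fitness, n_trials = 1
    )
    if (scenario$name == "bridge") {
      res$tau_hat <- tau_empirical(
        res$trajectory$time * scenario$model$fitness[1], # dimensionless clock
        bridge_node_freq(res$trajectory, "e"), params = scenario$params
      )$tau / scenario$model$fitness[1]
    }
  } else {
    rec <- if (scenario$name == "bridge") 100 else 1
    res$trials <- run_prosed(
      scenario$model, scenario$init, scenario$n_dilutions, scenario$dt, nt,
      seed, record_every = rec,
      engine = if (scenario$name == "bridge") "batch" else "serial"
    )
    res$ensemble <- ensemble_stats(res$trials)
    if (scenario$name == "bridge") {
      fe <- res$ensemble$mean[, 3, 1]
      res$tau_hat <- tau_empirical(
        res$ensemble$time * scenario$model$fitness[1], fe,
        params = scenario$params
      )$tau / scenario$model$fitness[1]
    }
  }
  res
}

#' Random probabilistic model for property tests
#'
#' Draws a valid [prgp_model()] with probability tensors sampled from
#' symmetric Dirichlet distributions and rates from documented ranges
#' (fitness in `[0.01, 0.2]`, spontaneous and switching rates in
#' `[0, 0.05]` when active). With an uncertainty flag off, the corresponding
#' tensor degenerates to its deterministic / inactive form (each
#' phenotype-noise slice a unit mass, zero mutation off-diagonal, zero
#' rates).
#'
#' @param G,P numbers of genotypes and phenotypes, >= 1.
#' @param seed integer seed; the draw is deterministic in it.
#' @param repl_mutation,phenotype_noise,spont,sps logical process flags.
#' @return a [prgp_model()].
#' @export
random_model <- function(G, P, seed, repl_mutation = TRUE,
                         phenotype_noise = TRUE, spont = FALSE, sps = FALSE) {
  stopifnot(G >= 1, P >= 1)
  set.seed(as.integer(seed))
  rdirich <- function(n) {
    x <- stats::rgamma(n, shape = 1)
    x / sum(x)
  }
  fitness <- stats::runif(P, 0.01, 0.2)
  MU <- diag(G)
  if (repl_mutation && G > 1) {
    MU <- t(vapply(seq_len(G), function(g) {
      w <- rdirich(G)
      # keep a majority of no-mutation mass on the diagonal
      w <- 0.2 * w
      w[g] <- w[g] + 0.8
      w
    }, numeric(G)))
  }
  PHI <- array(0, c(G, P, P))
  for (g in seq_len(G)) for (k in seq_len(P)) {
    PHI[g, k, ] <- if (phenotype_noise) rdirich(P) else {
      u <- rep(0, P)
      u[((g - 1) %% P) + 1] <- 1
      u
    }
  }
  spont_rate <- if (spont && G > 1) stats::runif(P, 0, 0.05) else rep(0, P)
  Mm <- uniform_offdiag(G)
  if (spont && G > 1) {
    Mm <- t(vapply(seq_len(G), function(g) {
      w <- rdirich(G)
      w[g] <- 0
      if (sum(w) == 0) w[-g][1] <- 1 else w <- w / sum(w)
      w
    }, numeric(G)))
  }
  sps_rate <- if (sps && P > 1) stats::runif(P, 0, 0.05) else rep(0, P)
  SIG <- array(0, c(G, P, P))
  for (g in seq_len(G)) for (k in seq_len(P)) {
    if (P == 1) next
    w <- if (sps) rdirich(P) else rep(1, P)
    w[k] <- 0
    SIG[g, k, ] <- w / sum(w)
  }
  prgp_model(
    genotypes = as.character(seq_len(G) - 1),
    phenotypes = as.character(seq_len(P) - 1),
    fitness = fitness, repl_mutation = MU, phenotype_noise = PHI,
    spont_rate = spont_rate, spont_mutation = Mm,
    sps_rate = sps_rate, sps_matrix = SIG, pop_size = 1e4
  )
}
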