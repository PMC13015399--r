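#' Probabilistic genotype-phenotype model
#'
#' Container for the full specification of an evolutionary model in which each
#' genotype maps probabilistically onto phenotypes. Individuals of phenotype
#' `p` replicate at Malthusian rate `X(p)`; offspring may mutate genotype at
#' birth (`repl_mutation`), are assigned a phenotype through the noise tensor
#' `phenotype_noise`, and during their lifetime may undergo spontaneous
#' mutation (rate `spont_rate`, targets `spont_mutation`, phenotype re-drawn
#' through the noise tensor of the new genotype) or stochastic phenotype
#' switching (rate `sps_rate`, targets `sps_matrix`).
#'
#' @param genotypes character or integer vector of genotype labels (length G).
#' @param phenotypes character or integer vector of phenotype labels (length P).
#' @param fitness numeric vector of Malthusian fitnesses, one per phenotype,
#'   all finite and >= 0.
#' @param repl_mutation G x G matrix of per-replication mutation
#'   probabilities; row `g` is the distribution of the offspring genotype given
#'   parent genotype `g` and includes the no-mutation diagonal, so every row
#'   sums to 1.
#' @param phenotype_noise G x P x P array; `phenotype_noise[g, k, p]` is the
#'   probability that an offspring of genotype `g` born to a parent of
#'   phenotype `k` is assigned phenotype `p`. Each `[g, k, ]` slice is a
#'   distribution.
#' @param spont_rate numeric vector (length P) of spontaneous mutation rates
#'   per unit time, by current phenotype. Default 0 (process off).
#' @param spont_mutation G x G matrix of spontaneous-mutation target
#'   probabilities with zero diagonal; each row sums to 1 over the off-diagonal
#'   targets (ignored when all spontaneous rates are zero). Default: uniform
#'   over the other genotypes.
#' @param sps_rate numeric vector (length P) of phenotype switching rates per
#'   unit time, by current phenotype. Default 0 (process off).
#' @param sps_matrix G x P x P array; `sps_matrix[g, k, p]` is the probability
#'   that a switching individual of genotype `g` moves from phenotype `k` to
#'   `p`. Self-transitions are excluded: the `[g, k, k]` entries are zero and
#'   each slice sums to 1 over `p != k` (ignored when all switching rates are
#'   zero). Default: uniform over the other phenotypes.
#' @param pop_size population size N used by the serial-dilution simulator;
#'   `NA` for infinite-population (deterministic) analyses.
#' @param time_scale scalar converting dilution steps to model time units.
#'
#' @return an object of class `prgp_model`.
#' @seealso [validate_model()], [build_two_by_two()], [build_bridge()]
#' @export
prgp_model <- function(genotypes, phenotypes, fitness, repl_mutation,
                       phenotype_noise, spont_rate = NULL, spont_mutation = NULL,
                       sps_rate = NULL, sps_matrix = NULL, pop_size = NA,
                       time_scale = 1) {
  genotypes <- as.character(genotypes)
  phenotypes <- as.character(phenotypes)
  G <- length(genotypes)
  P <- length(phenotypes)
  if (is.null(spont_rate)) spont_rate <- rep(0, P)
  if (is.null(sps_rate)) sps_rate <- rep(0, P)
  if (is.null(spont_mutation)) spont_mutation <- uniform_offdiag(G)
  if (is.null(sps_matrix)) {
    sps_matrix <- array(0, c(G, P, P))
    for (g in seq_len(G)) sps_matrix[g, , ] <- uniform_offdiag(P)
  }
  fitness <- as.numeric(fitness)
  names(fitness) <- phenotypes
  m <- structure(
    list(
      genotypes = genotypes, phenotypes = phenotypes, fitness = fitness,
      repl_mutation = as_matrix_named(repl_mutation, genotypes, genotypes),
      phenotype_noise = as_gkp_array(phenotype_noise, G, P),
      spont_rate = stats::setNames(as.numeric(spont_rate), phenotypes),
      spont_mutation = as_matrix_named(spont_mutation, genotypes, genotypes),
      sps_rate = stats::setNames(as.numeric(sps_rate), phenotypes),
      sps_matrix = as_gkp_array(sps_matrix, G, P),
      pop_size = pop_size, time_scale = time_scale
    ),
    class = "prgp_model"
  )
  m
}

uniform_offdiag <- function(n) {
  if (n == 1) return(matrix(0, 1, 1))
  m <- matrix(1 / (n - 1), n, n)
  diag(m) <- 0
  m
}

as_matrix_named <- function(x, rn, cn) {
  x <- as.matrix(x)
  if (nrow(x) == length(rn) && ncol(x) == length(cn)) dimnames(x) <- list(rn, cn)
  x
}

as_gkp_array <- function(x, G, P) {
  x <- if (is.array(x)) x else array(x, c(G, P, P))
  x
}

n_genotypes <- function(model) length(model$genotypes)
n_phenotypes <- function(model) length(model$phenotypes)

#' @export
print.prgp_model <- function(x, ...) {
  cat(sprintf(
    "<prgp_model> %d genotypes x %d phenotypes\n", n_genotypes(x), n_phenotypes(x)
  ))
  cat("  fitness X(p):", paste(format(x$fitness), collapse = " "), "\n")
  active <- c(
    if (any(x$repl_mutation[row(x$repl_mutation) != col(x$repl_mutation)] > 0)) "mutation-at-birth",
    if (any(x$spont_rate > 0)) "spontaneous-mutation",
    if (any(x$sps_rate > 0)) "phenotype-switching"
  )
  cat("  active processes:", if (length(active)) paste(active, collapse = ", ") else "selection + phenotype noise only", "\n")
  if (!is.na(x$pop_size)) cat("  pop_size N:", x$pop_size, "\n")
  invisible(x)
}

#' Validate a probabilistic genotype-phenotype model
#'
#' Checks structural consistency (tensor dimensions against the genotype and
#' phenotype sets) and the probabilistic invariants: every replication-mutation
#' row sums to 1; every phenotype-noise slice sums to 1; every switching slice
#' has zero self-transition mass and sums to 1 over the other phenotypes (when
#' switching is active for that phenotype); all rates and probabilities are
#' finite and non-negative. Structural errors are reported first, before any
#' probability checks.
#'
#' @param model a [prgp_model()].
#' @param tol absolute tolerance on probability sums (default 1e-12).
#' @return character vector of violations; empty when the model is valid. Each
#'   violation names the offending index.
#' @export
validate_model <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "prgp_model"))
  G <- n_genotypes(model)
  P <- n_phenotypes(model)
  v <- character(0)

  structural <- character(0)
  if (length(model$fitness) != P) {
    structural <- c(structural, sprintf("fitness has length %d, expected P=%d", length(model$fitness), P))
  }
  if (!all(dim(model$repl_mutation) == c(G, G))) {
    structural <- c(structural, sprintf(
      "repl_mutation is %s, expected %dx%d", paste(dim(model$repl_mutation), collapse = "x"), G, G
    ))
  }
  if (!all(dim(model$phenotype_noise) == c(G, P, P))) {
    structural <- c(structural, sprintf(
      "phenotype_noise is %s, expected %dx%dx%d",
      paste(dim(model$phenotype_noise), collapse = "x"), G, P, P
    ))
  }
  if (!all(dim(model$spont_mutation) == c(G, G))) {
    structural <- c(structural, sprintf(
      "spont_mutation is %s, expected %dx%d", paste(dim(model$spont_mutation), collapse = "x"), G, G
    ))
  }
  if (!all(dim(model$sps_matrix) == c(G, P, P))) {
    structural <- c(structural, sprintf(
      "sps_matrix is %s, expected %dx%dx%d", paste(dim(model$sps_matrix), collapse = "x"), G, P, P
    ))
  }
  if (length(model$spont_rate) != P) {
    structural <- c(structural, sprintf("spont_rate has length %d, expected P=%d", length(model$spont_rate), P))
  }
  if (length(model$sps_rate) != P) {
    structural <- c(structural, sprintf("sps_rate has length %d, expected P=%d", length(model$sps_rate), P))
  }
  if (length(structural) > 0) return(structural)

  num_fields <- list(
    fitness = model$fitness, repl_mutation = model$repl_mutation,
    phenotype_noise = model$phenotype_noise, spont_rate = model$spont_rate,
    spont_mutation = model$spont_mutation, sps_rate = model$sps_rate,
    sps_matrix = model$sps_matrix
  )
  for (nm in names(num_fields)) {
    x <- num_fields[[nm]]
    if (any(!is.finite(x))) v <- c(v, sprintf("%s contains non-finite values", nm))
    if (any(x < 0, na.rm = TRUE)) v <- c(v, sprintf("%s contains negative values", nm))
  }

  rs <- rowSums(model$repl_mutation)
  for (g in which(abs(rs - 1) > tol)) {
    v <- c(v, sprintf("repl_mutation row g=%s sums to %.15g, expected 1", model$genotypes[g], rs[g]))
  }
  for (g in seq_len(G)) for (k in seq_len(P)) {
    s <- sum(model$phenotype_noise[g, k, ])
    if (abs(s - 1) > tol) {
      v <- c(v, sprintf(
        "phenotype_noise slice (g=%s, k=%s) sums to %.15g, expected 1",
        model$genotypes[g], model$phenotypes[k], s
      ))
    }
  }
  if (any(model$spont_rate > 0)) {
    dg <- diag(model$spont_mutation)
    for (g in which(abs(dg) > tol)) {
      v <- c(v, sprintf("spont_mutation has self-transition mass at g=%s", model$genotypes[g]))
    }
    rs <- rowSums(model$spont_mutation)
    for (g in which(abs(rs - 1) > tol)) {
      v <- c(v, sprintf("spont_mutation row g=%s sums to %.15g, expected 1", model$genotypes[g], rs[g]))
    }
  }
  for (g in seq_len(G)) for (k in seq_len(P)) {
    if (abs(model$sps_matrix[g, k, k]) > tol) {
      v <- c(v, sprintf(
        "sps_matrix self-transition sigma_g(k->k) nonzero at (g=%s, k=%s)",
        model$genotypes[g], model$phenotypes[k]
      ))
    }
    if (model$sps_rate[k] > 0 && P > 1) {
      s <- sum(model$sps_matrix[g, k, -k])
      if (abs(s - 1) > tol) {
        v <- c(v, sprintf(
          "sps_matrix slice (g=%s, k=%s) sums to %.15g over targets, expected 1",
          model$genotypes[g], model$phenotypes[k], s
        ))
      }
    }
  }
  if (!is.na(model$pop_size) && (model$pop_size < 1 || model$pop_size != round(model$pop_size))) {
    v <- c(v, sprintf("pop_size must be a positive integer or NA, got %s", format(model$pop_size)))
  }
  v
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1], got %s", nm, format(x)), call. = FALSE)
  }
  x
}

#' Two-genotype / two-phenotype competition model
#'
#' The minimal competition model: two genotypes, two phenotypes, symmetric
#' mutation at birth, and phenotype assignment independent of the parental
#' phenotype. `pi0` and `pi1` are the probabilities that genotypes 0 and 1 map
#' onto the fitter phenotype 0. Spontaneous mutation and lifetime phenotype
#' switching are off.
#'
#' @param pi0,pi1 mapping probabilities onto phenotype 0 for genotypes 0 and 1.
#' @param mu symmetric per-replication mutation probability between the two
#'   genotypes.
#' @param X0,X1 Malthusian fitnesses of phenotypes 0 and 1 (X0 >= X1 >= 0 by
#'   the convention that phenotype 0 is the fitter one).
#' @param N population size for simulation (default 1e4).
#' @return a [prgp_model()] with genotypes `c("0", "1")` and phenotypes
#'   `c("0", "1")`.
#' @export
build_two_by_two <- function(pi0, pi1, mu, X0, X1, N = 1e4) {
  check_prob(pi0, "pi0"); check_prob(pi1, "pi1"); check_prob(mu, "mu")
  if (!is.finite(X0) || !is.finite(X1) || X0 < 0 || X1 < 0) {
    stop("fitnesses X0, X1 must be finite and >= 0", call. = FALSE)
  }
  phi <- array(0, c(2, 2, 2))
  phi[1, 1, ] <- phi[1, 2, ] <- c(pi0, 1 - pi0)
  phi[2, 1, ] <- phi[2, 2, ] <- c(pi1, 1 - pi1)
  prgp_model(
    genotypes = c("0", "1"), phenotypes = c("0", "1"),
    fitness = c(X0, X1),
    repl_mutation = rbind(c(1 - mu, mu), c(mu, 1 - mu)),
    phenotype_noise = phi,
    pop_size = N
  )
}

#' Three-genotype fitness-valley model with a phenotypic bridge
#'
#' Genotypes 0 and 2 map deterministically onto the fitter phenotype 0
#' (fitness `X0`); the intermediate genotype 1 maps onto phenotype 0 (the
#' "bridge") with low probability `pi` and onto the valley phenotype 1
#' (fitness `gamma * X0`) otherwise. Mutation occurs at birth between genotype
#' neighbors only: genotype 1 sends probability `mu/2` to each neighbor, while
#' genotypes 0 and 2 send probability `mu` to genotype 1. At `pi = 0` this is
#' the classical deterministic fitness-valley crossing problem.
#'
#' @param pi bridge mapping probability in `[0, 1]`.
#' @param gamma valley depth ratio `X(1)/X(0)` in `(0, 1]`.
#' @param mu per-replication mutation probability in `[0, 1]`.
#' @param X0 fitness of the peak phenotype, > 0.
#' @param N population size for simulation (default 1e4).
#' @return a [prgp_model()] with genotypes `c("0", "1", "2")` and phenotypes
#'   `c("0", "1")`.
#' @export
build_bridge <- function(pi, gamma, mu, X0, N = 1e4) {
  check_prob(pi, "pi"); check_prob(mu, "mu")
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0 || gamma > 1) {
    stop("`gamma` must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(X0) || X0 <= 0) stop("`X0` must be finite and > 0", call. = FALSE)
  phi <- array(0, c(3, 2, 2))
  for (k in 1:2) {
    phi[1, k, ] <- c(1, 0)
    phi[2, k, ] <- c(pi, 1 - pi)
    phi[3, k, ] <- c(1, 0)
  }
  mu_mat <- rbind(
    c(1 - mu, mu, 0),
    c(mu / 2, 1 - mu, mu / 2),
    c(0, mu, 1 - mu)
  )
  prgp_model(
    genotypes = c("0", "1", "2"), phenotypes = c("0", "1"),
    fitness = c(X0, gamma * X0),
    repl_mutation = mu_mat,
    phenotype_noise = phi,
    pop_size = N
  )
}

#' Shift the whole fitness landscape by a constant
#'
#' Returns a copy of the model with every phenotype fitness shifted by `A`.
#' With a deterministic genotype-phenotype map and no mutation the
#' infinite-population frequency dynamics are invariant under such shifts;
#' under probabilistic mapping they are not, because phenotype reassignment at
#' birth is coupled to the absolute replication rate.
#'
#' @param model a [prgp_model()].
#' @param A fitness offset; `fitness + A` must remain >= 0.
#' @return the shifted model.
#' @export
shift_fitness <- function(model, A) {
  stopifnot(inherits(model, "prgp_model"))
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A)) {
    stop("`A` must be a finite scalar", call. = FALSE)
  }
  if (any(model$fitness + A < 0)) {
    stop("shift would produce negative fitness", call. = FALSE)
  }
  model$fitness <- model$fitness + A
  model
}

#' Is the genotype-phenotype map deterministic?
#'
#' TRUE when every phenotype-noise slice puts all its mass on a single
#' phenotype (each slice contains a 1).
#' @param model a [prgp_model()].
#' @return logical scalar.
#' @export
is_deterministic_map <- function(model) {
  all(apply(model$phenotype_noise, c(1, 2), max) > 1 - 1e-12)
}
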