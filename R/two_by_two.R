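#' Exact equilibrium of the two-genotype / two-phenotype model
#'
#' Closed-form long-time frequency distribution of the minimal competition
#' model ([build_two_by_two()]). With `alpha_g = pi_g * X0 + (1 - pi_g) * X1`
#' (the mean replication output of genotype `g`) and
#' `beta = (1 - mu) * (alpha_0 + alpha_1)`, the equilibrium mean fitness is the
#' larger root
#' `Xbar_eq = (beta + sqrt(beta^2 - 4 alpha_0 alpha_1 (1 - 2 mu))) / 2`,
#' and the equilibrium vector over the pairs (g0p0, g0p1, g1p0, g1p1) is
#' `(pi_0 w_0, (1-pi_0) w_0, pi_1 w_1, (1-pi_1) w_1) / (w_0 + w_1)` where
#' `(w_0, w_1)` is the dominant eigenvector of the 2 x 2 genotype growth
#' matrix, `w_0 = mu * alpha_1`, `w_1 = Xbar_eq - (1 - mu) * alpha_0`.
#'
#' `method = "eigen"` instead extracts the dominant eigenvector of the full
#' 4 x 4 equilibrium matrix `M[(g,p),(h,k)] = phi_g(p) mu_{h->g} X(k)`; the two
#' routes agree to numerical precision and serve as mutual checks.
#'
#' @param pi0,pi1 probabilities that genotypes 0 and 1 map onto phenotype 0.
#' @param mu symmetric per-replication mutation probability.
#' @param X0,X1 phenotype fitnesses, `X0 >= X1 > 0` by convention (phenotype 0
#'   is the fitter one).
#' @param method `"closed"` (default) or `"eigen"`.
#' @return object of class `equilibrium_2x2`: list with `feq` (named 4-vector
#'   over `g0p0, g0p1, g1p0, g1p1`), `Xbar_eq`, `params`, and `derived`
#'   (`alpha0`, `alpha1`, `beta`).
#' @export
equilibrium_2x2 <- function(pi0, pi1, mu, X0, X1, method = c("closed", "eigen")) {
  method <- match.arg(method)
  check_prob(pi0, "pi0"); check_prob(pi1, "pi1"); check_prob(mu, "mu")
  if (X0 <= 0 && X1 <= 0) stop("degenerate landscape: X0 = X1 = 0", call. = FALSE)
  a0 <- pi0 * X0 + (1 - pi0) * X1
  a1 <- pi1 * X0 + (1 - pi1) * X1
  beta <- (1 - mu) * (a0 + a1)
  disc <- beta^2 - 4 * a0 * a1 * (1 - 2 * mu)
  xbar <- (beta + sqrt(max(disc, 0))) / 2

  if (method == "closed") {
    if (mu == 0) {
      w <- if (a0 > a1) c(1, 0) else if (a1 > a0) c(0, 1) else c(0.5, 0.5)
    } else {
      w <- c(mu * a1, xbar - (1 - mu) * a0)
    }
  } else {
    phi <- rbind(c(pi0, 1 - pi0), c(pi1, 1 - pi1))
    MU <- rbind(c(1 - mu, mu), c(mu, 1 - mu))
    X <- c(X0, X1)
    M <- matrix(0, 4, 4)
    for (g in 1:2) for (p in 1:2) for (h in 1:2) for (k in 1:2) {
      M[(g - 1) * 2 + p, (h - 1) * 2 + k] <- phi[g, p] * MU[h, g] * X[k]
    }
    e <- eigen(M)
    i <- which.max(Re(e$values))
    xbar <- Re(e$values[i])
    vec <- Re(e$vectors[, i])
    vec <- vec / sum(vec)
    w <- c(vec[1] + vec[2], vec[3] + vec[4])
  }
  w <- w / sum(w)
  feq <- c(pi0 * w[1], (1 - pi0) * w[1], pi1 * w[2], (1 - pi1) * w[2])
  names(feq) <- pair_names()
  structure(
    list(
      feq = feq, Xbar_eq = xbar,
      params = c(pi0 = pi0, pi1 = pi1, mu = mu, X0 = X0, X1 = X1),
      derived = c(alpha0 = a0, alpha1 = a1, beta = beta)
    ),
    class = "equilibrium_2x2"
  )
}

pair_names <- function() c("g0p0", "g0p1", "g1p0", "g1p1")

#' @export
print.equilibrium_2x2 <- function(x, ...) {
  cat("<equilibrium_2x2>\n")
  print(round(x$feq, 6))
  cat("  Xbar_eq =", format(x$Xbar_eq), "\n")
  invisible(x)
}

#' Descending frequency ordering of the four genotype-phenotype pairs
#'
#' @param feq 4-vector of equilibrium frequencies (an `equilibrium_2x2` is
#'   also accepted).
#' @param tie_tol boundary tolerance, relative to the largest frequency
#'   (default 1e-9): when any pairwise gap is below it the cell sits on a
#'   phase boundary.
#' @return list with `label` (e.g. `"g1p0>g1p1>g0p1>g0p0"`), `order`
#'   (permutation of 1:4), `min_gap`, and `boundary` flag.
#' @export
ordering_label <- function(feq, tie_tol = 1e-9) {
  if (inherits(feq, "equilibrium_2x2")) feq <- feq$feq
  stopifnot(length(feq) == 4)
  o <- order(feq, decreasing = TRUE)
  gaps <- abs(diff(feq[o]))
  list(
    label = paste(pair_names()[o], collapse = ">"),
    order = o,
    min_gap = min(gaps),
    boundary = min(gaps) < tie_tol * max(feq)
  )
}

#' Phase diagram of equilibrium orderings over the (pi1, mu) plane
#'
#' Evaluates the closed-form equilibrium on an `n_grid x n_grid` lattice over
#' the open unit square (grid points offset by half a cell from the
#' boundaries) and labels each cell by the descending ordering of the four
#' equilibrium frequencies. Cells whose smallest pairwise gap falls below
#' `tie_tol * max(feq)` are flagged as boundary cells.
#'
#' @param pi0 fixed mapping probability of genotype 0.
#' @param X0,X1 phenotype fitnesses (defaults 0.1 and 0.05).
#' @param n_grid lattice size per axis, >= 51.
#' @param tie_tol relative tie tolerance (default 1e-9).
#' @return object of class `phase_diagram`: `pi1`, `mu` (axis grids), `label`
#'   (n x n character matrix, rows indexed by pi1), `gap` (n x n numeric
#'   matrix of minimum pairwise gaps), `boundary` (logical matrix), plus the
#'   fixed parameters.
#' @export
phase_diagram <- function(pi0, X0 = 0.1, X1 = 0.05, n_grid = 201,
                          tie_tol = 1e-9) {
  stopifnot(n_grid >= 51)
  g <- (seq_len(n_grid) - 0.5) / n_grid
  pi1 <- g
  mu <- g
  a0 <- pi0 * X0 + (1 - pi0) * X1
  a1 <- pi1 * X0 + (1 - pi1) * X1 # vector over pi1
  # matrices indexed [pi1, mu]
  MUg <- matrix(mu, n_grid, n_grid, byrow = TRUE)
  A1 <- matrix(a1, n_grid, n_grid)
  beta <- (1 - MUg) * (a0 + A1)
  disc <- beta^2 - 4 * a0 * A1 * (1 - 2 * MUg)
  xbar <- (beta + sqrt(pmax(disc, 0))) / 2
  w0 <- MUg * A1
  w1 <- xbar - (1 - MUg) * a0
  tot <- w0 + w1
  f <- list(
    pi0 * w0 / tot, (1 - pi0) * w0 / tot,
    matrix(pi1, n_grid, n_grid) * w1 / tot,
    matrix(1 - pi1, n_grid, n_grid) * w1 / tot
  )
  # ordering code: 6 pairwise comparisons -> unique integer per permutation
  code <- matrix(0L, n_grid, n_grid)
  gap <- matrix(Inf, n_grid, n_grid)
  bit <- 1L
  for (i in 1:3) for (j in (i + 1):4) {
    d <- f[[i]] - f[[j]]
    code <- code + bit * (d > 0)
    gap <- pmin(gap, abs(d))
    bit <- bit * 2L
  }
  fmax <- pmax(f[[1]], f[[2]], f[[3]], f[[4]])
  boundary <- gap < tie_tol * fmax
  # decode each code into its ordering from the pairwise-win counts (exact
  # ties only occur in boundary cells, which are excluded from counting)
  ucode <- sort(unique(as.vector(code)))
  lab_of <- vapply(ucode, function(cc) {
    b <- as.integer(intToBits(cc))[1:6] # pairs (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
    wins <- c(b[1] + b[2] + b[3],
              (1 - b[1]) + b[4] + b[5],
              (1 - b[2]) + (1 - b[4]) + b[6],
              (1 - b[3]) + (1 - b[5]) + (1 - b[6]))
    paste(pair_names()[order(wins, decreasing = TRUE)], collapse = ">")
  }, character(1))
  label <- matrix(lab_of[match(code, ucode)], n_grid, n_grid)
  structure(
    list(
      pi1 = pi1, mu = mu, label = label, gap = gap, boundary = boundary,
      pi0 = pi0, X0 = X0, X1 = X1, tie_tol = tie_tol
    ),
    class = "phase_diagram"
  )
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "<phase_diagram> pi0 = %g, X = (%g, %g), %dx%d grid: %d sectors (%d boundary cells)\n",
    x$pi0, x$X0, x$X1, length(x$pi1), length(x$mu), count_sectors(x), sum(x$boundary)
  ))
  invisible(x)
}

#' Number of distinct ordering sectors in a phase diagram
#'
#' Counts the distinct descending-order labels among cells not flagged as
#' phase-boundary cells.
#'
#' @param pd a [phase_diagram()].
#' @return integer sector count.
#' @export
count_sectors <- function(pd) {
  stopifnot(inherits(pd, "phase_diagram"))
  length(unique(pd$label[!pd$boundary]))
}

#' @describeIn phase_diagram long-format data frame with columns
#'   `pi1, mu, label, gap, boundary`.
#' @param x a `phase_diagram`.
#' @param ... unused.
#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  n <- length(x$pi1)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    pi1 = x$pi1[grid$i], mu = x$mu[grid$j],
    label = x$label[cbind(grid$i, grid$j)],
    gap = x$gap[cbind(grid$i, grid$j)],
    boundary = x$boundary[cbind(grid$i, grid$j)],
    stringsAsFactors = FALSE
  )
}

#' Pairwise-equality boundary curves of the phase diagram
#'
#' For each of the 6 unordered pairs of equilibrium-frequency components,
#' locates the roots `mu*(pi1)` of `feq_i - feq_j = 0` along each grid line of
#' `pi1`, by sign-change bracketing on a fine `mu` scan followed by
#' [stats::uniroot()] refinement to tolerance 1e-10. A pair may have no root
#' on a slice (valid outcome: that boundary does not cross it).
#'
#' @param pi0 fixed mapping probability of genotype 0.
#' @param X0,X1 phenotype fitnesses.
#' @param pi1_grid values of pi1 at which to slice (default 101 half-offset
#'   points on (0,1)).
#' @param n_scan number of mu scan points per slice.
#' @return data frame with columns `pair` (e.g. `"g0p0=g1p1"`), `pi1`, `mu`;
#'   one row per located boundary point.
#' @export
boundary_curves <- function(pi0, X0 = 0.1, X1 = 0.05,
                            pi1_grid = ((1:101) - 0.5) / 101, n_scan = 401) {
  nm <- pair_names()
  mu_scan <- ((1:n_scan) - 0.5) / n_scan
  rows <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    pair_lab <- paste0(nm[i], "=", nm[j])
    for (p1 in pi1_grid) {
      fdiff <- function(mu) {
        e <- equilibrium_2x2(pi0, p1, mu, X0, X1)
        unname(e$feq[i] - e$feq[j])
      }
      vals <- vapply(mu_scan, fdiff, numeric(1))
      sc <- which(vals[-1] * vals[-n_scan] < 0)
      for (s in sc) {
        r <- stats::uniroot(fdiff, c(mu_scan[s], mu_scan[s + 1]), tol = 1e-10)
        rows[[length(rows) + 1]] <- data.frame(
          pair = pair_lab, pi1 = p1, mu = r$root, stringsAsFactors = FALSE
        )
      }
      zer <- which(vals == 0)
      for (s in zer) {
        rows[[length(rows) + 1]] <- data.frame(
          pair = pair_lab, pi1 = p1, mu = mu_scan[s], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pair = character(0), pi1 = numeric(0), mu = numeric(0)))
  }
  do.call(rbind, rows)
}
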