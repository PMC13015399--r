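#' Trajectory container
#'
#' Time series of genotype-phenotype frequency tensors plus mean fitness, with
#' trial structure. Frequencies are stored as an array `[time, genotype,
#' phenotype]`; simulator trajectories also carry integer counts.
#'
#' @param time numeric vector of times.
#' @param dilution integer vector of dilution indices (NA for ODE output).
#' @param freq array `c(n_times, G, P)` of frequencies.
#' @param mean_fitness numeric vector of mean fitness at each time.
#' @param trial trial identifier (integer or `"ode"`).
#' @param model the generating [prgp_model()] (labels and hash are retained).
#' @param dt time step (NA for ODE output).
#' @param N population size (NA for ODE output).
#' @param seed RNG seed used for this trial (NA for ODE output).
#' @param counts optional array `c(n_times, G, P)` of integer counts.
#' @return object of class `propgen_trajectory`.
#' @export
new_trajectory <- function(time, dilution, freq, mean_fitness, trial, model,
                           dt, N, seed, counts = NULL) {
  structure(
    list(
      time = time, dilution = dilution, freq = freq,
      mean_fitness = mean_fitness, trial = trial,
      genotypes = model$genotypes, phenotypes = model$phenotypes,
      model_hash = model_hash(model), dt = dt, N = N, seed = seed,
      counts = counts
    ),
    class = "propgen_trajectory"
  )
}

#' @export
print.propgen_trajectory <- function(x, ...) {
  cat(sprintf(
    "<propgen_trajectory> trial %s: %d recorded times, %d genotypes x %d phenotypes\n",
    as.character(x$trial), length(x$time), dim(x$freq)[2], dim(x$freq)[3]
  ))
  invisible(x)
}

#' @describeIn new_trajectory long-format data frame with columns
#'   `trial, dilution, time, genotype, phenotype, count, frequency,
#'   mean_fitness`.
#' @param x a `propgen_trajectory`.
#' @param ... unused.
#' @export
as.data.frame.propgen_trajectory <- function(x, ...) {
  nt <- length(x$time)
  G <- dim(x$freq)[2]
  P <- dim(x$freq)[3]
  grid <- expand.grid(
    t = seq_len(nt), g = seq_len(G), p = seq_len(P),
    KEEP.OUT.ATTRS = FALSE
  )
  data.frame(
    trial = as.character(x$trial),
    dilution = x$dilution[grid$t],
    time = x$time[grid$t],
    genotype = x$genotypes[grid$g],
    phenotype = x$phenotypes[grid$p],
    count = if (is.null(x$counts)) NA_real_ else x$counts[cbind(grid$t, grid$g, grid$p)],
    frequency = x$freq[cbind(grid$t, grid$g, grid$p)],
    mean_fitness = x$mean_fitness[grid$t],
    stringsAsFactors = FALSE
  )
}

#' Ensemble mean and standard error over trials
#'
#' @param trajs list of `propgen_trajectory` objects sharing the same recorded
#'   times.
#' @return list with `time`, `dilution`, `mean` (array `[time, G, P]`), `se`
#'   (same shape; standard error of the ensemble mean), `mean_fitness`, and
#'   `n_trials`.
#' @export
ensemble_stats <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  nt <- length(trajs[[1]]$time)
  dims <- dim(trajs[[1]]$freq)
  K <- length(trajs)
  acc <- array(0, dims)
  acc2 <- array(0, dims)
  xb <- 0
  for (tr in trajs) {
    stopifnot(length(tr$time) == nt)
    acc <- acc + tr$freq
    acc2 <- acc2 + tr$freq^2
    xb <- xb + tr$mean_fitness
  }
  m <- acc / K
  va <- pmax(acc2 / K - m^2, 0) * K / max(K - 1, 1)
  list(
    time = trajs[[1]]$time, dilution = trajs[[1]]$dilution,
    mean = m, se = sqrt(va / K), mean_fitness = xb / K, n_trials = K
  )
}

#' First dilution index after which a trajectory stays near a reference
#'
#' Smallest recorded index `d` such that the sup-norm distance between the
#' frequency tensor and `reference` remains below `tol` for all recorded times
#' from `d` onward.
#'
#' @param traj a `propgen_trajectory`, or a list as returned by
#'   [ensemble_stats()].
#' @param reference G x P frequency matrix (or vector of length G*P).
#' @param tol positive sup-norm tolerance.
#' @return the dilution index (falling back to the record index when dilution
#'   indices are absent), or `NA` if the trajectory never settles within `tol`.
#' @export
detect_equilibration <- function(traj, reference, tol) {
  stopifnot(tol > 0)
  freq <- if (inherits(traj, "propgen_trajectory")) traj$freq else traj$mean
  dil <- if (inherits(traj, "propgen_trajectory")) traj$dilution else traj$dilution
  nt <- dim(freq)[1]
  ref <- array(rep(as.numeric(reference), each = nt), dim(freq))
  dist <- apply(abs(freq - ref), 1, max)
  ok <- rev(cumprod(rev(dist < tol))) == 1
  if (!any(ok)) return(NA_integer_)
  i <- which(ok)[1]
  if (!is.null(dil) && !all(is.na(dil))) dil[i] else i - 1L
}
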