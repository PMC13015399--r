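#' @title Model and trajectory input/output
#' @description Model configurations round-trip through YAML or JSON
#'   (selected by file extension) losslessly to 1e-15; trajectories are
#'   written as TSV with 17 significant digits plus a JSON metadata sidecar.
#' @name propgen_io
NULL

# FNV-1a over the decimal rendering of all numeric fields; stable across
# sessions, used only to stamp outputs with the generating model.
model_hash <- function(model) {
  s <- paste(
    c(model$genotypes, model$phenotypes,
      format(c(model$fitness, model$repl_mutation, model$phenotype_noise,
               model$spont_rate, model$spont_mutation, model$sps_rate,
               model$sps_matrix, as.numeric(model$pop_size),
               model$time_scale), digits = 17)),
    collapse = "|"
  )
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

model_to_list <- function(model) {
  list(
    genotypes = model$genotypes,
    phenotypes = model$phenotypes,
    fitness = unname(model$fitness),
    mu = unname(model$repl_mutation),
    phi = model$phenotype_noise,
    R = unname(model$spont_rate),
    m = unname(model$spont_mutation),
    S = unname(model$sps_rate),
    sigma = model$sps_matrix,
    N = model$pop_size,
    time_scale = model$time_scale
  )
}

model_from_list <- function(x, mu_convention = c("includes_self", "excludes_self")) {
  mu_convention <- match.arg(mu_convention)
  required <- c("genotypes", "phenotypes", "fitness", "mu", "phi")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("model config missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  known <- c(required, "R", "m", "S", "sigma", "N", "time_scale")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown model config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  G <- length(x$genotypes)
  P <- length(x$phenotypes)
  mu <- to_matrix(x$mu, G, G, "mu")
  if (mu_convention == "excludes_self") {
    diag(mu) <- 0
    diag(mu) <- 1 - rowSums(mu)
  }
  m <- prgp_model(
    genotypes = x$genotypes, phenotypes = x$phenotypes,
    fitness = as.numeric(x$fitness),
    repl_mutation = mu,
    phenotype_noise = to_array3(x$phi, G, P, "phi"),
    spont_rate = if (!is.null(x$R)) as.numeric(x$R) else NULL,
    spont_mutation = if (!is.null(x$m)) to_matrix(x$m, G, G, "m") else NULL,
    sps_rate = if (!is.null(x$S)) as.numeric(x$S) else NULL,
    sps_matrix = if (!is.null(x$sigma)) to_array3(x$sigma, G, P, "sigma") else NULL,
    pop_size = if (!is.null(x$N)) x$N else NA,
    time_scale = x$time_scale %||% 1
  )
  v <- validate_model(m)
  if (length(v)) {
    stop("invalid model config:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  m
}

to_matrix <- function(x, nr, nc, nm) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  if (!all(dim(x) == c(nr, nc))) {
    stop(sprintf("config key `%s` must be a %dx%d matrix", nm, nr, nc),
         call. = FALSE)
  }
  x
}

to_array3 <- function(x, G, P, nm) {
  if (is.list(x)) {
    # list of G matrices, each P x P
    slices <- lapply(x, function(s) to_matrix(s, P, P, nm))
    a <- array(0, c(G, P, P))
    for (g in seq_len(G)) a[g, , ] <- slices[[g]]
    return(a)
  }
  x <- as.array(x)
  if (length(dim(x)) != 3 || !all(dim(x) == c(G, P, P))) {
    stop(sprintf("config key `%s` must be a %dx%dx%d array", nm, G, P, P),
         call. = FALSE)
  }
  x
}

#' Write / read a model configuration
#'
#' The on-disk representation uses keys `genotypes, phenotypes, fitness, mu,
#' phi, R, m, S, sigma, N, time_scale`; matrices are stored as lists of rows
#' and the `phi`/`sigma` tensors as lists of per-genotype matrices. Format is
#' chosen by extension: `.json` (jsonlite, full double precision) or
#' `.yaml`/`.yml`.
#'
#' @param model a [prgp_model()].
#' @param path file path ending in `.json`, `.yaml`, or `.yml`.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   validated [prgp_model()].
#' @export
write_model <- function(model, path) {
  x <- model_to_list(model)
  x$mu <- matrix_rows(x$mu)
  x$m <- matrix_rows(x$m)
  x$phi <- tensor_slices(x$phi)
  x$sigma <- tensor_slices(x$sigma)
  fmt <- config_format(path)
  if (fmt == "json") {
    jsonlite::write_json(x, path, digits = I(17), auto_unbox = FALSE, pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(x, precision = 22), path)
  }
  invisible(path)
}

matrix_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
tensor_slices <- function(a) {
  lapply(seq_len(dim(a)[1]), function(g) matrix_rows(a[g, , , drop = TRUE]))
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json"
  else if (ext %in% c("yaml", "yml")) "yaml"
  else stop("unsupported config extension: .", ext, " (use .json/.yaml/.yml)",
            call. = FALSE)
}

#' @rdname write_model
#' @param mu_convention whether the stored `mu` rows include the no-mutation
#'   diagonal (`"includes_self"`, default: rows sum to 1) or list only
#'   off-diagonal probabilities (`"excludes_self"`: the diagonal is filled
#'   with the remainder).
#' @export
read_model <- function(path, mu_convention = c("includes_self", "excludes_self")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- config_format(path)
  x <- if (fmt == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_list(x, mu_convention = match.arg(mu_convention))
}

#' Load a run configuration
#'
#' Reads a structured run configuration (YAML or JSON) with keys `model`
#' (inline model mapping or path to a model file), `engine` (`"prosed"` or
#' `"ode"`), `dt`, `n_dilutions`, `t_max`, `trials`, `seed`, `out`, and
#' `record_every`. Unknown keys are errors, never silently ignored; range
#' violations name the offending key.
#'
#' @param path configuration file path.
#' @return object of class `propgen_config` (a validated named list with
#'   defaults filled in).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- config_format(path)
  x <- if (fmt == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("model", "engine", "dt", "n_dilutions", "t_max", "trials", "seed",
             "out", "record_every")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$model)) stop("config key `model` is required", call. = FALSE)
  model <- if (is.character(x$model)) {
    read_model(if (file.exists(x$model)) x$model else
      file.path(dirname(path), x$model))
  } else {
    model_from_list(x$model)
  }
  cfg <- list(
    model = model,
    engine = x$engine %||% "prosed",
    dt = x$dt %||% (1 / (2 * max(model$fitness))),
    n_dilutions = x$n_dilutions %||% 250,
    t_max = x$t_max %||% NULL,
    trials = x$trials %||% 1,
    seed = x$seed %||% 1,
    out = x$out %||% "trajectory.tsv",
    record_every = x$record_every %||% 1
  )
  if (!cfg$engine %in% c("prosed", "ode")) {
    stop("config key `engine` must be 'prosed' or 'ode'", call. = FALSE)
  }
  for (k in c("dt", "n_dilutions", "trials", "seed", "record_every")) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0) {
      stop(sprintf("config key `%s` must be a positive number", k), call. = FALSE)
    }
  }
  class(cfg) <- "propgen_config"
  cfg
}

#' Write / read trajectories as TSV
#'
#' Writes one or more trajectories in the long format
#' `trial, dilution, time, genotype, phenotype, count, frequency,
#' mean_fitness` (tab-separated, frequencies at 17 significant digits) and a
#' JSON sidecar `<path>.json` carrying run metadata (model hash, seeds, dt,
#' N, package version).
#'
#' @param trajs a `propgen_trajectory` or list of them.
#' @param path output TSV path.
#' @param sidecar write the metadata sidecar (default TRUE).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the long-format data frame.
#' @export
write_trajectory <- function(trajs, path, sidecar = TRUE) {
  if (inherits(trajs, "propgen_trajectory")) trajs <- list(trajs)
  df <- if (length(trajs) == 0) {
    data.frame(
      trial = character(0), dilution = integer(0), time = numeric(0),
      genotype = character(0), phenotype = character(0), count = numeric(0),
      frequency = numeric(0), mean_fitness = numeric(0)
    )
  } else {
    do.call(rbind, lapply(trajs, as.data.frame))
  }
  out <- df
  for (col in c("time", "count", "frequency", "mean_fitness")) {
    out[[col]] <- format(df[[col]], digits = 17, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- list(
      model_hash = if (length(trajs)) trajs[[1]]$model_hash else NA,
      seeds = if (length(trajs)) vapply(trajs, function(t) as.integer(t$seed), integer(1)) else integer(0),
      dt = if (length(trajs)) trajs[[1]]$dt else NA,
      N = if (length(trajs)) trajs[[1]]$N else NA,
      version = as.character(utils::packageVersion("propgen"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, colClasses = c(
      trial = "character", dilution = "integer", time = "numeric",
      genotype = "character", phenotype = "character", count = "numeric",
      frequency = "numeric", mean_fitness = "numeric"
    )),
    error = function(e) stop("malformed trajectory file: ", conditionMessage(e),
                             call. = FALSE)
  )
  df
}
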