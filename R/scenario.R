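#' Scenario configuration
#'
#' Bundles everything needed to train a joint schedule/network system for
#' one chemical-exchange scenario: the template spin system and its varied
#' parameter ranges, the schedule length, initialization, bounds and
#' trainable columns, noise level, and training hyperparameters.
#'
#' @param pools Template [pool_system()] (fixed constants; varied fields
#'   are overridden per sample).
#' @param ranges Named list of `c(min, max)` ranges for the varied tissue
#'   parameters (any of `fb`, `kb`, `fc`, `kc`, `r1a`, `r2a`).
#' @param field A [field_context()].
#' @param n_images Schedule length N (default 10).
#' @param noise_sigma Additive white Gaussian noise standard deviation
#'   injected into raw signals (default 0.002).
#' @param schedule List with `init` (named list of per-column values,
#'   scalars recycled to N), `bounds` (named list `c(lo, hi)`) and
#'   `trainable` (character vector of column names).
#' @param training List of hyperparameters; defaults: `batch_size = 256`,
#'   `epochs = 100`, `lr_schedule = 0.001`, `lr_net = 1e-04`,
#'   `n_train = 20000`, `n_dev = 2000`.
#' @param seed Integer base seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(pools, ranges, field = field_context(),
                            n_images = 10, noise_sigma = 0.002,
                            schedule = list(), training = list(), seed = 1L) {
  stopifnot(inherits(pools, "pool_system"))
  if (!length(ranges)) abort("at least one varied parameter range is required")
  ok <- c("fb", "kb", "fc", "kc", "r1a", "r2a")
  bad <- setdiff(names(ranges), ok)
  if (length(bad)) abort(paste0("unknown range parameter(s): ",
                                paste(bad, collapse = ", ")))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      abort(paste0("range for '", nm, "' must be finite c(min, max)"))
  }
  if (n_images < 1) abort("n_images must be >= 1")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  sched_def <- list(
    init = list(omega1_uT = 2, tsat_s = 3, wrf_ppm = 3, fa_deg = 60,
                trec_s = 1),
    bounds = list(omega1_uT = c(0, 6)),
    trainable = "omega1_uT")
  schedule <- check_keys(modifyList(sched_def, schedule), names(sched_def),
                         "schedule")
  schedule$init <- check_keys(schedule$init, SCHED_COLS, "schedule$init")
  train_def <- list(batch_size = 256, epochs = 100, lr_schedule = 1e-3,
                    lr_net = 1e-4, n_train = 20000, n_dev = 2000)
  training <- check_keys(modifyList(train_def, training), names(train_def),
                         "training")
  structure(list(pools = pools, ranges = ranges, field = field,
                 n_images = as.integer(n_images), noise_sigma = noise_sigma,
                 schedule = schedule, training = training,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    abort(paste0("unknown key(s) in ", where, ": ",
                 paste(unknown, collapse = ", ")))
  x
}

#' Read / write a scenario configuration as YAML
#'
#' The YAML schema mirrors [scenario_config()]: top-level keys `pools`
#' (`water`, optional `solute`, `semisolid`), `field`, `ranges`,
#' `n_images`, `noise_sigma`, `schedule`, `training`, `seed`. Unknown keys
#' anywhere are a hard error, so typos are caught at load time; omitted
#' keys take the documented defaults.
#'
#' @param path YAML file path.
#' @return `load_scenario` returns a validated [scenario_config()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  y <- yaml::read_yaml(path)
  y <- check_keys(y, c("pools", "field", "ranges", "n_images", "noise_sigma",
                       "schedule", "training", "seed"), "scenario")
  if (is.null(y$pools) || is.null(y$pools$water))
    abort("scenario must define pools$water")
  pw <- check_keys(y$pools, c("water", "solute", "semisolid"), "pools")
  w <- check_keys(pw$water, c("r1a", "r2a", "m0"), "pools$water")
  pools <- pool_system(r1a = w$r1a, r2a = w$r2a, m0 = w$m0 %||% 1,
                       solute = pw$solute, semisolid = pw$semisolid)
  fc <- if (!is.null(y$field))
    do.call(field_context, check_keys(y$field, c("b0", "gamma_2pi"), "field"))
  else field_context()
  ranges <- lapply(y$ranges, as.numeric)
  args <- list(pools = pools, ranges = ranges, field = fc)
  for (k in c("n_images", "noise_sigma", "schedule", "training", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(scenario_config, args)
}

#' @rdname load_scenario
#' @param config A [scenario_config()].
#' @export
save_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$pools
  y <- list(
    pools = c(list(water = p$water),
              if (!is.null(p$solute)) list(solute = p$solute),
              if (!is.null(p$semisolid)) list(semisolid = p$semisolid)),
    field = list(b0 = config$field$b0, gamma_2pi = config$field$gamma_2pi),
    ranges = config$ranges,
    n_images = config$n_images,
    noise_sigma = config$noise_sigma,
    schedule = config$schedule,
    training = config$training,
    seed = config$seed)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Draw tissue-parameter tuples uniformly over the scenario ranges
#'
#' @param config A [scenario_config()].
#' @param n Number of tuples (>= 1).
#' @param seed Optional seed; distinct seeds give disjoint (independent)
#'   draws for train and development sets.
#' @return A tibble with one column per varied parameter.
#' @export
sample_params <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (n < 1) abort("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tibble::as_tibble(lapply(config$ranges, function(r) runif(n, r[1], r[2])))
}

#' Inject white Gaussian noise into raw signals
#'
#' Noise is added to raw (unnormalized) signals, mimicking acquisition
#' noise that precedes any post-processing.
#'
#' @param signals Numeric vector or matrix of raw signals.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Optional seed.
#' @return Object of the same shape with i.i.d. N(0, sigma^2) added.
#' @export
add_noise <- function(signals, sigma, seed = NULL) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(signals)
  if (!is.null(seed)) set.seed(seed)
  signals + rnorm(length(signals), 0, sigma)
}

#' Two-norm normalization along the temporal dimension
#'
#' Scales a signal trajectory (or each row of a trajectory matrix) to unit
#' Euclidean norm, the pixel-wise preprocessing applied before both
#' network reconstruction and dictionary dot-product matching.
#'
#' @param signal Numeric vector, or matrix with one trajectory per row.
#' @return Unit-norm vector / row-normalized matrix.
#' @export
normalize_trajectory <- function(signal) {
  if (is.matrix(signal)) {
    nrm <- sqrt(rowSums(signal^2))
    if (any(nrm == 0)) abort("zero-norm trajectory cannot be normalized")
    return(signal / nrm)
  }
  nrm <- sqrt(sum(signal^2))
  if (nrm == 0) abort("zero-norm trajectory cannot be normalized")
  signal / nrm
}

#' Convert solute concentration to proton volume fraction
#'
#' The exchangeable-proton volume fraction relative to the two-proton
#' 55.5 M water pool: `fb = n_protons * conc / 111000` with `conc` in mM.
#'
#' @param conc_mM Solute concentration (mM, >= 0).
#' @param n_protons Number of equivalent exchangeable protons per molecule
#'   (e.g. 3 for the amine protons of L-arginine).
#' @return Volume fraction (dimensionless).
#' @export
concentration_to_fraction <- function(conc_mM, n_protons) {
  if (any(conc_mM < 0)) abort("concentration must be >= 0")
  if (any(n_protons < 1)) abort("n_protons must be >= 1")
  n_protons * conc_mM / 111000
}

#' @rdname concentration_to_fraction
#' @param fb Volume fraction (>= 0).
#' @export
fraction_to_concentration <- function(fb, n_protons) {
  if (any(fb < 0)) abort("volume fraction must be >= 0")
  if (any(n_protons < 1)) abort("n_protons must be >= 1")
  fb * 111000 / n_protons
}

#' Build a simulated-signal dictionary on a regular parameter grid
#'
#' Simulates the Cartesian product of the supplied grid values under the
#' given schedule and stores the two-norm-normalized trajectories next to
#' their generating parameter table, for fingerprint dot-product matching.
#'
#' @param config A [scenario_config()].
#' @param schedule An [acq_schedule()].
#' @param grid Named list of grid value vectors (defaults to 32 equally
#'   spaced values per varied range).
#' @param max_entries Guard against absurd grids (default 5e5 rows).
#' @return An object of class `cest_dictionary` with elements `signals`
#'   (M x N unit-norm matrix) and `params` (M-row tibble).
#' @export
build_dictionary <- function(config, schedule, grid = NULL,
                             max_entries = 5e5) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(grid))
    grid <- lapply(config$ranges, function(r) seq(r[1], r[2], length.out = 32))
  if (!all(lengths(grid) >= 1)) abort("grid values must be nonempty")
  m <- prod(lengths(grid))
  if (m > max_entries)
    abort(paste0("dictionary would have ", m, " entries (cap ", max_entries, ")"))
  params <- tibble::as_tibble(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  sims <- simulate_signals(params, config$pools, schedule, config$field)
  structure(list(signals = normalize_trajectory(sims$signal),
                 params = params),
            class = "cest_dictionary")
}

#' @export
print.cest_dictionary <- function(x, ...) {
  cat(sprintf("<cest_dictionary: %d entries x %d images; parameters: %s>\n",
              nrow(x$signals), ncol(x$signals),
              paste(names(x$params), collapse = ", ")))
  invisible(x)
}

#' Persist / restore a dictionary as a CSV pair
#'
#' Writes `<stem>_signals.csv` (normalized trajectories) and
#' `<stem>_params.csv` (generating parameter table).
#'
#' @param dictionary A `cest_dictionary`.
#' @param stem Path stem (no extension).
#' @return `save_dictionary` returns `stem` invisibly.
#' @export
save_dictionary <- function(dictionary, stem) {
  sig <- as.data.frame(dictionary$signals)
  names(sig) <- paste0("s", seq_len(ncol(sig)))
  readr::write_csv(sig, paste0(stem, "_signals.csv"))
  readr::write_csv(as.data.frame(dictionary$params),
                   paste0(stem, "_params.csv"))
  invisible(stem)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(stem) {
  sig <- as.matrix(readr::read_csv(paste0(stem, "_signals.csv"),
                                   show_col_types = FALSE))
  dimnames(sig) <- NULL
  params <- readr::read_csv(paste0(stem, "_params.csv"),
                            show_col_types = FALSE)
  structure(list(signals = sig, params = params), class = "cest_dictionary")
}
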