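SCHED_COLS <- c("omega1_uT", "tsat_s", "wrf_ppm", "fa_deg", "trec_s")

#' Construct an acquisition schedule
#'
#' An acquisition schedule is the scanner-facing protocol of an N-image
#' molecular-information-encoding acquisition: per image a continuous-wave
#' saturation pulse (power `omega1_uT` in microtesla, duration `tsat_s`,
#' frequency offset `wrf_ppm` relative to water) followed by a spoiled
#' single-shot readout (excitation flip angle `fa_deg`) and a recovery
#' delay `trec_s`. A subset of the five columns can be flagged trainable,
#' in which case box bounds per column must be supplied.
#'
#' @param omega1_uT,tsat_s,wrf_ppm,fa_deg,trec_s Numeric vectors of common
#'   length N (scalars are recycled).
#' @param trainable Character vector of column names to optimize.
#' @param bounds Named list of `c(lower, upper)` per column; required for
#'   every trainable column. Values must lie within their bounds.
#' @return A tibble of class `acq_schedule` with columns `index` plus the
#'   five protocol columns; `trainable` and `bounds` stored as attributes.
#' @examples
#' acq_schedule(omega1_uT = c(2, 4), tsat_s = 3, wrf_ppm = 3,
#'              fa_deg = 60, trec_s = 1,
#'              trainable = "omega1_uT", bounds = list(omega1_uT = c(0, 6)))
#' @export
acq_schedule <- function(omega1_uT, tsat_s, wrf_ppm, fa_deg, trec_s,
                         trainable = character(), bounds = list()) {
  vals <- list(omega1_uT = omega1_uT, tsat_s = tsat_s, wrf_ppm = wrf_ppm,
               fa_deg = fa_deg, trec_s = trec_s)
  n <- max(lengths(vals))
  vals <- lapply(vals, function(v) {
    if (length(v) == 1) rep(v, n)
    else if (length(v) == n) v
    else abort("schedule columns must share a common length")
  })
  if (n < 1) abort("schedule must have at least one entry")
  with(vals, {
    if (any(!is.finite(unlist(vals)))) abort("schedule values must be finite")
    if (any(omega1_uT < 0)) abort("omega1_uT must be >= 0")
    if (any(tsat_s < 0) || any(trec_s < 0)) abort("durations must be >= 0")
    if (any(fa_deg < 0 | fa_deg > 180)) abort("fa_deg must be in [0, 180]")
  })
  bad <- setdiff(trainable, SCHED_COLS)
  if (length(bad)) abort(paste0("unknown trainable column(s): ",
                                paste(bad, collapse = ", ")))
  for (cn in trainable) {
    if (is.null(bounds[[cn]]))
      abort(paste0("trainable column '", cn, "' needs bounds"))
  }
  for (cn in names(bounds)) {
    b <- bounds[[cn]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2])
      abort(paste0("bounds for '", cn, "' must be finite c(lower, upper)"))
    if (any(vals[[cn]] < b[1] - 1e-12) || any(vals[[cn]] > b[2] + 1e-12))
      abort(paste0("schedule column '", cn, "' outside its bounds"))
  }
  out <- tibble::tibble(index = seq_len(n), !!!vals)
  structure(out, trainable = trainable, bounds = bounds,
            class = c("acq_schedule", class(out)))
}

sched_matrix <- function(schedule) {
  as.matrix(schedule[, SCHED_COLS])
}

sched_trainable <- function(schedule) attr(schedule, "trainable", exact = TRUE)
sched_bounds <- function(schedule) attr(schedule, "bounds", exact = TRUE)

set_sched_values <- function(schedule, col, values) {
  schedule[[col]] <- values
  schedule
}

#' Initialize a schedule from a scenario configuration
#'
#' `fixed` mode takes the per-column initial values stored in the
#' configuration; `random` mode draws each trainable column uniformly
#' within its bounds (non-trainable columns keep their fixed values).
#'
#' @param config A [scenario_config()].
#' @param mode `"fixed"` or `"random"`.
#' @param seed Optional integer seed controlling the random draw.
#' @return An [acq_schedule()].
#' @export
init_schedule <- function(config, mode = c("random", "fixed"), seed = NULL) {
  mode <- match.arg(mode)
  sc <- config$schedule
  n <- config$n_images
  vals <- lapply(SCHED_COLS, function(cn) {
    v <- sc$init[[cn]]
    if (length(v) == 1) rep(v, n) else v
  })
  names(vals) <- SCHED_COLS
  if (mode == "random") {
    if (!is.null(seed)) set.seed(seed)
    for (cn in sc$trainable) {
      b <- sc$bounds[[cn]]
      vals[[cn]] <- runif(n, b[1], b[2])
    }
  }
  acq_schedule(vals$omega1_uT, vals$tsat_s, vals$wrf_ppm, vals$fa_deg,
               vals$trec_s, trainable = sc$trainable, bounds = sc$bounds)
}

#' Total acquisition time of a schedule
#'
#' Sum of saturation and recovery periods plus a configurable per-image
#' readout duration (default 0, treating the single-shot readout as a
#' point event).
#'
#' @param schedule An [acq_schedule()].
#' @param readout_s Per-image readout duration in seconds.
#' @return Scalar time in seconds.
#' @export
acquisition_time <- function(schedule, readout_s = 0) {
  stopifnot(inherits(schedule, "acq_schedule"), readout_s >= 0)
  sum(schedule$tsat_s + schedule$trec_s) + nrow(schedule) * readout_s
}

#' Export / import a schedule as CSV
#'
#' The scanner-facing artifact: a CSV with the fixed header
#' `index,omega1_uT,tsat_s,wrf_ppm,fa_deg,trec_s`.
#'
#' @param schedule An [acq_schedule()].
#' @param path File path.
#' @return `export_schedule` returns `path` invisibly.
#' @export
export_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "acq_schedule"))
  df <- as.data.frame(schedule[, c("index", SCHED_COLS)])
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname export_schedule
#' @param trainable,bounds Optional metadata to re-attach on import; when
#'   `bounds` is given, imported values are checked against them.
#' @export
import_schedule <- function(path, trainable = character(), bounds = list()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("index", SCHED_COLS)
  if (!identical(names(df), need))
    abort(paste0("malformed schedule CSV; expected columns ",
                 paste(need, collapse = ",")))
  acq_schedule(df$omega1_uT, df$tsat_s, df$wrf_ppm, df$fa_deg, df$trec_s,
               trainable = trainable, bounds = bounds)
}

#' Plot an acquisition schedule
#'
#' One panel per protocol parameter versus image index.
#'
#' @param object An [acq_schedule()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acq_schedule <- function(object, ...) {
  long <- tidyr::pivot_longer(as.data.frame(object), -"index",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "image index", y = NULL)
}
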