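#' Bloch-McConnell generator matrix under continuous-wave irradiation
#'
#' Assembles the time-invariant linear system `dM/dt = A M + c` coupling
#' the (Mx, My, Mz) components of all pools during continuous-wave
#' saturation. Units are converted internally: the pulse amplitude from
#' microtesla to rad/s via the proton gyromagnetic ratio, and frequency
#' offsets from ppm to rad/s via the static field.
#'
#' @param pools A [pool_system()] with at least one exchanging pool when a
#'   multi-pool matrix is requested.
#' @param omega1_uT Saturation amplitude (microtesla, >= 0).
#' @param wrf_ppm Saturation frequency offset (ppm relative to water).
#' @param field A [field_context()].
#' @return List with the generator matrix `A` (3p x 3p for p pools) and
#'   constant vector `c`.
#' @export
bm_matrix <- function(pools, omega1_uT, wrf_ppm, field = field_context()) {
  stopifnot(inherits(pools, "pool_system"))
  if (!is.finite(omega1_uT) || omega1_uT < 0 || !is.finite(wrf_ppm))
    abort("omega1_uT must be finite >= 0 and wrf_ppm finite")
  bm_matrix_cpp(pool_vector(pools), n_pools(pools), omega1_uT, wrf_ppm,
                field$b0)
}

#' Propagate magnetization through a continuous-wave saturation block
#'
#' Exact solution of the affine Bloch-McConnell system over the saturation
#' period via the matrix exponential of the augmented generator; exact for
#' time-invariant (continuous-wave) irradiation.
#'
#' @param m Magnetization state vector (length `3 * n_pools`), e.g. from
#'   [equilibrium_state()].
#' @inheritParams bm_matrix
#' @param tsat_s Saturation duration in seconds (>= 0).
#' @return The magnetization state at the end of saturation.
#' @export
saturation_propagate <- function(m, pools, omega1_uT, tsat_s, wrf_ppm,
                                 field = field_context()) {
  stopifnot(inherits(pools, "pool_system"))
  if (!is.finite(tsat_s) || tsat_s < 0) abort("tsat_s must be finite >= 0")
  drop(sat_propagate_cpp(m, pool_vector(pools), n_pools(pools),
                         omega1_uT, tsat_s, wrf_ppm, field$b0))
}

#' Spoiled readout and longitudinal recovery
#'
#' Models a gradient-spoiled single-shot readout: transverse components of
#' all pools are zeroed (spoiling), the acquired signal is the water Mz
#' times sin(FA), excitation scales every pool's Mz by cos(FA), and each
#' pool then relaxes longitudinally toward its equilibrium for the
#' recovery period. Transverse components remain zero at output.
#'
#' @param m Magnetization state vector.
#' @param pools A [pool_system()].
#' @param fa_deg Excitation flip angle in degrees (0-180).
#' @param trec_s Recovery time in seconds (>= 0).
#' @return List with `signal` (the acquired scalar) and `m` (the state at
#'   the end of recovery).
#' @export
readout_relax <- function(m, pools, fa_deg, trec_s) {
  stopifnot(inherits(pools, "pool_system"))
  if (!is.finite(fa_deg) || fa_deg < 0 || fa_deg > 180)
    abort("fa_deg must be in [0, 180]")
  if (!is.finite(trec_s) || trec_s < 0) abort("trec_s must be >= 0")
  readout_relax_cpp(m, pool_vector(pools), n_pools(pools), fa_deg, trec_s)
}

#' Simulate the signal trajectory of a full acquisition schedule
#'
#' Applies saturation followed by spoiled readout and recovery for each of
#' the N schedule entries in order, carrying the magnetization over
#' between entries (no reset to equilibrium mid-schedule). The schedule
#' starts from thermal equilibrium unless `m_start` is given.
#'
#' @param pools A [pool_system()].
#' @param schedule An [acq_schedule()].
#' @param field A [field_context()].
#' @param m_start Optional starting magnetization state.
#' @param jacobian If `TRUE`, also return the exact N x K jacobian of the
#'   signals with respect to the schedule's trainable parameters
#'   (columns ordered as trainable column blocks, entries within block).
#' @return Numeric length-N signal vector; with `jacobian = TRUE`, a list
#'   with `signals` and `jacobian`.
#' @export
simulate_schedule <- function(pools, schedule, field = field_context(),
                              m_start = NULL, jacobian = FALSE) {
  stopifnot(inherits(pools, "pool_system"), inherits(schedule, "acq_schedule"))
  gcols <- SCHED_COLS %in% (if (jacobian) sched_trainable(schedule) else character())
  res <- sim_trajectory_cpp(pool_vector(pools), n_pools(pools),
                            sched_matrix(schedule), field$b0, gcols, m_start)
  if (jacobian) {
    colnames(res$jacobian) <- jac_colnames(schedule)
    list(signals = drop(res$signals), jacobian = res$jacobian)
  } else {
    drop(res$signals)
  }
}

jac_colnames <- function(schedule) {
  tr <- SCHED_COLS[SCHED_COLS %in% sched_trainable(schedule)]
  n <- nrow(schedule)
  unlist(lapply(tr, function(cn) paste0(cn, "[", seq_len(n), "]")))
}

# Batch simulation over a pool-parameter matrix (rows = 13-element pool
# vectors). Returns signals (M x N) and, optionally, the per-sample
# jacobian cube (N x K x M). Internal hot path used by training,
# dictionary generation and phantom rendering.
sim_batch <- function(pool_mat, npools, schedule, field, jacobian = FALSE) {
  gcols <- SCHED_COLS %in% sched_trainable(schedule)
  if (!jacobian) gcols <- rep(FALSE, 5)
  sim_batch_cpp(pool_mat, npools, sched_matrix(schedule), field$b0,
                jacobian, gcols)
}

#' Simulate signal trajectories for a table of tissue parameters
#'
#' Vectorized forward model: each row of `params` overrides fields of the
#' template pool system (recognized columns: `fb`, `kb`, `fc`, `kc`,
#' `r1a`, `r2a`) and is simulated under the given schedule.
#'
#' @param params Data frame of per-sample tissue parameters.
#' @param pools Template [pool_system()] supplying all fixed constants.
#' @param schedule An [acq_schedule()].
#' @param field A [field_context()].
#' @return The input tibble with a matrix column `signal` (one length-N
#'   trajectory per row).
#' @export
simulate_signals <- function(params, pools, schedule,
                             field = field_context()) {
  pm <- pool_param_matrix(params, pools)
  sims <- sim_batch(pm$mat, pm$npools, schedule, field)
  out <- tibble::as_tibble(params)
  out$signal <- sims$signals
  out
}

# Build the M x 13 pool matrix from a template and a table of overrides.
pool_param_matrix <- function(params, pools) {
  base <- pool_vector(pools)
  npools <- n_pools(pools)
  idx <- c(r1a = 1, r2a = 2, fb = 4, kb = 5, r1b = 6, r2b = 7,
           fc = 9, kc = 10)
  m <- matrix(base, nrow = nrow(params), ncol = 13, byrow = TRUE)
  for (cn in intersect(names(params), names(idx)))
    m[, idx[[cn]]] <- params[[cn]]
  if (any(c("fb", "kb") %in% names(params)) && npools < 2)
    abort("params vary a solute pool but the template has none")
  if (any(c("fc", "kc") %in% names(params)) && npools < 3)
    abort("params vary a semisolid pool but the template has none")
  list(mat = m, npools = npools)
}
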