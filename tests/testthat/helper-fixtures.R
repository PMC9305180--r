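# Shared fixtures: an amine-like two-pool phantom scenario (exchangeable
# protons at 3 ppm, concentrations 12.5-100 mM at 3 protons/molecule,
# exchange rates 100-1400 s^-1, PBS-like water relaxation at 9.4 T).

amine_pools <- function(fb = 1e-3, kb = 500) {
  pool_system(r1a = 1 / 2.8, r2a = 1 / 1.2,
              solute = list(fb = fb, kb = kb, dwb = 3, r1b = 1, r2b = 30))
}

three_pool_fixture <- function() {
  pool_system(r1a = 1 / 1.8, r2a = 1 / 0.04,
              solute = list(fb = 0.002, kb = 300, dwb = 3.5, r1b = 1,
                            r2b = 40),
              semisolid = list(fc = 0.1, kc = 50, dwc = 0, r1c = 1,
                               r2c = 1e5))
}

amine_config <- function(epochs = 2, n_train = 512, n_dev = 128,
                         batch_size = 128, trainable = "omega1_uT",
                         noise_sigma = 0.002, seed = 1) {
  scenario_config(
    amine_pools(),
    ranges = list(fb = concentration_to_fraction(c(12.5, 100), 3),
                  kb = c(100, 1400)),
    noise_sigma = noise_sigma,
    schedule = list(
      init = list(omega1_uT = 2, tsat_s = 3, wrf_ppm = 3, fa_deg = 60,
                  trec_s = 1),
      bounds = list(omega1_uT = c(0, 6), tsat_s = c(0.5, 4),
                    wrf_ppm = c(-6, 6), fa_deg = c(10, 90),
                    trec_s = c(0.2, 3)),
      trainable = trainable),
    training = list(batch_size = batch_size, epochs = epochs,
                    n_train = n_train, n_dev = n_dev),
    seed = seed)
}

random_schedule <- function(n = 10, seed = 1,
                            trainable = SCHED_COLS_FIXTURE) {
  set.seed(seed)
  acq_schedule(
    omega1_uT = runif(n, 0.5, 5.5), tsat_s = runif(n, 1, 3),
    wrf_ppm = runif(n, 2, 4), fa_deg = runif(n, 30, 90),
    trec_s = runif(n, 0.3, 1.5),
    trainable = trainable,
    bounds = list(omega1_uT = c(0, 6), tsat_s = c(0, 4), wrf_ppm = c(-5, 5),
                  fa_deg = c(0, 180), trec_s = c(0, 3)))
}

SCHED_COLS_FIXTURE <- c("omega1_uT", "tsat_s", "wrf_ppm", "fa_deg", "trec_s")

# Central finite-difference jacobian of the signal trajectory w.r.t. one
# schedule entry; Richardson-extrapolated central differences for the
# saturation duration and offset, whose several-krad/s oscillatory
# dependence dominates plain central differences at any single step size.
fd_signal_grad <- function(pools, schedule, field, col, n, h) {
  shift <- function(d) {
    s <- schedule
    s[[col]][n] <- s[[col]][n] + d
    simulate_schedule(pools, s, field)
  }
  central <- function(h) (shift(h) - shift(-h)) / (2 * h)
  if (col %in% c("tsat_s", "wrf_ppm")) (4 * central(h / 2) - central(h)) / 3
  else central(h)
}

FD_STEPS <- c(omega1_uT = 1e-5, tsat_s = 3e-5, wrf_ppm = 3e-5,
              fa_deg = 1e-4, trec_s = 1e-6)
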