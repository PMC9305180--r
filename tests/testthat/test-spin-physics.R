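test_that("generator matrix matches an independently assembled textbook form", {
  # independent symbolic assembly of the two-pool CW Bloch-McConnell
  # generator, written directly from the coupled equations
  set.seed(4)
  for (i in 1:5) {
    r1a <- runif(1, 0.2, 1.5); r2a <- runif(1, 0.5, 20)
    fb <- runif(1, 1e-4, 0.01); kb <- runif(1, 20, 2000)
    r1b <- runif(1, 0.5, 2); r2b <- runif(1, 10, 100); dwb <- runif(1, -4, 5)
    w1_uT <- runif(1, 0, 6); wrf <- runif(1, -4, 5); b0 <- 9.4
    g <- 2 * pi * 42.577
    w1 <- g * w1_uT
    da <- (0 - wrf) * g * b0
    db <- (dwb - wrf) * g * b0
    kab <- fb * kb
    A_ref <- matrix(0, 6, 6)
    A_ref[1, ] <- c(-(r2a + kab), da, 0, kb, 0, 0)
    A_ref[2, ] <- c(-da, -(r2a + kab), w1, 0, kb, 0)
    A_ref[3, ] <- c(0, -w1, -(r1a + kab), 0, 0, kb)
    A_ref[4, ] <- c(kab, 0, 0, -(r2b + kb), db, 0)
    A_ref[5, ] <- c(0, kab, 0, -db, -(r2b + kb), w1)
    A_ref[6, ] <- c(0, 0, kab, 0, -w1, -(r1b + kb))
    c_ref <- c(0, 0, r1a, 0, 0, r1b * fb)
    ps <- pool_system(r1a = r1a, r2a = r2a,
                      solute = list(fb = fb, kb = kb, dwb = dwb,
                                    r1b = r1b, r2b = r2b))
    sys <- bm_matrix(ps, w1_uT, wrf, field_context(b0))
    expect_equal(sys$A, A_ref, tolerance = 1e-12)
    expect_equal(as.vector(sys$c), c_ref, tolerance = 1e-12)
  }
})

test_that("no-exchange and no-RF limits decouple the expected blocks", {
  ps <- pool_system(r1a = 0.5, r2a = 2,
                    solute = list(fb = 0, kb = 0, dwb = 3, r2b = 30))
  sys <- bm_matrix(ps, 2, 3)
  expect_equal(sys$A[1:3, 4:6], matrix(0, 3, 3))  # water gains nothing
  expect_equal(sys$A[4:6, 1:3], matrix(0, 3, 3))  # solute gains nothing

  ps2 <- amine_pools()
  sys2 <- bm_matrix(ps2, 0, 3)
  # omega1 = 0: no My <-> Mz coupling anywhere
  expect_equal(sys2$A[2, 3], 0); expect_equal(sys2$A[3, 2], 0)
  expect_equal(sys2$A[5, 6], 0); expect_equal(sys2$A[6, 5], 0)
  # water Mz row is pure relaxation plus exchange
  expect_equal(sys2$A[3, 3], -(1 / 2.8 + ps2$solute$fb * ps2$solute$kb))
  expect_equal(sys2$c[3], 1 / 2.8)
})

test_that("saturation propagation matches adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  ps <- pool_system(r1a = 0.5, r2a = 2,
                    solute = list(fb = 0.003, kb = 500, dwb = 3, r1b = 1,
                                  r2b = 30))
  fc <- field_context(9.4)
  sys <- bm_matrix(ps, 2, 3, fc)
  m0 <- equilibrium_state(ps)
  sol <- deSolve::ode(y = m0, times = c(0, 3),
                      func = function(t, y, p) list(as.vector(sys$A %*% y + sys$c)),
                      rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)
  m_exp <- saturation_propagate(m0, ps, 2, 3, 3, fc)
  expect_lt(max(abs(m_exp - sol[2, -1])) / max(abs(sol[2, -1])), 1e-6)
})

test_that("zero-duration and no-RF saturation reduce to closed forms", {
  ps <- amine_pools()
  m0 <- equilibrium_state(ps)
  expect_equal(saturation_propagate(m0, ps, 3, 0, 3), m0)

  # water-only T1 relaxation from a partially saturated state
  psw <- pool_system(r1a = 0.5, r2a = 2,
                     solute = list(fb = 0, kb = 0, dwb = 3))
  mz0 <- 0.25; t <- 1.7
  m <- saturation_propagate(c(0, 0, mz0, 0, 0, 0), psw, 0, t, 3)
  expect_equal(m[3], 1 + (mz0 - 1) * exp(-0.5 * t), tolerance = 1e-9)
})

test_that("readout applies spoiling, excitation and recovery as closed forms", {
  ps <- pool_system(r1a = 0.5, r2a = 2, solute = list(fb = 0, kb = 0, dwb = 3))
  # FA = 90: signal equals Mz, longitudinal store is emptied
  out <- readout_relax(c(0.1, -0.2, 0.7, 0, 0, 0), ps, 90, 1.3)
  expect_equal(out$signal, 0.7)
  expect_equal(out$m[3], 1 - exp(-0.5 * 1.3), tolerance = 1e-12)
  expect_equal(out$m[c(1, 2, 4, 5)], rep(0, 4))
  # FA = 0: no signal, state only relaxes
  out0 <- readout_relax(c(0, 0, 0.5, 0, 0, 0), ps, 0, 2)
  expect_equal(out0$signal, 0)
  expect_equal(out0$m[3], 1 + (0.5 - 1) * exp(-0.5 * 2))
})

test_that("readout matches a fine-step discrete Bloch simulation", {
  ps <- pool_system(r1a = 0.5, r2a = 2, solute = list(fb = 0, kb = 0, dwb = 3))
  out <- readout_relax(c(0, 0, 0.5, 0, 0, 0), ps, 60, 1)
  expect_equal(out$signal, 0.5 * sin(60 * pi / 180), tolerance = 1e-12)
  # brute-force Euler relaxation of the post-excitation Mz
  mz <- 0.5 * cos(60 * pi / 180)
  dt <- 1e-5
  for (i in seq_len(1 / dt)) mz <- mz + dt * 0.5 * (1 - mz)
  expect_equal(out$m[3], mz, tolerance = 1e-4)
})

test_that("schedule simulation composes single steps and carries magnetization", {
  ps <- amine_pools()
  fc <- field_context()
  s1 <- acq_schedule(2.5, 2, 3, 70, 0.8)
  sig <- simulate_schedule(ps, s1, fc)
  m <- saturation_propagate(equilibrium_state(ps), ps, 2.5, 2, 3, fc)
  ro <- readout_relax(m, ps, 70, 0.8)
  expect_equal(sig, ro$signal, tolerance = 1e-12)

  # N = 2 equals manual chaining through the carried-over state
  s2 <- acq_schedule(c(2.5, 4), c(2, 1), 3, 70, 0.8)
  sig2 <- simulate_schedule(ps, s2, fc)
  m2 <- saturation_propagate(ro$m, ps, 4, 1, 3, fc)
  ro2 <- readout_relax(m2, ps, 70, 0.8)
  expect_equal(sig2, c(ro$signal, ro2$signal), tolerance = 1e-12)
})

test_that("unsaturated fully recovered schedule yields M0 sin(FA)", {
  psw <- pool_system(r1a = 0.5, r2a = 2, solute = list(fb = 0, kb = 0, dwb = 3))
  sch <- acq_schedule(0, 0.5, 3, 45, 25)  # trec >= 10/R1a
  sig <- simulate_schedule(psw, sch, m_start = NULL)
  expect_equal(rep(sin(45 * pi / 180), 1), sig, tolerance = 1e-4)
  sch10 <- acq_schedule(rep(0, 10), 0.5, 3, 45, 25)
  expect_equal(simulate_schedule(psw, sch10),
               rep(sin(45 * pi / 180), 10), tolerance = 1e-4)
})

test_that("full-schedule trajectory matches an end-to-end ODE simulation", {
  skip_if_not_installed("deSolve")
  ps <- amine_pools(fb = 0.0015, kb = 800)
  fc <- field_context()
  sch <- random_schedule(10, seed = 7, trainable = character())
  sig <- simulate_schedule(ps, sch, fc)
  # independent oracle: integrate each saturation block with deSolve and
  # apply the readout algebra by hand
  m <- equilibrium_state(ps)
  meq <- m
  oracle <- numeric(10)
  for (n in 1:10) {
    sys <- bm_matrix(ps, sch$omega1_uT[n], sch$wrf_ppm[n], fc)
    sol <- deSolve::ode(y = m, times = c(0, sch$tsat_s[n]),
                        func = function(t, y, p)
                          list(as.vector(sys$A %*% y + sys$c)),
                        rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)
    m <- sol[2, -1]
    fa <- sch$fa_deg[n] * pi / 180
    m[c(1, 2, 4, 5)] <- 0
    oracle[n] <- m[3] * sin(fa)
    for (z in c(3, 6)) {
      r1 <- if (z == 3) ps$water$r1a else ps$solute$r1b
      mz <- m[z] * cos(fa)
      m[z] <- meq[z] + (mz - meq[z]) * exp(-r1 * sch$trec_s[n])
    }
  }
  expect_lt(max(abs(sig - oracle)) / max(abs(oracle)), 1e-5)
})

test_that("acquisition time sums saturation, recovery and readout periods", {
  sch <- acq_schedule(rep(2, 10), 3, 3, 60, 0.5)
  expect_equal(acquisition_time(sch), 35)
  expect_equal(acquisition_time(sch, readout_s = 0.02), 35.2)
  set.seed(1)
  s2 <- random_schedule(8, seed = 3, trainable = character())
  expect_equal(acquisition_time(s2), sum(s2$tsat_s) + sum(s2$trec_s))
})

test_that("vanishing exchange converges to the water-only signal", {
  psw <- pool_system(r1a = 0.4, r2a = 1, solute = list(fb = 0, kb = 0, dwb = 3))
  sch <- random_schedule(6, seed = 9, trainable = character())
  ref <- simulate_schedule(psw, sch)
  dev_of <- function(eps) {
    ps_k <- pool_system(r1a = 0.4, r2a = 1,
                        solute = list(fb = 0.002, kb = eps, dwb = 3))
    ps_f <- pool_system(r1a = 0.4, r2a = 1,
                        solute = list(fb = eps, kb = 500, dwb = 3))
    max(abs(simulate_schedule(ps_k, sch) - ref),
        abs(simulate_schedule(ps_f, sch) - ref))
  }
  d6 <- dev_of(1e-6); d8 <- dev_of(1e-8)
  expect_lt(d8, d6)          # converges as the pool vanishes
  expect_lt(d6, 1e-3)
  expect_lt(d8, 1e-5)
})

test_that("label-side saturation removes more water Mz than reference side", {
  ps <- amine_pools(fb = 0.002, kb = 400)
  m0 <- equilibrium_state(ps)
  m_lab <- saturation_propagate(m0, ps, 3, 3, +3)
  m_ref <- saturation_propagate(m0, ps, 3, 3, -3)
  expect_lt(m_lab[3], m_ref[3])
})

test_that("longer on-resonance labeling never increases water Mz", {
  ps <- amine_pools(fb = 0.002, kb = 150)
  m0 <- equilibrium_state(ps)
  mz <- vapply(seq(0.2, 4, by = 0.2), function(ts)
    saturation_propagate(m0, ps, 2, ts, 3)[3], numeric(1))
  expect_true(all(diff(mz) <= 1e-10))
})

test_that("invalid physical inputs are rejected", {
  expect_error(pool_system(r1a = -1, r2a = 2), "positive")
  expect_error(pool_system(r1a = 1, r2a = 2,
                           solute = list(fb = 1.2, kb = 10, dwb = 3)),
               "fraction")
  expect_error(pool_system(r1a = 1, r2a = 2,
                           solute = list(fb = 0.01, kb = -5, dwb = 3)),
               "exchange rate")
  expect_error(pool_system(r1a = 1, r2a = 2,
                           solute = list(fb = 0.01, kb = 5, dwb = 3,
                                         bogus = 1)), "unknown")
  ps <- amine_pools()
  expect_error(bm_matrix(ps, -1, 3), "omega1")
  expect_error(bm_matrix(ps, 2, NaN), "finite")
  expect_error(saturation_propagate(equilibrium_state(ps), ps, 2, -1, 3),
               "tsat")
  expect_error(readout_relax(equilibrium_state(ps), ps, 200, 1), "fa_deg")
})
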