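test_that("MTR asymmetry is the exact normalized difference", {
  expect_equal(mtr_asym(0.9, 0.9, 1), 0)
  expect_equal(mtr_asym(0.9, 0.8, 1), 0.1)
  set.seed(2)
  s_m <- runif(20); s_p <- runif(20); s0 <- runif(20, 0.5, 2)
  expect_equal(mtr_asym(s_m, s_p, s0), (s_m - s_p) / s0)
  expect_error(mtr_asym(0.9, 0.8, 0), "positive")
})

test_that("dot-product matching recovers rows, scales and near neighbors", {
  cfg <- amine_config()
  sch <- init_schedule(cfg, mode = "random", seed = 12)
  dict <- build_dictionary(cfg, sch,
                           grid = list(fb = seq(5e-4, 2.5e-3, length.out = 8),
                                       kb = seq(150, 1350, length.out = 8)))
  m <- dot_product_match(dict$signals[23, ], dict)
  expect_equal(m$match, 23)
  expect_equal(m$score, 1, tolerance = 1e-12)
  expect_equal(dot_product_match(5.7 * dict$signals[23, ], dict)$match, 23)

  # small perturbations resolve to the brute-force nearest entry
  set.seed(13)
  for (i in sample(nrow(dict$signals), 5)) {
    q <- dict$signals[i, ] + rnorm(10, 0, 1e-4)
    brute <- which.max(as.vector(dict$signals %*% normalize_trajectory(q)))
    expect_equal(dot_product_match(q, dict)$match, brute)
  }
  expect_error(dot_product_match(runif(10),
                                 structure(list(signals = matrix(0, 0, 10),
                                                params = tibble::tibble()),
                                           class = "cest_dictionary")),
               "empty")
  expect_error(dot_product_match(runif(8), dict), "width")
})

test_that("duplicate dictionary entries resolve to the lowest row index", {
  sig <- normalize_trajectory(matrix(runif(30), 3, 10, byrow = TRUE))
  dict <- structure(list(signals = sig[c(1, 2, 2, 3), ],
                         params = tibble::tibble(id = 1:4)),
                    class = "cest_dictionary")
  expect_equal(dot_product_match(sig[2, ], dict)$match, 2)
})

test_that("QUESP fitting is self-consistent on model-generated data", {
  fb <- concentration_to_fraction(50, 3)
  powers <- 0:6
  mtr <- cestopt:::quesp_model(powers, ksw = 500, fb = fb, r1a = 0.35,
                               r2a = 0.8, dw_ppm = 3, tsat_s = 3)
  series <- tibble::tibble(power_uT = powers, s_plus = 1 - mtr,
                           s_minus = 1, s0 = 1)
  fit <- quesp_fit(series, r1a = 0.35, r2a = 0.8, dw_ppm = 3,
                   mode = "fixed_concentration", fb = fb)
  expect_equal(fit$estimate$estimate[fit$estimate$term == "ksw"], 500,
               tolerance = 1e-4)
  free <- quesp_fit(series, r1a = 0.35, r2a = 0.8, dw_ppm = 3,
                    mode = "free_concentration")
  est <- setNames(free$estimate$estimate, free$estimate$term)
  expect_equal(unname(est["ksw"]), 500, tolerance = 1e-3)
  expect_equal(unname(est["fb"]), fb, tolerance = 1e-3)
})

test_that("small-signal asymmetry is linear in the volume fraction", {
  low <- cestopt:::quesp_model(2, ksw = 300, fb = 1e-4, r1a = 0.35,
                               r2a = 0.8, dw_ppm = 3, tsat_s = 0.3)
  high <- cestopt:::quesp_model(2, ksw = 300, fb = 2e-4, r1a = 0.35,
                                r2a = 0.8, dw_ppm = 3, tsat_s = 0.3)
  expect_equal(high / low, 2, tolerance = 0.02)
})

test_that("QUESP on Bloch-McConnell data recovers the exchange rate", {
  fb <- concentration_to_fraction(50, 3)
  ps <- amine_pools(fb = fb, kb = 350)
  series <- simulate_quesp(ps, powers_uT = 0:6, tsat_s = 3)
  fit <- quesp_fit(series, r1a = 1 / 2.8, r2a = 1 / 1.2, dw_ppm = 3,
                   mode = "fixed_concentration", fb = fb)
  est <- fit$estimate$estimate[fit$estimate$term == "ksw"]
  expect_lt(abs(est - 350) / 350, 0.1)
  # invariance to global rescaling of the signals
  series2 <- dplyr::mutate(series, s_plus = s_plus * 3.7,
                           s_minus = s_minus * 3.7, s0 = s0 * 3.7)
  fit2 <- quesp_fit(series2, r1a = 1 / 2.8, r2a = 1 / 1.2, dw_ppm = 3,
                    mode = "fixed_concentration", fb = fb)
  expect_equal(fit2$estimate$estimate[fit2$estimate$term == "ksw"], est,
               tolerance = 1e-9)
})

test_that("absent CEST effect is flagged as non-identifiable", {
  series <- tibble::tibble(power_uT = 0:6, s_plus = 0.8, s_minus = 0.8,
                           s0 = 1)
  expect_error(quesp_fit(series, r1a = 0.35, r2a = 0.8, dw_ppm = 3,
                         mode = "fixed_concentration", fb = 1e-3),
               class = "cestopt_nonidentifiable")
})

test_that("method comparison computes errors, ANOVA, Tukey and Pearson", {
  expect_equal(abs(100 - 97.58), 2.42)
  set.seed(7)
  truth <- seq(10, 100, length.out = 18)
  good <- tibble::tibble(method = "good", id = 1:18, truth = truth,
                         estimate = truth + rnorm(18, 0, 0.5))
  bad <- tibble::tibble(method = "bad", id = 1:18, truth = truth,
                        estimate = truth + rnorm(18, 25, 10))
  cmp <- method_comparison(dplyr::bind_rows(good, bad))
  expect_lt(cmp$anova$p.value, 0.01)
  expect_true(all(tidy(cmp)$significant))
  expect_equal(cmp$errors$abs_error,
               abs(cmp$errors$truth - cmp$errors$estimate))
  r_good <- cmp$pearson$r[cmp$pearson$method == "good"]
  expect_equal(r_good, cor(good$truth, good$estimate))

  same <- dplyr::bind_rows(
    dplyr::mutate(good, method = "a"), dplyr::mutate(good, method = "b"))
  cmp2 <- method_comparison(same)
  expect_gt(cmp2$anova$p.value, 0.99)
  expect_false(any(tidy(cmp2)$significant))

  uneven <- dplyr::bind_rows(good, bad[1:10, ])
  expect_error(method_comparison(uneven), "identical test set")
})

test_that("the reference schedule reproduces its documented structure", {
  ref <- reference_schedule(n = 10, wrf_ppm = 3, seed = 5)
  expect_equal(ref$tsat_s, rep(3, 10))
  expect_equal(ref$trec_s, rep(1, 10))
  expect_equal(ref$fa_deg, rep(60, 10))
  expect_equal(ref$wrf_ppm, rep(3, 10))
  expect_true(all(ref$omega1_uT >= 0 & ref$omega1_uT <= 6))
  expect_identical(reference_schedule(seed = 5)$omega1_uT,
                   ref$omega1_uT)
})
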