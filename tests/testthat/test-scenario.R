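test_that("parameter sampling is uniform within ranges and reproducible", {
  cfg <- amine_config()
  p1 <- sample_params(cfg, 1000, seed = 5)
  p2 <- sample_params(cfg, 1000, seed = 5)
  expect_identical(p1, p2)
  expect_named(p1, c("fb", "kb"))
  big <- sample_params(cfg, 1e4, seed = 6)
  for (nm in names(cfg$ranges)) {
    r <- cfg$ranges[[nm]]
    expect_gte(min(big[[nm]]), r[1])
    expect_lte(max(big[[nm]]), r[2])
    # extreme order statistics of 1e4 uniform draws sit near the bounds
    expect_lt(min(big[[nm]]), r[1] + 0.002 * diff(r))
    expect_gt(max(big[[nm]]), r[2] - 0.002 * diff(r))
  }
  expect_error(sample_params(cfg, 0), ">= 1")

  cfg_deg <- scenario_config(amine_pools(),
                             ranges = list(fb = c(1e-3, 1e-3),
                                           kb = c(500, 500)))
  pd <- sample_params(cfg_deg, 10, seed = 1)
  expect_true(all(pd$fb == 1e-3) && all(pd$kb == 500))
})

test_that("noise injection has the configured moments", {
  x <- matrix(0, 1000, 1000)
  y <- add_noise(x, 0.002, seed = 3)
  expect_equal(sd(y), 0.002, tolerance = 0.01)
  expect_equal(mean(y), 0, tolerance = 1e-5)
  expect_identical(add_noise(x, 0), x)
  expect_error(add_noise(x, -1), ">= 0")
})

test_that("two-norm normalization is exact, idempotent and scale invariant", {
  expect_equal(normalize_trajectory(rep(3, 10)), rep(1 / sqrt(10), 10))
  v <- c(0.3, -0.1, 0.45, 0.2)
  u <- normalize_trajectory(v)
  expect_equal(sum(u^2), 1)
  expect_equal(normalize_trajectory(u), u)
  expect_equal(normalize_trajectory(7.3 * v), u)
  expect_error(normalize_trajectory(rep(0, 4)), "zero-norm")
  M <- matrix(rnorm(20), 4)
  expect_equal(rowSums(normalize_trajectory(M)^2), rep(1, 4))
})

test_that("concentration and volume fraction convert exactly both ways", {
  expect_equal(concentration_to_fraction(0, 3), 0)
  expect_equal(concentration_to_fraction(100, 3), 300 / 111000)
  conc <- c(12.5, 33, 100)
  expect_equal(fraction_to_concentration(
    concentration_to_fraction(conc, 3), 3), conc)
  expect_error(concentration_to_fraction(-1, 3), ">= 0")
})

test_that("dictionary rows are normalized simulations of the grid product", {
  cfg <- amine_config()
  sch <- init_schedule(cfg, mode = "fixed")
  grid <- list(fb = c(5e-4, 1e-3, 2e-3), kb = c(200, 700, 1200))
  dict <- build_dictionary(cfg, sch, grid = grid)
  expect_equal(nrow(dict$signals), 9)
  expect_equal(nrow(dict$params), 9)
  expect_equal(rowSums(dict$signals^2), rep(1, 9), tolerance = 1e-12)
  # spot-check rows against direct simulation
  for (i in c(1, 5, 9)) {
    ps <- amine_pools(fb = dict$params$fb[i], kb = dict$params$kb[i])
    expect_equal(as.vector(dict$signals[i, ]),
                 normalize_trajectory(simulate_schedule(ps, sch, cfg$field)),
                 tolerance = 1e-12)
  }
  # single grid point
  d1 <- build_dictionary(cfg, sch, grid = list(fb = 1e-3, kb = 500))
  expect_equal(nrow(d1$signals), 1)
  # reproducibility is bit-identical
  d2 <- build_dictionary(cfg, sch, grid = grid)
  expect_identical(dict$signals, d2$signals)
  expect_error(build_dictionary(cfg, sch, grid = grid, max_entries = 5),
               "cap")
})

test_that("distinct parameter pairs give distinct noise-free trajectories", {
  cfg <- amine_config()
  sch <- init_schedule(cfg, mode = "random", seed = 2)
  dict <- build_dictionary(cfg, sch,
                           grid = list(fb = seq(5e-4, 2.5e-3, length.out = 6),
                                       kb = seq(150, 1350, length.out = 6)))
  d <- as.matrix(dist(dict$signals))
  expect_gt(min(d[upper.tri(d)]), 0)
})

test_that("scenario YAML round-trips and rejects unknown keys", {
  cfg <- amine_config(trainable = c("omega1_uT", "trec_s"))
  path <- tempfile(fileext = ".yaml")
  save_scenario(cfg, path)
  cfg2 <- load_scenario(path)
  expect_equal(cfg2$ranges, cfg$ranges)
  expect_equal(cfg2$training, cfg$training)
  expect_equal(cfg2$schedule$trainable, cfg$schedule$trainable)
  expect_equal(cfg2$pools$solute, cfg$pools$solute)
  expect_equal(cfg2$field$b0, cfg$field$b0)

  y <- yaml::read_yaml(path)
  y$typo_key <- 1
  yaml::write_yaml(y, path)
  expect_error(load_scenario(path), "typo_key")
})

test_that("minimal scenario files take the documented defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "pools:",
    "  water: {r1a: 0.35, r2a: 0.8}",
    "  solute: {fb: 0.001, kb: 500, dwb: 3}",
    "ranges:",
    "  fb: [0.0003, 0.003]",
    "  kb: [100, 1400]"), path)
  cfg <- load_scenario(path)
  expect_equal(cfg$n_images, 10L)
  expect_equal(cfg$noise_sigma, 0.002)
  expect_equal(cfg$training$batch_size, 256)
  expect_equal(cfg$training$epochs, 100)
  expect_equal(cfg$training$lr_schedule, 1e-3)
  expect_equal(cfg$training$lr_net, 1e-4)
  expect_equal(cfg$field$b0, 9.4)
})

test_that("dictionary CSV persistence round-trips", {
  cfg <- amine_config()
  sch <- init_schedule(cfg, mode = "fixed")
  dict <- build_dictionary(cfg, sch, grid = list(fb = c(5e-4, 1e-3),
                                                 kb = c(300, 900)))
  stem <- tempfile()
  save_dictionary(dict, stem)
  d2 <- load_dictionary(stem)
  expect_equal(d2$signals, dict$signals, tolerance = 1e-12)
  expect_equal(as.data.frame(d2$params), as.data.frame(dict$params),
               tolerance = 1e-12)
})
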