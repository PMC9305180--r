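#' Magnetization transfer ratio asymmetry
#'
#' `MTRasym = (S(-dw) - S(+dw)) / S0`: positive when saturation on the
#' solute (label) side removes more water signal than the reference side.
#'
#' @param s_minus Signal with saturation at the reference offset (-dw).
#' @param s_plus Signal with saturation at the label offset (+dw).
#' @param s0 Unsaturated signal (> 0).
#' @return Numeric vector of asymmetries.
#' @export
mtr_asym <- function(s_minus, s_plus, s0) {
  if (any(s0 <= 0)) abort("s0 must be positive")
  (s_minus - s_plus) / s0
}

#' Fingerprint dictionary dot-product matching
#'
#' Two-norm normalizes each query trajectory and returns, per query, the
#' dictionary entry with the maximum inner product (ties broken by lowest
#' row index) together with its generating parameters and the score.
#'
#' @param trajectories Numeric vector (one trajectory) or matrix with one
#'   trajectory per row; raw (unnormalized) signals are accepted.
#' @param dictionary A `cest_dictionary` from [build_dictionary()].
#' @param chunk Rows matched per block (bounds the score-matrix memory).
#' @return Tibble with `match` (dictionary row), `score`, and one column
#'   per dictionary parameter.
#' @export
dot_product_match <- function(trajectories, dictionary, chunk = 2048L) {
  stopifnot(inherits(dictionary, "cest_dictionary"))
  X <- if (is.matrix(trajectories)) trajectories
       else matrix(trajectories, nrow = 1)
  if (!nrow(dictionary$signals)) abort("empty dictionary")
  if (ncol(X) != ncol(dictionary$signals))
    abort("trajectory width does not match dictionary")
  Xn <- normalize_trajectory(X)
  D <- t(dictionary$signals)
  idx <- integer(nrow(Xn)); score <- numeric(nrow(Xn))
  for (start in seq(1, nrow(Xn), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(Xn))
    sc <- Xn[rows, , drop = FALSE] %*% D
    idx[rows] <- apply(sc, 1, which.max)
    score[rows] <- sc[cbind(seq_along(rows), idx[rows])]
  }
  dplyr::bind_cols(tibble::tibble(match = idx, score = score),
                   dictionary$params[idx, , drop = FALSE])
}

#' Simulate a QUESP measurement series with the full spin physics
#'
#' For each saturation power, the water signal after a single saturation
#' block at the label offset (+dw of the solute) and at the mirrored
#' reference offset (-dw), each starting from thermal equilibrium (long
#' repetition time), plus the unsaturated signal `s0`.
#'
#' @param pools A [pool_system()] with a solute pool.
#' @param powers_uT Saturation powers (default 0:6 microtesla).
#' @param tsat_s Saturation duration (default 3 s).
#' @param fa_deg Readout flip angle (default 90).
#' @param field A [field_context()].
#' @return Tibble of class data, columns `power_uT`, `s_plus`, `s_minus`,
#'   `s0`.
#' @export
simulate_quesp <- function(pools, powers_uT = 0:6, tsat_s = 3, fa_deg = 90,
                           field = field_context()) {
  stopifnot(inherits(pools, "pool_system"))
  if (is.null(pools$solute)) abort("QUESP simulation needs a solute pool")
  dw <- pools$solute$dwb
  meq <- equilibrium_state(pools)
  sig <- function(w1, wrf) {
    m <- saturation_propagate(meq, pools, w1, tsat_s, wrf, field)
    readout_relax(m, pools, fa_deg, 0)$signal
  }
  s0 <- sig(0, dw)
  tibble::tibble(
    power_uT = powers_uT,
    s_plus = vapply(powers_uT, sig, numeric(1), wrf = dw),
    s_minus = vapply(powers_uT, sig, numeric(1), wrf = -dw),
    s0 = s0)
}

# Finite-saturation-time QUESP model for the asymmetry as a function of
# saturation amplitude, in the rotating-frame relaxation (R1rho) form:
# exchange-dependent relaxation of water when saturating on the solute
# resonance is Rex = fb*ksw*w1^2 / (w1^2 + ksw*(ksw + R2b)); the mirrored
# reference offset picks up the Lorentzian tail of the same line at
# distance 2*dw. Each side's longitudinal decay along the effective field
# (tilt angle theta, sin^2 = w1^2/(w1^2 + dw^2)) gives
# Z(Tsat) = Zss + (cos^2 - Zss) exp(-R1rho Tsat), Zss = cos^2 R1a / R1rho,
# and MTRasym = Z_ref - Z_label. Accounts for direct water saturation
# (spillover) and solute-line broadening, which the textbook
# alpha = w1^2/(w1^2 + ksw^2) form neglects.
quesp_model <- function(power_uT, ksw, fb, r1a, r2a, dw_ppm, tsat_s,
                        b0 = 9.4, r2b = 30) {
  w1 <- 2 * pi * 42.577 * power_uT
  dw <- 2 * pi * 42.577 * b0 * dw_ppm
  s2 <- w1^2 / (w1^2 + dw^2)
  c2 <- 1 - s2
  width2 <- w1^2 + ksw * (ksw + r2b)
  rex_lab <- fb * ksw * w1^2 / width2
  rex_ref <- rex_lab * width2 / (width2 + (2 * dw)^2)
  zt <- function(rex) {
    r1rho <- r1a * c2 + r2a * s2 + rex
    zss <- c2 * r1a / r1rho
    zss + (c2 - zss) * exp(-r1rho * tsat_s)
  }
  zt(rex_ref) - zt(rex_lab)
}

#' Exchange-rate estimation from saturation-power series (QUESP)
#'
#' Nonlinear least-squares fit of the measured MTR asymmetry versus
#' saturation power using a finite-saturation-time exchange model. With
#' `mode = "fixed_concentration"` the solute volume fraction is a known
#' input and only the exchange rate is fitted; with
#' `mode = "free_concentration"` both are estimated simultaneously.
#'
#' @param series Data frame with columns `power_uT`, `s_plus`, `s_minus`,
#'   `s0` (see [simulate_quesp()] for the convention).
#' @param r1a,r2a Measured water longitudinal / transverse relaxation
#'   rates (s^-1), fixed inputs to the fit.
#' @param dw_ppm Solute chemical shift (ppm), the saturation offset used.
#' @param tsat_s Saturation duration of the series (s).
#' @param b0 Static field (T).
#' @param r2b Assumed solute transverse relaxation rate (s^-1).
#' @param mode `"fixed_concentration"` or `"free_concentration"`.
#' @param fb Known solute volume fraction (required for fixed mode; used
#'   as the starting value in free mode if supplied).
#' @return An object of class `quesp_fit` with `estimate` (tibble of
#'   fitted parameters), the underlying `fit`, and the input data with
#'   fitted values.
#' @export
quesp_fit <- function(series, r1a, r2a, dw_ppm, tsat_s = 3, b0 = 9.4,
                      r2b = 30,
                      mode = c("fixed_concentration", "free_concentration"),
                      fb = NULL) {
  mode <- match.arg(mode)
  need <- c("power_uT", "s_plus", "s_minus", "s0")
  if (!all(need %in% names(series)))
    abort(paste0("series must have columns ", paste(need, collapse = ", ")))
  df <- tibble::tibble(power_uT = series$power_uT,
                       mtr = mtr_asym(series$s_minus, series$s_plus,
                                      series$s0))
  if (all(abs(df$mtr) < sqrt(.Machine$double.eps)))
    rlang::abort("no measurable CEST effect: exchange rate not identifiable",
                 class = "cestopt_nonidentifiable")
  if (mode == "fixed_concentration") {
    if (is.null(fb)) abort("fixed_concentration mode requires fb")
    fit <- minpack.lm::nlsLM(
      mtr ~ quesp_model(power_uT, ksw, fb, r1a, r2a, dw_ppm, tsat_s, b0, r2b),
      data = df, start = list(ksw = 500), lower = c(ksw = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    if (sum(abs(df$mtr) > sqrt(.Machine$double.eps)) < 3)
      abort("free_concentration mode needs >= 3 powers with nonzero asymmetry")
    fit <- minpack.lm::nlsLM(
      mtr ~ quesp_model(power_uT, ksw, fb, r1a, r2a, dw_ppm, tsat_s, b0, r2b),
      data = df, start = list(ksw = 500, fb = fb %||% 1e-3),
      lower = c(ksw = 0, fb = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- tibble::as_tibble(summary(fit)$coefficients, rownames = "term")
  names(est) <- c("term", "estimate", "std.error", "statistic", "p.value")
  df$fitted <- fitted(fit)
  structure(list(estimate = est, fit = fit, data = df, mode = mode,
                 r1a = r1a, tsat_s = tsat_s),
            class = "quesp_fit")
}

#' @export
print.quesp_fit <- function(x, ...) {
  cat(sprintf("<quesp_fit (%s)>\n", x$mode))
  print(x$estimate)
  invisible(x)
}

#' @describeIn quesp_fit Fitted parameters as a tibble.
#' @param x A `quesp_fit`.
#' @param ... Unused.
#' @export
tidy.quesp_fit <- function(x, ...) x$estimate

#' @describeIn quesp_fit One-row fit summary.
#' @export
glance.quesp_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = nrow(x$data),
                 sigma = summary(x$fit)$sigma,
                 rss = sum(resid(x$fit)^2))
}

#' Seeded pseudo-random reference schedule
#'
#' An unoptimized fingerprinting protocol: saturation powers drawn
#' uniformly within bounds, fixed 3 s saturation, 1 s recovery, 60 degree
#' flip angle, and saturation on-resonance with the target solute.
#'
#' @param n Number of images (default 10).
#' @param wrf_ppm Solute chemical shift to saturate at (ppm).
#' @param seed Seed for the power draw.
#' @param power_range Power bounds in microtesla (default `c(0, 6)`).
#' @return An [acq_schedule()] (no trainable columns).
#' @export
reference_schedule <- function(n = 10, wrf_ppm = 3, seed = 1,
                               power_range = c(0, 6)) {
  set.seed(seed)
  acq_schedule(omega1_uT = runif(n, power_range[1], power_range[2]),
               tsat_s = 3, wrf_ppm = wrf_ppm, fa_deg = 60, trec_s = 1)
}

#' Compare quantification variants on a common test set
#'
#' Computes per-case absolute errors `|truth - estimate|` for each method,
#' a one-way ANOVA across methods, pairwise Tukey HSD decisions at the
#' given significance level, and per-method Pearson correlations between
#' truth and estimate.
#'
#' @param results Data frame with columns `method`, `id` (test-case
#'   label), `truth`, `estimate`; every method must cover the identical
#'   set of ids.
#' @param alpha Significance level for Tukey decisions (default 0.05).
#' @return An object of class `method_comparison` with elements `errors`,
#'   `anova`, `tukey`, and `pearson` (all tibbles).
#' @export
method_comparison <- function(results, alpha = 0.05) {
  need <- c("method", "id", "truth", "estimate")
  if (!all(need %in% names(results)))
    abort(paste0("results must have columns ", paste(need, collapse = ", ")))
  results <- tibble::as_tibble(results)
  ids <- split(results$id, results$method)
  ref <- sort(unique(results$id))
  same <- vapply(ids, function(v) identical(sort(v), ref), logical(1))
  if (!all(same)) abort("all methods must share the identical test set")
  errors <- dplyr::mutate(results,
                          abs_error = abs(.data$truth - .data$estimate),
                          method = factor(.data$method))
  fit <- aov(abs_error ~ method, data = errors)
  s <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(df = s$Df[1], df_resid = s$Df[2],
                              statistic = s$`F value`[1],
                              p.value = s$`Pr(>F)`[1])
  tk <- TukeyHSD(fit)$method
  tukey_tbl <- tibble::tibble(
    contrast = rownames(tk), diff = tk[, "diff"], conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"], adj.p.value = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha)
  pearson_tbl <- purrr::map_dfr(split(errors, errors$method),
    function(d) {
      ct <- suppressWarnings(cor.test(d$truth, d$estimate))
      tibble::tibble(method = as.character(d$method[1]),
                     r = unname(ct$estimate), p.value = ct$p.value,
                     median_abs_error = stats::median(d$abs_error),
                     mean_abs_error = mean(d$abs_error))
    })
  structure(list(errors = errors, anova = anova_tbl, tukey = tukey_tbl,
                 pearson = pearson_tbl, alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$pearson)
  cat(sprintf("ANOVA: F(%d, %d) = %.3g, p = %.3g\n", x$anova$df,
              x$anova$df_resid, x$anova$statistic, x$anova$p.value))
  invisible(x)
}

#' @describeIn method_comparison Pairwise Tukey HSD table.
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @export
tidy.method_comparison <- function(x, ...) x$tukey

#' @describeIn method_comparison One-row ANOVA summary.
#' @export
glance.method_comparison <- function(x, ...) x$anova

#' @describeIn method_comparison Absolute-error box plot by method.
#' @param object A `method_comparison`.
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$method, y = .data$abs_error)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "absolute error")
}
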