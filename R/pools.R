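#' Define a multi-pool spin system
#'
#' Describes the tissue ground truth for a chemical-exchange experiment:
#' the free water pool ("a"), an optional exchangeable solute pool ("b",
#' e.g. amide, amine or guanidinium protons) and an optional semisolid
#' macromolecular pool ("c"). Relaxation is parameterized by rates in
#' s^-1; pool sizes by proton volume fractions relative to water;
#' exchange by the solute-to-water rate in s^-1 (often written Hz);
#' chemical shifts in ppm relative to the water resonance.
#'
#' @param r1a,r2a Water longitudinal / transverse relaxation rates (s^-1).
#' @param m0 Equilibrium water longitudinal magnetization (normalized).
#' @param solute Optional list with elements `fb` (volume fraction),
#'   `kb` (exchange rate s^-1), `dwb` (ppm), and optionally `r1b`, `r2b`
#'   (defaults 1 and 30 s^-1, typical for labile amine/amide protons).
#' @param semisolid Optional list with elements `fc`, `kc`, and optionally
#'   `dwc` (default 0 ppm), `r1c` (default 1 s^-1), `r2c` (default 1e5 s^-1,
#'   i.e. T2 of 10 us, modeling the semisolid pool as a very short-T2
#'   Lorentzian Bloch-McConnell pool).
#' @return An object of class `pool_system`.
#' @examples
#' pool_system(r1a = 1/2.8, r2a = 1/1.2,
#'             solute = list(fb = 0.001, kb = 500, dwb = 3))
#' @export
pool_system <- function(r1a, r2a, m0 = 1,
                        solute = NULL, semisolid = NULL) {
  stopifnot(is.numeric(r1a), is.numeric(r2a), is.numeric(m0))
  if (!is.finite(r1a) || !is.finite(r2a) || !is.finite(m0) ||
      r1a <= 0 || r2a <= 0 || m0 <= 0)
    abort("water pool requires finite positive r1a, r2a, m0")
  ps <- list(water = list(r1a = r1a, r2a = r2a, m0 = m0))
  if (!is.null(solute)) {
    solute <- complete_pool(solute, c(fb = NA, kb = NA, dwb = NA,
                                      r1b = 1, r2b = 30), "solute")
    check_xpool(solute$fb, solute$kb, "solute")
    ps$solute <- solute
  }
  if (!is.null(semisolid)) {
    semisolid <- complete_pool(semisolid, c(fc = NA, kc = NA, dwc = 0,
                                            r1c = 1, r2c = 1e5), "semisolid")
    check_xpool(semisolid$fc, semisolid$kc, "semisolid")
    ps$semisolid <- semisolid
  }
  structure(ps, class = "pool_system")
}

complete_pool <- function(x, defaults, name) {
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    abort(paste0("unknown ", name, " field(s): ", paste(unknown, collapse = ", ")))
  out <- as.list(defaults)
  out[names(x)] <- x
  missing <- names(out)[vapply(out, function(v) is.na(v[1]), logical(1))]
  if (length(missing))
    abort(paste0(name, " pool missing required field(s): ",
                 paste(missing, collapse = ", ")))
  rates <- setdiff(names(out), c("fb", "kb", "fc", "kc", "dwb", "dwc"))
  for (r in rates) if (!is.finite(out[[r]]) || out[[r]] <= 0)
    abort(paste0(name, " relaxation rates must be finite and positive"))
  out
}

check_xpool <- function(f, k, name) {
  if (!is.finite(f) || f < 0 || f >= 1)
    abort(paste0(name, " volume fraction must satisfy 0 <= f < 1"))
  if (!is.finite(k) || k < 0)
    abort(paste0(name, " exchange rate must be >= 0"))
}

#' @export
print.pool_system <- function(x, ...) {
  cat(sprintf("<pool_system: %d pool(s)>\n", n_pools(x)))
  cat(sprintf("  water:     R1a=%.4g R2a=%.4g M0=%.4g\n",
              x$water$r1a, x$water$r2a, x$water$m0))
  if (!is.null(x$solute))
    cat(sprintf("  solute:    fb=%.4g kb=%.4g dwb=%.4g ppm (R1b=%.3g R2b=%.3g)\n",
                x$solute$fb, x$solute$kb, x$solute$dwb,
                x$solute$r1b, x$solute$r2b))
  if (!is.null(x$semisolid))
    cat(sprintf("  semisolid: fc=%.4g kc=%.4g dwc=%.4g ppm (R1c=%.3g R2c=%.3g)\n",
                x$semisolid$fc, x$semisolid$kc, x$semisolid$dwc,
                x$semisolid$r1c, x$semisolid$r2c))
  invisible(x)
}

#' Number of pools in a spin system
#' @param pools A [pool_system()].
#' @return Integer 1, 2 or 3.
#' @export
n_pools <- function(pools) {
  stopifnot(inherits(pools, "pool_system"))
  1L + !is.null(pools$solute) + !is.null(pools$semisolid)
}

# Flatten to the fixed 13-element layout the C++ propagator expects.
# Order: R1a,R2a,M0, fb,kb,R1b,R2b,dwb, fc,kc,R1c,R2c,dwc.
pool_vector <- function(pools) {
  s <- pools$solute %||% list(fb = 0, kb = 0, r1b = 1, r2b = 30, dwb = 0)
  c3 <- pools$semisolid %||% list(fc = 0, kc = 0, r1c = 1, r2c = 1e5, dwc = 0)
  c(pools$water$r1a, pools$water$r2a, pools$water$m0,
    s$fb, s$kb, s$r1b, s$r2b, s$dwb,
    c3$fc, c3$kc, c3$r1c, c3$r2c, c3$dwc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thermal-equilibrium magnetization state
#'
#' Each pool contributes (Mx, My, Mz) rotating-frame components, water
#' first; at equilibrium all transverse components vanish and each pool's
#' Mz equals its volume fraction times the water M0.
#'
#' @param pools A [pool_system()].
#' @return Numeric vector of length `3 * n_pools(pools)`.
#' @export
equilibrium_state <- function(pools) {
  np <- n_pools(pools)
  m <- numeric(3 * np)
  m[3] <- pools$water$m0
  if (np >= 2) m[6] <- pools$solute$fb * pools$water$m0
  if (np >= 3) m[9] <- pools$semisolid$fc * pools$water$m0
  m
}

#' Static-field context
#'
#' @param b0 Static field strength in Tesla (default 9.4, a typical
#'   preclinical scanner).
#' @param gamma_2pi Proton gyromagnetic ratio over 2*pi in MHz/T.
#' @return An object of class `field_context`.
#' @export
field_context <- function(b0 = 9.4, gamma_2pi = 42.577) {
  if (!is.finite(b0) || b0 <= 0) abort("b0 must be finite and positive")
  structure(list(b0 = b0, gamma_2pi = gamma_2pi), class = "field_context")
}
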