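#' Specify a synthetic vial phantom
#'
#' A square imaging grid holding circular vials of known solute
#' concentration and exchange rate in a water-only background, emulating
#' the tube phantoms used to validate quantitative CEST methods. The mm
#' coordinate system is centered on the image; pixel (i, j) covers
#' `fov_mm / grid` mm per side.
#'
#' @param vials Data frame with columns `x_mm`, `y_mm`, `radius_mm`,
#'   `conc_mM`, `ksw_hz` (one row per vial).
#' @param grid Matrix size (default 64).
#' @param fov_mm Field of view in mm (default 32).
#' @param n_protons Exchangeable protons per solute molecule used to map
#'   concentration to volume fraction (default 3, amine-like).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(vials, grid = 64, fov_mm = 32, n_protons = 3) {
  vials <- tibble::as_tibble(vials)
  need <- c("x_mm", "y_mm", "radius_mm", "conc_mM", "ksw_hz")
  if (!all(need %in% names(vials)))
    abort(paste0("vials must have columns ", paste(need, collapse = ", ")))
  if (any(vials$conc_mM < 0) || any(vials$ksw_hz < 0))
    abort("concentrations and exchange rates must be >= 0")
  half <- fov_mm / 2
  if (any(abs(vials$x_mm) + vials$radius_mm > half |
          abs(vials$y_mm) + vials$radius_mm > half))
    abort("vials must lie fully inside the field of view")
  if (nrow(vials) > 1) {
    d <- as.matrix(stats::dist(vials[, c("x_mm", "y_mm")]))
    rr <- outer(vials$radius_mm, vials$radius_mm, `+`)
    diag(d) <- Inf
    if (any(d < rr)) abort("vials overlap")
  }
  structure(list(vials = vials, grid = as.integer(grid), fov_mm = fov_mm,
                 n_protons = n_protons), class = "phantom_spec")
}

#' Default three-vial layout
#'
#' Three equal vials on a ring, the classic tube-phantom arrangement.
#'
#' @param conc_mM,ksw_hz Length-3 vectors of vial concentrations (mM) and
#'   exchange rates (s^-1).
#' @param radius_mm Vial radius (default 5.013 mm, i.e. a 79 mm^2 circle).
#' @param ring_mm Distance of vial centers from the image center.
#' @inheritParams phantom_spec
#' @return A [phantom_spec()].
#' @export
three_vial_phantom <- function(conc_mM, ksw_hz, radius_mm = sqrt(79 / pi),
                               ring_mm = 8.5, grid = 64, fov_mm = 32,
                               n_protons = 3) {
  stopifnot(length(conc_mM) == 3, length(ksw_hz) == 3)
  ang <- c(90, 210, 330) * pi / 180
  phantom_spec(tibble::tibble(
    x_mm = ring_mm * cos(ang), y_mm = ring_mm * sin(ang),
    radius_mm = radius_mm, conc_mM = conc_mM, ksw_hz = ksw_hz),
    grid = grid, fov_mm = fov_mm, n_protons = n_protons)
}

# Pixel-center coordinates (mm) of a spec's grid.
pixel_centers <- function(spec) {
  px <- spec$fov_mm / spec$grid
  (seq_len(spec$grid) - 0.5) * px - spec$fov_mm / 2
}

# Integer label matrix: 0 background, i for vial i.
phantom_labels <- function(spec) {
  xy <- pixel_centers(spec)
  lab <- matrix(0L, spec$grid, spec$grid)
  for (i in seq_len(nrow(spec$vials))) {
    v <- spec$vials[i, ]
    d2 <- outer((xy - v$x_mm)^2, (xy - v$y_mm)^2, `+`)
    lab[d2 <= v$radius_mm^2] <- i
  }
  lab
}

#' Render a noisy image stack from a vial phantom
#'
#' Simulates the per-voxel signal trajectory of every pixel under the
#' given schedule (vial pixels use that vial's volume fraction and
#' exchange rate; background pixels contain water only), then injects
#' white Gaussian noise. Ground-truth parameter maps are returned with
#' the stack.
#'
#' @param spec A [phantom_spec()].
#' @param pools Template [pool_system()] supplying relaxation constants
#'   and the solute chemical shift (must contain a solute pool).
#' @param schedule An [acq_schedule()].
#' @param field A [field_context()].
#' @param noise_sigma Additive noise standard deviation.
#' @param seed Optional seed for the noise draw.
#' @return An object of class `cest_phantom`: `stack` (N x H x W array),
#'   `truth_fb`, `truth_kb` (H x W matrices), `labels`, and `spec`.
#' @export
render_phantom <- function(spec, pools, schedule, field = field_context(),
                           noise_sigma = 0.002, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(pools, "pool_system"),
            inherits(schedule, "acq_schedule"))
  if (is.null(pools$solute)) abort("phantom rendering needs a solute pool")
  lab <- phantom_labels(spec)
  fb_vals <- concentration_to_fraction(spec$vials$conc_mM, spec$n_protons)
  kb_vals <- spec$vials$ksw_hz
  # unique tissue classes: background (water only) + one per vial
  params <- tibble::tibble(fb = c(0, fb_vals), kb = c(0, kb_vals))
  sims <- simulate_signals(params, pools, schedule, field)
  traj <- sims$signal                      # (nvials+1) x N
  N <- ncol(traj)
  H <- spec$grid
  stack <- array(0, c(N, H, H))
  for (n in seq_len(N))
    stack[n, , ] <- matrix(traj[lab + 1L, n], H, H)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    stack <- stack + array(rnorm(length(stack), 0, noise_sigma), dim(stack))
  }
  truth_fb <- matrix(c(0, fb_vals)[lab + 1L], H, H)
  truth_kb <- matrix(c(0, kb_vals)[lab + 1L], H, H)
  structure(list(stack = stack, truth_fb = truth_fb, truth_kb = truth_kb,
                 labels = lab, spec = spec),
            class = "cest_phantom")
}

#' Circular ROIs centered on each vial
#'
#' @param spec A [phantom_spec()].
#' @param radius_mm ROI radius; the default 5.013 mm gives the standard
#'   79 mm^2 analysis circle, shrunk to the vial radius when the vial is
#'   smaller.
#' @return Tibble with columns `roi`, `x_mm`, `y_mm`, `radius_mm`.
#' @export
vial_rois <- function(spec, radius_mm = sqrt(79 / pi)) {
  tibble::tibble(roi = seq_len(nrow(spec$vials)),
                 x_mm = spec$vials$x_mm, y_mm = spec$vials$y_mm,
                 radius_mm = pmin(radius_mm, spec$vials$radius_mm))
}

#' Read / write ROI specifications as JSON
#'
#' @param rois Tibble with `roi`, `x_mm`, `y_mm`, `radius_mm`.
#' @param path JSON file path.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write parameter maps to NIfTI
#'
#' Writes the volume-fraction and exchange-rate maps of a reconstruction
#' as `<stem>_fb.nii.gz` and `<stem>_kb.nii.gz` with the pixel size
#' implied by the field of view.
#'
#' @param map A `cest_map` from [reconstruct_map()].
#' @param stem Output path stem.
#' @param fov_mm Field of view (mm) for the voxel size header.
#' @export
write_map_nifti <- function(map, stem, fov_mm = 32) {
  px <- fov_mm / nrow(map$fb)
  for (nm in c("fb", "kb")) {
    img <- RNifti::asNifti(map[[nm]], pixdim = c(px, px))
    RNifti::writeNifti(img, paste0(stem, "_", nm, ".nii.gz"))
  }
  invisible(stem)
}

#' Read a parameter map written by [write_map_nifti()]
#'
#' @param stem Path stem used when writing.
#' @return A `cest_map` (without mask).
#' @export
read_map_nifti <- function(stem) {
  fb <- matrix(RNifti::readNifti(paste0(stem, "_fb.nii.gz")),
               nrow = dim(RNifti::readNifti(paste0(stem, "_fb.nii.gz")))[1])
  kb_img <- RNifti::readNifti(paste0(stem, "_kb.nii.gz"))
  kb <- matrix(kb_img, nrow = dim(kb_img)[1])
  structure(list(fb = fb, kb = kb, mask = NULL, elapsed_s = NA_real_),
            class = "cest_map")
}
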