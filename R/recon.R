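#' Voxelwise quantitative map reconstruction
#'
#' Feeds every voxel's raw trajectory through two-norm normalization and
#' the trained reconstruction network, producing volume-fraction and
#' exchange-rate maps. Voxels whose trajectory has zero norm (no signal)
#' are masked out rather than raising an error.
#'
#' @param net A trained [recon_net()].
#' @param stack Image stack, an N x H x W array whose first dimension
#'   matches the network input width.
#' @param mask Optional logical H x W matrix restricting reconstruction.
#' @return An object of class `cest_map`: matrices `fb` and `kb` (named
#'   after the network targets; `NA` outside the mask), the effective
#'   `mask`, and the reconstruction wall time `elapsed_s`.
#' @export
reconstruct_map <- function(net, stack, mask = NULL) {
  stopifnot(inherits(net, "recon_net"), is.array(stack),
            length(dim(stack)) == 3)
  d <- dim(stack)
  if (d[1] != net$n_in)
    abort(sprintf("stack has %d images but network expects %d", d[1],
                  net$n_in))
  H <- d[2]; W <- d[3]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  if (!any(mask)) abort("empty mask")
  t0 <- proc.time()[["elapsed"]]
  X <- t(matrix(stack, nrow = d[1]))            # (H*W) x N, column-major
  sel <- as.vector(mask)
  nrm <- sqrt(rowSums(X^2))
  sel <- sel & nrm > 0
  out <- net_forward(net, X[sel, , drop = FALSE] / nrm[sel])
  maps <- lapply(out, function(v) {
    m <- rep(NA_real_, H * W)
    m[sel] <- v
    matrix(m, H, W)
  })
  structure(list(fb = maps[[1]], kb = maps[[2]],
                 mask = matrix(sel, H, W),
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "cest_map")
}

#' @export
print.cest_map <- function(x, ...) {
  cat(sprintf("<cest_map: %d x %d (%d voxels reconstructed in %.3g s)>\n",
              nrow(x$fb), ncol(x$fb),
              if (is.null(x$mask)) length(x$fb) else sum(x$mask),
              x$elapsed_s))
  invisible(x)
}

#' ROI statistics on parameter maps
#'
#' Mean, standard deviation and voxel count of both parameter maps inside
#' each circular region of interest.
#'
#' @param map A `cest_map` from [reconstruct_map()].
#' @param rois Tibble with columns `roi`, `x_mm`, `y_mm`, `radius_mm`
#'   (e.g. from [vial_rois()] or [read_rois()]).
#' @param fov_mm Field of view (mm) defining the pixel geometry.
#' @return Tibble with one row per ROI: `roi`, `n_voxels`, `fb_mean`,
#'   `fb_sd`, `kb_mean`, `kb_sd`.
#' @export
roi_stats <- function(map, rois, fov_mm = 32) {
  stopifnot(inherits(map, "cest_map"))
  H <- nrow(map$fb)
  px <- fov_mm / H
  xy <- (seq_len(H) - 0.5) * px - fov_mm / 2
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    inside <- outer((xy - r$x_mm)^2, (xy - r$y_mm)^2, `+`) <= r$radius_mm^2
    if (!is.null(map$mask)) inside <- inside & map$mask
    if (!any(inside)) abort(paste0("ROI ", r$roi, " is empty"))
    fb <- map$fb[inside]; kb <- map$kb[inside]
    tibble::tibble(roi = r$roi, n_voxels = sum(inside),
                   fb_mean = mean(fb), fb_sd = sd(fb),
                   kb_mean = mean(kb), kb_sd = sd(kb))
  })
}

#' Plot a reconstructed parameter map pair
#'
#' @param object A `cest_map`.
#' @param ... Unused.
#' @return A ggplot object with one facet per parameter.
#' @export
autoplot.cest_map <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(c("fb", "kb"), function(nm) {
    m <- object[[nm]]
    tibble::tibble(parameter = nm,
                   x = rep(seq_len(nrow(m)), ncol(m)),
                   y = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
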