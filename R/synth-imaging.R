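#' Parameters for the synthetic dye-filled astrocyte image
#'
#' Describes a two-photon-like frame of a dye-loaded astrocyte: a bright
#' unsaturated soma (`soma_peak`, the F_max of the volume-fraction equation),
#' filamentous branches radiating from it, and a dim unresolved leaflet field
#' filling the neuropil at intensity
#' `background + leaflet_vf * (soma_peak - background)`. A dye-free circle of
#' pure background is embedded at a known location so the background estimator
#' has a valid target.
#'
#' @param frame_size_um frame side lengths in micrometers (length 2).
#' @param pixel_size_um lateral pixel size, micrometers per pixel.
#' @param soma_center soma center (x, y) in micrometers; default frame middle.
#' @param soma_radius_um soma radius in micrometers.
#' @param soma_peak soma fluorescence (arbitrary units); this is F_max.
#' @param background background fluorescence F_0.
#' @param leaflet_vf ground-truth leaflet volume fraction in `[0, 1]`.
#' @param n_branches number of straight branches radiating from the soma.
#' @param branch_length_um branch length in micrometers.
#' @param branch_width_um branch width in micrometers (2-4 px at default
#'   resolution).
#' @param branch_peak branch fluorescence; defaults to 90% of dynamic range.
#' @param bg_circle_center center of the dye-free circle (micrometers);
#'   default lower-left corner region.
#' @param bg_circle_diameter_um diameter of the dye-free circle (>= 10).
#' @param n_planes number of z-planes (identical scene, independent noise).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed; generators are pure functions of (params, seed).
#' @return an `imaging_params` list.
#' @export
imaging_params <- function(frame_size_um = c(100, 100),
                           pixel_size_um = 0.25,
                           soma_center = frame_size_um / 2,
                           soma_radius_um = 3.5,
                           soma_peak = 200,
                           background = 10,
                           leaflet_vf = 0.032,
                           n_branches = 6,
                           branch_length_um = 40,
                           branch_width_um = 0.75,
                           branch_peak = background + 0.9 * (soma_peak - background),
                           bg_circle_center = c(12, 12),
                           bg_circle_diameter_um = 12,
                           n_planes = 1,
                           noise_sd = 0,
                           seed = 42) {
  stopifnot(leaflet_vf >= 0, leaflet_vf <= 1,
            soma_peak > background, background >= 0,
            pixel_size_um > 0, bg_circle_diameter_um >= 10)
  structure(list(frame_size_um = frame_size_um, pixel_size_um = pixel_size_um,
                 soma_center = soma_center, soma_radius_um = soma_radius_um,
                 soma_peak = soma_peak, background = background,
                 leaflet_vf = leaflet_vf, n_branches = n_branches,
                 branch_length_um = branch_length_um,
                 branch_width_um = branch_width_um, branch_peak = branch_peak,
                 bg_circle_center = bg_circle_center,
                 bg_circle_diameter_um = bg_circle_diameter_um,
                 n_planes = n_planes, noise_sd = noise_sd, seed = seed),
            class = "imaging_params")
}

# Pixel-center coordinate grids in micrometers for an (nx, ny) frame.
pixel_grid_um <- function(nx, ny, px) {
  list(x = (seq_len(nx) - 0.5) * px, y = (seq_len(ny) - 0.5) * px)
}

# Distance from each point of a grid to a segment from `a` of direction
# `theta` and length `len` (all in micrometers).
dist_to_ray <- function(gx, gy, a, theta, len) {
  dx <- outer(gx - a[1], rep(1, length(gy)))
  dy <- outer(rep(1, length(gx)), gy - a[2])
  ux <- cos(theta); uy <- sin(theta)
  tproj <- dx * ux + dy * uy
  tclamp <- pmin(pmax(tproj, 0), len)
  sqrt((dx - tclamp * ux)^2 + (dy - tclamp * uy)^2)
}

#' Generate a synthetic dye-filled astrocyte image
#'
#' Renders soma, branches, leaflet field, a dye-free background circle, and
#' additive Gaussian noise. Ground truth (volume fraction, soma geometry,
#' branch raster, background-circle location) travels with the image.
#'
#' @param params an [imaging_params()] object.
#' @return a `labeled_image`: list with `planes` (list of matrices indexed
#'   `[x, y]`), `pixel_size_um`, and `ground_truth`.
#' @export
gen_astrocyte_image <- function(params) {
  stopifnot(inherits(params, "imaging_params"))
  p <- params
  px <- p$pixel_size_um
  nx <- round(p$frame_size_um[1] / px); ny <- round(p$frame_size_um[2] / px)
  # Frame must hold the soma plus the 30 um analysis annulus.
  need <- p$soma_radius_um + 30
  edge_clearance <- min(p$soma_center, p$frame_size_um - p$soma_center)
  if (edge_clearance < need)
    stop("frame too small to contain the soma plus a 30 um annulus")
  g <- pixel_grid_um(nx, ny, px)
  dxs <- outer(g$x - p$soma_center[1], rep(1, ny))
  dys <- outer(rep(1, nx), g$y - p$soma_center[2])
  r_soma <- sqrt(dxs^2 + dys^2)

  amp <- p$soma_peak - p$background
  base <- matrix(p$background + p$leaflet_vf * amp, nx, ny)

  # Dye-free circle: pure background.
  rbg <- sqrt(outer(g$x - p$bg_circle_center[1], rep(1, ny))^2 +
                outer(rep(1, nx), g$y - p$bg_circle_center[2])^2)
  in_bg <- rbg <= p$bg_circle_diameter_um / 2
  base[in_bg] <- p$background

  # Branches: straight filaments from the soma edge, deterministic golden-angle
  # spread with a small seeded jitter so they never align with profile lines.
  branch_angles <- with_seed(p$seed, {
    jitter <- stats::runif(p$n_branches, -4, 4) * pi / 180
    (seq_len(p$n_branches) - 1) * 2 * pi / max(1, p$n_branches) +
      7 * pi / 180 + jitter
  })
  branch_mask <- matrix(FALSE, nx, ny)
  for (th in branch_angles) {
    d <- dist_to_ray(g$x, g$y, p$soma_center, th, p$branch_length_um)
    branch_mask <- branch_mask | (d <= p$branch_width_um / 2 &
                                    r_soma > p$soma_radius_um * 0.5)
  }
  img0 <- base
  img0[branch_mask] <- pmax(img0[branch_mask], p$branch_peak)

  # Soma: flat plateau with a ~0.5 um soft shoulder.
  soma_prof <- p$background + amp / (1 + exp((r_soma - p$soma_radius_um) / 0.25))
  img0 <- pmax(img0, soma_prof)

  planes <- with_seed(p$seed + 1L, lapply(seq_len(p$n_planes), function(k) {
    if (p$noise_sd > 0) img0 + matrix(stats::rnorm(nx * ny, 0, p$noise_sd), nx, ny)
    else img0
  }))

  gt <- list(vf = p$leaflet_vf, soma_center = p$soma_center,
             soma_radius_um = p$soma_radius_um, f_max = p$soma_peak,
             f_0 = p$background, n_branches = p$n_branches,
             branch_angles = branch_angles,
             branch_length_um = p$branch_length_um,
             branch_mask = branch_mask,
             bg_circle_center = p$bg_circle_center,
             bg_circle_diameter_um = p$bg_circle_diameter_um)
  structure(list(planes = planes, pixel_size_um = px, ground_truth = gt,
                 params = p),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("labeled_image: %d plane(s), %d x %d px at %.3g um/px\n",
              length(x$planes), d[1], d[2], x$pixel_size_um))
  invisible(x)
}
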