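#' Parameters for a synthetic puncta-stained frame
#'
#' Emulates a confocal frame of connexin-like immunofluorescent puncta: discs
#' of a stated diameter placed by a hard-core point process (minimum
#' center-to-center separation enforced by rejection sampling) on a smooth
#' background, rendered with sub-pixel area coverage, an optional Gaussian
#' PSF, and additive noise.
#'
#' The default contrast (`amplitude` about twice the segmentation threshold)
#' puts the threshold near the punctum half-maximum, so measured diameters
#' follow the full-width-at-half-maximum convention and track the drawn
#' diameter. For bright sub-micron puncta use [puncta_preset()].
#'
#' @param density_per_um2 expected cluster count per square micrometer.
#' @param diameter_um disc diameter (um); must be at least 2 pixels.
#' @param amplitude peak disc intensity above background (arb. units).
#' @param background_base flat background level.
#' @param background_ramp peak-to-peak amplitude of a smooth linear ramp
#'   added to the background (the "smooth background").
#' @param noise_sd additive Gaussian noise SD.
#' @param frame_size_um frame side lengths (um), length 2.
#' @param pixel_size_um pixel size (um/px).
#' @param min_separation_um hard-core center separation; default twice the
#'   diameter so rendered clusters never merge.
#' @param psf_sigma_um Gaussian PSF sigma (um); 0 disables blurring.
#' @param seed RNG seed.
#' @return a `puncta_params` list.
#' @export
puncta_params <- function(density_per_um2 = 0.02,
                          diameter_um = 1.4,
                          amplitude = 7,
                          background_base = 4,
                          background_ramp = 2,
                          noise_sd = 0.05 * amplitude,
                          frame_size_um = c(50, 50),
                          pixel_size_um = 0.25,
                          min_separation_um = 2 * diameter_um,
                          psf_sigma_um = 0.125,
                          seed = 42) {
  stopifnot(density_per_um2 >= 0, pixel_size_um > 0,
            diameter_um >= 2 * pixel_size_um)
  coverage <- density_per_um2 * pi * diameter_um^2 / 4
  if (coverage >= 0.2)
    stop("expected disc coverage ", signif(coverage, 3),
         " >= 0.2: clusters would not stay separable")
  structure(list(density_per_um2 = density_per_um2, diameter_um = diameter_um,
                 amplitude = amplitude, background_base = background_base,
                 background_ramp = background_ramp, noise_sd = noise_sd,
                 frame_size_um = frame_size_um, pixel_size_um = pixel_size_um,
                 min_separation_um = min_separation_um,
                 psf_sigma_um = psf_sigma_um, seed = seed),
            class = "puncta_params")
}

#' Channel presets for synthetic connexin frames
#'
#' Two documented signal-to-noise presets: `"cx30_proximal"` renders
#' micron-scale puncta at moderate contrast (threshold at half-maximum, i.e.
#' FWHM-calibrated diameters); `"cx43"` renders bright sub-micron puncta at
#' high contrast so every punctum clears the five-pixel minimum cluster size.
#'
#' @param which preset name.
#' @param ... overrides passed to [puncta_params()].
#' @return a `puncta_params` object.
#' @export
puncta_preset <- function(which = c("cx30_proximal", "cx43"), ...) {
  which <- match.arg(which)
  defaults <- switch(which,
    cx30_proximal = list(density_per_um2 = 0.02, diameter_um = 1.4,
                         amplitude = 7, noise_sd = 0.35,
                         psf_sigma_um = 0.125),
    cx43 = list(density_per_um2 = 0.24, diameter_um = 0.5,
                amplitude = 400, noise_sd = 8, psf_sigma_um = 0.175,
                min_separation_um = 1.25))
  args <- utils::modifyList(defaults, list(...))
  do.call(puncta_params, args)
}

# Hard-core (sequential rejection) placement of n points with minimum
# separation `sep` in a rectangle, uniform marginal density.
hardcore_place <- function(n, size, sep, max_tries = 2000L) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::runif(1, 0, size[1]); y <- stats::runif(1, 0, size[2])
      if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= sep^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("infeasible density/separation combination: could not place point ",
           i, " of ", n, " with min separation ", sep, " um")
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic puncta frame
#'
#' @param params a [puncta_params()] object.
#' @return a `labeled_image` with one plane; `ground_truth` carries the true
#'   centers (um) and the drawn diameter.
#' @export
gen_puncta_frame <- function(params) {
  stopifnot(inherits(params, "puncta_params"))
  p <- params
  px <- p$pixel_size_um
  nx <- round(p$frame_size_um[1] / px); ny <- round(p$frame_size_um[2] / px)
  n <- round(p$density_per_um2 * prod(p$frame_size_um))

  img <- with_seed(p$seed, {
    g <- pixel_grid_um(nx, ny, px)
    theta <- stats::runif(1, 0, 2 * pi)
    ramp <- outer(g$x * cos(theta), rep(1, ny)) +
      outer(rep(1, nx), g$y * sin(theta))
    ramp <- ramp - min(ramp)
    if (max(ramp) > 0) ramp <- ramp / max(ramp)
    img <- matrix(p$background_base, nx, ny) + p$background_ramp * ramp

    centers <- if (n > 0) hardcore_place(n, p$frame_size_um,
                                         p$min_separation_um)
    else cbind(x = numeric(0), y = numeric(0))

    # Render discs with 4x4 sub-pixel area coverage.
    r_um <- p$diameter_um / 2
    r_px <- r_um / px
    s <- 4L
    off <- (seq_len(s) - 0.5) / s - 0.5
    sub <- expand.grid(dx = off, dy = off)
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, 1] / px + 0.5; cy <- centers[i, 2] / px + 0.5
      i0 <- max(1L, floor(cx - r_px - 1)); i1 <- min(nx, ceiling(cx + r_px + 1))
      j0 <- max(1L, floor(cy - r_px - 1)); j1 <- min(ny, ceiling(cy + r_px + 1))
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      cov <- matrix(0, length(ii), length(jj))
      for (k in seq_len(nrow(sub))) {
        dxk <- outer(ii + sub$dx[k] - cx, rep(1, length(jj)))
        dyk <- outer(rep(1, length(ii)), jj + sub$dy[k] - cy)
        cov <- cov + (dxk^2 + dyk^2 <= r_px^2)
      }
      img[ii, jj] <- img[ii, jj] + p$amplitude * cov / nrow(sub)
    }
    if (p$psf_sigma_um > 0) img <- gaussian_blur(img, p$psf_sigma_um / px)
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nx * ny, 0, p$noise_sd), nx, ny)
    attr(img, "centers") <- centers
    img
  })
  centers <- attr(img, "centers"); attr(img, "centers") <- NULL
  gt <- list(centers_um = centers, diameter_um = p$diameter_um,
             n_true = nrow(centers))
  structure(list(planes = list(img), pixel_size_um = px, ground_truth = gt,
                 params = p),
            class = "labeled_image")
}
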