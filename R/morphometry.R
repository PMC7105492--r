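#' Coherence-enhancing diffusion filtering
#'
#' Structure-tensor anisotropic diffusion that smooths along coherent
#' (filamentous) structures while preserving them across their width, the
#' standard preprocessing for enhancing thin branches before binarization.
#' Explicit finite-difference scheme; the image is normalized to `[0, 1]`
#' internally and rescaled back.
#'
#' @param img numeric matrix.
#' @param n_iter number of diffusion iterations.
#' @param dt time step (stable below 0.25).
#' @param sigma gradient pre-smoothing sigma (px).
#' @param rho structure-tensor integration sigma (px).
#' @param alpha baseline (cross-structure) diffusivity in `(0, 1)`.
#' @param coh_scale coherence scale: diffusivity along structures saturates
#'   once the squared eigenvalue difference exceeds this value (on the
#'   normalized intensity scale).
#' @return filtered matrix, same dimensions.
#' @export
ced_filter <- function(img, n_iter = 10, dt = 0.2, sigma = 1, rho = 4,
                       alpha = 0.05, coh_scale = 1e-4) {
  rng <- range(img)
  if (diff(rng) == 0) return(img)
  u <- (img - rng[1]) / diff(rng)
  shift <- function(m, di, dj) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    m[ri, cj, drop = FALSE]
  }
  for (it in seq_len(n_iter)) {
    us <- gaussian_blur(u, sigma)
    ux <- (shift(us, 1, 0) - shift(us, -1, 0)) / 2
    uy <- (shift(us, 0, 1) - shift(us, 0, -1)) / 2
    j11 <- gaussian_blur(ux * ux, rho)
    j12 <- gaussian_blur(ux * uy, rho)
    j22 <- gaussian_blur(uy * uy, rho)
    disc <- sqrt((j11 - j22)^2 + 4 * j12^2)
    # Major eigenvector (across structures): (c, s); minor is orthogonal.
    c1 <- 2 * j12
    s1 <- j22 - j11 + disc
    nrm <- sqrt(c1^2 + s1^2)
    flat <- nrm < 1e-12
    c1 <- ifelse(flat, 1, c1 / pmax(nrm, 1e-12))
    s1 <- ifelse(flat, 0, s1 / pmax(nrm, 1e-12))
    kappa <- disc^2
    lam1 <- alpha                                   # across the structure
    lam2 <- alpha + (1 - alpha) * exp(-coh_scale / pmax(kappa, 1e-30))
    d11 <- lam1 * c1^2 + lam2 * s1^2
    d12 <- (lam1 - lam2) * c1 * s1
    d22 <- lam1 * s1^2 + lam2 * c1^2
    gx <- (shift(u, 1, 0) - shift(u, -1, 0)) / 2
    gy <- (shift(u, 0, 1) - shift(u, 0, -1)) / 2
    fx <- d11 * gx + d12 * gy
    fy <- d12 * gx + d22 * gy
    div <- (shift(fx, 1, 0) - shift(fx, -1, 0)) / 2 +
      (shift(fy, 0, 1) - shift(fy, 0, -1)) / 2
    u <- u + dt * div
  }
  u * diff(rng) + rng[1]
}

#' Build a binary branch mask from a z-stack
#'
#' Planes are resampled to the target lateral resolution (0.25 um/px by
#' default), coherence-enhancing diffusion filtered, collapsed by maximal
#' intensity projection, and binarized by local-mean adaptive thresholding.
#'
#' @param stack a `labeled_image` or a list of matrices.
#' @param pixel_size_um pixel size of the input planes (taken from the
#'   `labeled_image` when available).
#' @param target_px_um target resolution after resampling.
#' @param ced list of arguments to [ced_filter()], or `NULL` to skip.
#' @param window_px adaptive-threshold local-mean window (px).
#' @param offset threshold offset above the local mean, in intensity units;
#'   `"auto"` (default) uses 3 x MAD of the image minus its local mean,
#'   which keeps pure-noise regions out of the mask. `0` reproduces plain
#'   local-mean thresholding.
#' @return a `binary_mask`: logical matrix with attributes `pixel_size_um`
#'   and `provenance`.
#' @export
preprocess_mask <- function(stack, pixel_size_um = NULL, target_px_um = 0.25,
                            ced = list(), window_px = 51, offset = "auto") {
  if (inherits(stack, "labeled_image")) {
    pixel_size_um <- stack$pixel_size_um
    planes <- stack$planes
  } else planes <- stack
  if (!length(planes)) stop("empty stack")
  stopifnot(!is.null(pixel_size_um))
  f <- pixel_size_um / target_px_um
  planes <- lapply(planes, function(pl) {
    if (abs(f - 1) > 1e-9)
      pl <- EBImage::resize(pl, w = round(nrow(pl) * f),
                            h = round(ncol(pl) * f))
    if (!is.null(ced)) pl <- do.call(ced_filter, c(list(pl), ced))
    pl
  })
  mip <- Reduce(pmax, planes)
  lm <- local_mean(mip, window_px)
  resid <- mip - lm
  # Auto offset: 3 x MAD of the residual (keeps noise out of the mask),
  # floored at 1% of the dynamic range (keeps numerically flat regions out
  # when there is no noise to estimate from).
  off <- if (identical(offset, "auto"))
    max(3 * stats::mad(resid), 0.01 * diff(range(mip)))
  else offset
  mask <- resid > off
  structure(mask, pixel_size_um = target_px_um,
            provenance = list(window_px = window_px, offset = off,
                              ced = if (is.null(ced)) NULL else
                                utils::modifyList(formals(ced_filter)[-1], ced),
                              n_planes = length(planes)),
            class = c("binary_mask", class(mask)))
}

# Pixels of the one-pixel-wide rasterized circle of radius r_px around
# center (px coords), ordered by angle. Returns NULL if the circle leaves
# the frame.
circle_ring_pixels <- function(dim_xy, center_px, r_px) {
  cx <- center_px[1]; cy <- center_px[2]
  if (cx - r_px < 0.5 || cx + r_px > dim_xy[1] + 0.5 ||
      cy - r_px < 0.5 || cy + r_px > dim_xy[2] + 0.5) return(NULL)
  i0 <- max(1L, floor(cx - r_px - 1)); i1 <- min(dim_xy[1], ceiling(cx + r_px + 1))
  j0 <- max(1L, floor(cy - r_px - 1)); j1 <- min(dim_xy[2], ceiling(cy + r_px + 1))
  ii <- i0:i1; jj <- j0:j1
  dx <- outer(ii - cx, rep(1, length(jj)))
  dy <- outer(rep(1, length(ii)), jj - cy)
  d <- sqrt(dx^2 + dy^2)
  sel <- which(abs(d - r_px) <= 0.5, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  px <- cbind(i = ii[sel[, 1]], j = jj[sel[, 2]])
  ang <- atan2(px[, 2] - cy, px[, 1] - cx)
  px[order(ang), , drop = FALSE]
}

# Count cyclic runs of TRUE in a logical vector (run spanning the ends
# counts once).
cyclic_runs <- function(v) {
  n <- length(v)
  if (!n || !any(v)) return(0L)
  if (all(v)) return(1L)
  starts <- sum(v & !c(v[n], v[-n]))
  as.integer(starts)
}

# Number of mask intersections along an angularly ordered ring: runs of
# foreground pixels (cyclic), with runs that touch through 8-adjacency
# (e.g. across a one-pixel angular gap) merged transitively, so the count
# equals the number of 8-connected foreground components on the ring.
ring_intersections <- function(mask, ring) {
  v <- mask[ring]
  n <- length(v)
  if (!any(v)) return(0L)
  if (all(v)) return(1L)
  run_id <- integer(n)
  id <- 0L
  prev <- FALSE
  for (k in seq_len(n)) {
    if (v[k]) {
      if (!prev) id <- id + 1L
      run_id[k] <- id
    }
    prev <- v[k]
  }
  if (v[1] && v[n]) run_id[run_id == id] <- run_id[1]  # cyclic wrap
  ids <- unique(run_id[run_id > 0L])
  if (length(ids) == 1L) return(1L)
  pos <- ring[v, , drop = FALSE]
  rid <- run_id[v]
  # Union runs whose pixels are 8-adjacent.
  parent <- seq_along(ids)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    pa <- pos[rid == ids[a], , drop = FALSE]
    pb <- pos[rid == ids[b], , drop = FALSE]
    touch <- any(outer(pa[, 1], pb[, 1], function(x, y) abs(x - y) <= 1L) &
                   outer(pa[, 2], pb[, 2], function(x, y) abs(x - y) <= 1L))
    if (touch) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}

#' Sholl profile of a binary mask
#'
#' For each radius, the number of intersections of the mask with the
#' discretized circle perimeter: foreground pixels of the one-pixel-wide
#' circle raster are walked in angular order and counted as connected runs,
#' with periodic closure (a run spanning the walk's start and end counts
#' once). Radii whose circle leaves the frame are reported `NA`, not zero.
#'
#' @param mask a `binary_mask` (or logical matrix plus `pixel_size_um`).
#' @param center_um soma center (x, y) in micrometers.
#' @param radii_um circle radii in micrometers (strictly increasing);
#'   default 1-50 um in 1 um steps.
#' @param pixel_size_um required when `mask` is a bare matrix.
#' @return a `sholl_profile` data frame with `radius_um` and
#'   `intersections`.
#' @export
sholl_profile <- function(mask, center_um, radii_um = seq(1, 50, by = 1),
                          pixel_size_um = attr(mask, "pixel_size_um")) {
  stopifnot(!is.null(pixel_size_um), !is.unsorted(radii_um, strictly = TRUE))
  m <- mask != 0
  cpx <- center_um / pixel_size_um + 0.5
  stopifnot(cpx[1] >= 1, cpx[1] <= nrow(m), cpx[2] >= 1, cpx[2] <= ncol(m))
  counts <- vapply(radii_um, function(r) {
    ring <- circle_ring_pixels(dim(m), cpx, r / pixel_size_um)
    if (is.null(ring)) return(NA_integer_)
    ring_intersections(m, ring)
  }, integer(1))
  structure(data.frame(radius_um = radii_um, intersections = counts),
            center_um = center_um, class = c("sholl_profile", "data.frame"))
}

#' Radial fluorescence profiles from the soma center
#'
#' Samples the plane along `n_lines` radial lines separated by
#' `360 / n_lines` degrees (22.5 degrees for the default eight lines), with
#' bilinear sub-pixel interpolation at a one-pixel radial step.
#'
#' @param plane numeric matrix (the z-plane through the soma middle).
#' @param center_um soma center (x, y) in micrometers.
#' @param pixel_size_um pixel size (um/px).
#' @param n_lines number of lines (default 8).
#' @param angle0_deg orientation of the first line (degrees).
#' @param step_px radial sampling step in pixels.
#' @return list of `intensity_profile` data frames (`distance_um`, `F`,
#'   `excised`), one per line, each carrying its angle as an attribute.
#' @export
radial_profiles <- function(plane, center_um, pixel_size_um, n_lines = 8,
                            angle0_deg = 0, step_px = 1) {
  cpx <- center_um / pixel_size_um + 0.5
  if (cpx[1] < 1 || cpx[1] > nrow(plane) || cpx[2] < 1 || cpx[2] > ncol(plane))
    stop("center outside frame")
  max_r_px <- min(cpx[1] - 1, nrow(plane) - cpx[1],
                  cpx[2] - 1, ncol(plane) - cpx[2])
  r_px <- seq(0, max_r_px, by = step_px)
  lapply(seq_len(n_lines) - 1L, function(k) {
    th <- (angle0_deg + k * 360 / n_lines) * pi / 180
    x <- cpx[1] + r_px * cos(th)
    y <- cpx[2] + r_px * sin(th)
    f <- interp_bilinear(plane, x, y)
    ok <- !is.na(f)
    structure(data.frame(distance_um = r_px[ok] * pixel_size_um, F = f[ok],
                         excised = FALSE),
              angle_deg = angle0_deg + k * 360 / n_lines,
              class = c("intensity_profile", "data.frame"))
  })
}

#' Excise branch crossings from a radial intensity profile
#'
#' Flags contiguous runs where the profile exceeds its local baseline by
#' more than `threshold` of the dynamic range `f_max - f_0` -- the large
#' fluorescence fluctuations produced by optically resolved branches. The
#' baseline is a running median (5 um window); the excursion is detected on
#' a lightly smoothed copy (1 um running mean) so single-sample noise spikes
#' are not excised. Flagged samples carry no fluorescence downstream.
#'
#' @param profile an `intensity_profile` data frame.
#' @param f_max,f_0 soma peak and background fluorescence defining the
#'   dynamic range the threshold refers to.
#' @param threshold excursion threshold as a fraction of `f_max - f_0`.
#' @param baseline_um running-median baseline window (um).
#' @param smooth_um detection smoothing window (um).
#' @return the profile with its `excised` flags set.
#' @export
excise_branches <- function(profile, f_max, f_0, threshold = 0.10,
                            baseline_um = 5, smooth_um = 1) {
  stopifnot(nrow(profile) > 0)
  d <- profile$distance_um
  step <- if (nrow(profile) > 1) stats::median(diff(d)) else 1
  base <- running_median(profile$F, round(baseline_um / step))
  det <- running_mean(profile$F, round(smooth_um / step))
  profile$excised <- (det - base) > threshold * (f_max - f_0)
  profile
}

#' Background fluorescence from a dye-free circle
#'
#' Mean intensity over the darkest feasible circle of the stated diameter
#' (automatic placement over all fully-contained positions), or over a
#' user-supplied circle. An exclusion mask (e.g. the astrocytic arbor)
#' restricts feasible placements to circles wholly outside it.
#'
#' @param plane numeric matrix.
#' @param pixel_size_um pixel size (um/px).
#' @param diameter_um circle diameter (um), default 10.
#' @param exclusion_mask optional logical matrix of excluded pixels.
#' @param circle_center_um optional fixed circle center (um); skips the
#'   search.
#' @return list with `f0` (mean intensity) and `center_um`.
#' @export
estimate_background <- function(plane, pixel_size_um, diameter_um = 10,
                                exclusion_mask = NULL,
                                circle_center_um = NULL) {
  r_px <- diameter_um / 2 / pixel_size_um
  means <- disc_mean(plane, r_px)
  nx <- nrow(plane); ny <- ncol(plane)
  ix <- seq_len(nx); iy <- seq_len(ny)
  feasible <- outer(ix - 0.5 >= r_px & ix - 0.5 <= nx - r_px,
                    iy - 0.5 >= r_px & iy - 0.5 <= ny - r_px, "&")
  if (!is.null(exclusion_mask)) {
    overlap <- disc_mean(exclusion_mask * 1, r_px)
    feasible <- feasible & (overlap < 1e-9)
  }
  if (!is.null(circle_center_um)) {
    cpx <- round(circle_center_um / pixel_size_um + 0.5)
    stopifnot(cpx[1] >= 1, cpx[1] <= nx, cpx[2] >= 1, cpx[2] <= ny)
    return(list(f0 = means[cpx[1], cpx[2]],
                center_um = (cpx - 0.5) * pixel_size_um))
  }
  if (!any(feasible)) stop("no feasible background circle")
  means[!feasible] <- Inf
  best <- arrayInd(which.min(means), dim(means))
  list(f0 = means[best], center_um = (c(best) - 0.5) * pixel_size_um)
}

#' Leaflet volume fraction from radial profiles
#'
#' Averages the non-excised fluorescence across the radial lines onto a
#' common distance grid, applies the volume-fraction relation
#' `VF(i) = (F(i) - F0) / (Fmax - F0)`, and reports the mean over the
#' 8-30 um segment (soma and domain-boundary regions excluded). `f_max`
#' defaults to the peak of the mean profile in the soma, which is less
#' noise-biased than the per-line maximum. Noise-driven excursions outside
#' `[0, 1]` are reported as-is, not clamped.
#'
#' @param profiles list of (excised) `intensity_profile` data frames.
#' @param f_0 background fluorescence.
#' @param f_max soma peak fluorescence; default max of the mean profile.
#' @param range_um analysis segment, default `c(8, 30)`.
#' @return a `vf_result`: list with `mean_vf`, `curve` (data frame
#'   `distance_um`, `vf`, `n_lines`), `f_max`, `f_0`, `range_um`.
#' @export
estimate_vf <- function(profiles, f_0, f_max = NULL, range_um = c(8, 30)) {
  stopifnot(length(profiles) >= 1)
  grid <- profiles[[which.max(vapply(profiles, nrow, 1L))]]$distance_um
  fmat <- vapply(profiles, function(pr) {
    f <- rep(NA_real_, length(grid))
    idx <- match(round(pr$distance_um, 6), round(grid, 6))
    keep <- !pr$excised & !is.na(idx)
    f[idx[keep]] <- pr$F[keep]
    f
  }, numeric(length(grid)))
  nline <- rowSums(!is.na(fmat))
  fmean <- rowMeans(fmat, na.rm = TRUE)
  fmean[nline == 0] <- NA_real_
  if (is.null(f_max)) f_max <- max(fmean, na.rm = TRUE)
  if (f_max <= f_0) stop("f_max must exceed f_0")
  vf <- (fmean - f_0) / (f_max - f_0)
  seg <- grid >= range_um[1] & grid <= range_um[2] & !is.na(vf)
  if (!any(seg)) stop("no usable samples in the analysis segment")
  structure(list(mean_vf = mean(vf[seg]),
                 curve = data.frame(distance_um = grid, vf = vf,
                                    n_lines = nline),
                 f_max = f_max, f_0 = f_0, range_um = range_um),
            class = "vf_result")
}

#' @export
print.vf_result <- function(x, ...) {
  cat(sprintf("vf_result: mean VF %.4f over %g-%g um (F_max %.3g, F_0 %.3g)\n",
              x$mean_vf, x$range_um[1], x$range_um[2], x$f_max, x$f_0))
  invisible(x)
}
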