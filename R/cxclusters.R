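#' Segment connexin-like puncta in a single plane
#'
#' The punctum-bearing detail (high-pass) image is the plane minus its
#' Gaussian blur (`sigma` = 25 px). Foreground pixels are detail pixels
#' exceeding one standard deviation above the 99th percentile of the
#' smoothed picture, with both statistics measured above the smoothed
#' picture's dark level (its minimum); 8-connected components of at least
#' `min_px` pixels are retained. Referencing the smoothed statistics to
#' their own dark level makes the segmentation exactly invariant to a
#' constant intensity offset while keeping the threshold sensitive to the
#' scene's overall brightness, as a threshold quoted from the smoothed
#' picture must be. The standard deviation defaults to that of the
#' smoothed image (`sd_ref = "smooth"`); `"highpass"` selects the SD of
#' the detail image instead.
#'
#' @param plane numeric matrix (one z-plane) or a one-plane `labeled_image`.
#' @param pixel_size_um pixel size (um/px).
#' @param sigma_px Gaussian blur sigma, in pixels.
#' @param min_px minimum cluster size in connected pixels.
#' @param sd_ref which image the "one standard deviation" refers to.
#' @param intensity_weighted use intensity-weighted centroids.
#' @return a `cluster_set`: list with `clusters` (data frame `id`, `x_um`,
#'   `y_um`, `n_px`, `diameter_um`), `pixels` (list of n x 2 pixel-index
#'   matrices), `pixel_size_um`, `threshold`.
#' @export
segment_clusters <- function(plane, pixel_size_um = NULL, sigma_px = 25,
                             min_px = 5, sd_ref = c("smooth", "highpass"),
                             intensity_weighted = FALSE) {
  sd_ref <- match.arg(sd_ref)
  if (inherits(plane, "labeled_image")) {
    pixel_size_um <- plane$pixel_size_um
    plane <- plane$planes[[1]]
  }
  stopifnot(!is.null(pixel_size_um))
  empty <- function(thr) structure(
    list(clusters = data.frame(id = integer(0), x_um = numeric(0),
                               y_um = numeric(0), n_px = integer(0),
                               diameter_um = numeric(0)),
         pixels = list(), pixel_size_um = pixel_size_um, threshold = thr),
    class = "cluster_set")
  if (diff(range(plane)) == 0) return(empty(NA_real_))
  smooth <- gaussian_blur(plane, sigma_px)
  hp <- plane - smooth
  thr <- stats::quantile(smooth, 0.99, names = FALSE) - min(smooth) +
    if (sd_ref == "smooth") stats::sd(smooth) else stats::sd(hp)
  fg <- hp > thr
  lab <- label8(fg)
  if (!any(lab > 0)) return(empty(thr))
  tab <- tabulate(lab)
  keep <- which(tab >= min_px)
  if (!length(keep)) return(empty(thr))
  px <- pixel_size_um
  pixels <- lapply(keep, function(k) arrayInd(which(lab == k), dim(lab)))
  rows <- lapply(seq_along(keep), function(i) {
    pp <- pixels[[i]]
    xy <- (pp - 0.5) * px
    if (intensity_weighted) {
      w <- hp[pp]; w <- pmax(w, 0); w <- w / sum(w)
      ctr <- c(sum(xy[, 1] * w), sum(xy[, 2] * w))
    } else ctr <- colMeans(xy)
    data.frame(id = i, x_um = ctr[1], y_um = ctr[2], n_px = nrow(pp),
               diameter_um = cluster_diameter(pp, px))
  })
  structure(list(clusters = do.call(rbind, rows), pixels = pixels,
                 pixel_size_um = pixel_size_um, threshold = thr),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) at %.3g um/px\n",
              nrow(x$clusters), x$pixel_size_um))
  invisible(x)
}

#' Cluster diameter (maximum caliper)
#'
#' Longest distance between two pixel centers of the same cluster, times the
#' pixel size -- equivalently the diameter of the smallest enclosing circle
#' through the two farthest points. Computed on the convex hull, so it
#' matches the brute-force all-pairs maximum.
#'
#' @param pixels n x 2 matrix of integer pixel indices.
#' @param pixel_size_um pixel size (um/px).
#' @return diameter in micrometers (0 for a single pixel).
#' @export
cluster_diameter <- function(pixels, pixel_size_um = 1) {
  n <- nrow(pixels)
  if (n < 2) return(0)
  h <- grDevices::chull(pixels[, 1], pixels[, 2])
  hp <- pixels[h, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  sqrt(max(d2)) * pixel_size_um
}

#' Delaunay triangulation of cluster centers
#'
#' Inter-cluster spacing quantified as the edge lengths of the Delaunay
#' triangulation of the centers. Two centers give the single connecting
#' edge; collinear centers degrade to consecutive path edges.
#'
#' @param centers n x 2 matrix or data frame of center coordinates (um).
#' @param drop_boundary drop convex-hull boundary edges (default FALSE;
#'   published cluster meshworks include them).
#' @return a `cluster_graph`: list with `edges` (data frame `from`, `to`,
#'   `length_um`) and `mean_edge_um`.
#' @export
delaunay_intercluster <- function(centers, drop_boundary = FALSE) {
  centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  n <- nrow(centers)
  if (n < 2) stop("need at least 2 centers")
  mk <- function(from, to) {
    len <- sqrt((centers[from, 1] - centers[to, 1])^2 +
                  (centers[from, 2] - centers[to, 2])^2)
    structure(list(edges = data.frame(from = from, to = to, length_um = len),
                   mean_edge_um = mean(len)),
              class = "cluster_graph")
  }
  if (n == 2) return(mk(1L, 2L))
  # Collinear centers: deldir cannot triangulate; fall back to path edges
  # along the common line.
  cc <- sweep(centers, 2, colMeans(centers))
  sv <- svd(cc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    ord <- order(cc %*% sv$v[, 1])
    return(mk(ord[-n], ord[-1]))
  }
  dd <- deldir::deldir(centers[, 1], centers[, 2], suppressMsge = TRUE)
  seg <- dd$delsgs
  if (drop_boundary) {
    hull <- grDevices::chull(centers)
    on_hull <- seg$ind1 %in% hull & seg$ind2 %in% hull
    # Keep hull-vertex pairs that are not consecutive hull edges.
    hull_edges <- cbind(hull, c(hull[-1], hull[1]))
    is_hull_edge <- mapply(function(a, b)
      any((hull_edges[, 1] == a & hull_edges[, 2] == b) |
            (hull_edges[, 1] == b & hull_edges[, 2] == a)),
      seg$ind1, seg$ind2)
    seg <- seg[!(on_hull & is_hull_edge), , drop = FALSE]
  }
  mk(seg$ind1, seg$ind2)
}

# Areas of half-open annular rings [r, r + dr) clipped to the frame
# rectangle [0, W] x [0, H], by fine-grid quadrature (cell = dr / 10).
ring_areas_in_frame <- function(soma_um, inner_radii, dr, frame_um) {
  step <- dr / 10
  gx <- seq(step / 2, frame_um[1] - step / 2, by = step)
  gy <- seq(step / 2, frame_um[2] - step / 2, by = step)
  d <- sqrt(outer((gx - soma_um[1])^2, rep(1, length(gy))) +
              outer(rep(1, length(gx)), (gy - soma_um[2])^2))
  edges <- c(inner_radii, inner_radii[length(inner_radii)] + dr)
  dd <- d[d >= edges[1] & d < edges[length(edges)]]
  counts <- tabulate(findInterval(dd, edges), nbins = length(inner_radii))
  counts * step^2
}

#' Radial cluster density and size profile around a soma
#'
#' Concentric rings of width `dr_um` from `r_from_um` to `r_to_um`; per ring,
#' the cluster count divided by the ring area (clipped to the frame, so
#' densities stay unbiased near the frame border) and the mean cluster
#' diameter. Summaries report the soma-proximal mean (r < 10 um) and the
#' mean over all rings.
#'
#' @param clusters a `cluster_set`, or a data frame with `x_um`, `y_um`,
#'   `diameter_um`.
#' @param soma_um soma centroid (x, y) in micrometers.
#' @param frame_um frame size (um); needed to clip ring areas.
#' @param r_from_um,r_to_um,dr_um ring geometry, default 2.5-50 um in 0.5 um
#'   steps.
#' @return a `radial_cluster_profile`: data frame (`r_inner_um`,
#'   `area_um2`, `count`, `density_per_um2`, `mean_diameter_um`) with
#'   summary attributes `proximal_mean_density`, `proximal_mean_diameter`
#'   (r < 10 um), `overall_mean_density`, `overall_mean_diameter`.
#' @export
radial_cluster_profile <- function(clusters, soma_um, frame_um,
                                   r_from_um = 2.5, r_to_um = 50,
                                   dr_um = 0.5) {
  df <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  inner <- seq(r_from_um, r_to_um - dr_um, by = dr_um)
  areas <- ring_areas_in_frame(soma_um, inner, dr_um, frame_um)
  d <- sqrt((df$x_um - soma_um[1])^2 + (df$y_um - soma_um[2])^2)
  ring_idx <- findInterval(d, c(inner, r_to_um), rightmost.closed = FALSE)
  inside <- d >= r_from_um & d < r_to_um
  counts <- tabulate(ring_idx[inside], nbins = length(inner))
  mean_diam <- vapply(seq_along(inner), function(k) {
    sel <- inside & ring_idx == k
    if (any(sel)) mean(df$diameter_um[sel]) else NA_real_
  }, numeric(1))
  dens <- ifelse(areas > 0, counts / areas, NA_real_)
  out <- data.frame(r_inner_um = inner, area_um2 = areas, count = counts,
                    density_per_um2 = dens, mean_diameter_um = mean_diam)
  prox <- out$r_inner_um + dr_um <= 10
  valid <- !is.na(out$density_per_um2)
  structure(out,
            soma_um = soma_um,
            proximal_mean_density = mean(out$density_per_um2[prox & valid]),
            proximal_mean_diameter =
              mean(out$mean_diameter_um[prox], na.rm = TRUE),
            overall_mean_density = mean(out$density_per_um2[valid]),
            overall_mean_diameter = mean(out$mean_diameter_um, na.rm = TRUE),
            class = c("radial_cluster_profile", "data.frame"))
}
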