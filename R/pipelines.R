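#' Leaflet volume fraction from a dye-filled astrocyte image
#'
#' Full radial-profile pipeline: eight radial lines from the soma center,
#' automatic dye-free-circle background, branch excision, and the
#' volume-fraction relation averaged over 8-30 um.
#'
#' @param limg a `labeled_image` (one plane used) or a numeric matrix.
#' @param center_um soma center; defaults to the image's ground-truth
#'   annotation.
#' @param pixel_size_um pixel size when `limg` is a bare matrix.
#' @param range_um analysis segment.
#' @param excise_threshold branch-excision threshold (fraction of dynamic
#'   range).
#' @return a `vf_result` (see [estimate_vf()]).
#' @export
vf_from_image <- function(limg, center_um = NULL, pixel_size_um = NULL,
                          range_um = c(8, 30), excise_threshold = 0.10) {
  if (inherits(limg, "labeled_image")) {
    plane <- limg$planes[[1]]
    pixel_size_um <- limg$pixel_size_um
    if (is.null(center_um)) center_um <- limg$ground_truth$soma_center
  } else plane <- limg
  stopifnot(!is.null(center_um), !is.null(pixel_size_um))
  profs <- radial_profiles(plane, center_um, pixel_size_um)
  f0 <- estimate_background(plane, pixel_size_um)$f0
  # Provisional soma peak from the raw mean profile (branches stay below the
  # soma plateau, so the maximum sits in the soma).
  grid <- profs[[which.max(vapply(profs, nrow, 1L))]]$distance_um
  fmat <- vapply(profs, function(pr) {
    f <- rep(NA_real_, length(grid))
    f[match(round(pr$distance_um, 6), round(grid, 6))] <- pr$F
    f
  }, numeric(length(grid)))
  f_max <- max(rowMeans(fmat, na.rm = TRUE), na.rm = TRUE)
  profs <- lapply(profs, excise_branches, f_max = f_max, f_0 = f0,
                  threshold = excise_threshold)
  estimate_vf(profs, f_0 = f0, f_max = f_max, range_um = range_um)
}

#' Sholl profile from a dye-filled astrocyte image
#'
#' Mask construction ([preprocess_mask()]) followed by circle-intersection
#' counting from the soma center.
#'
#' @param limg a `labeled_image`.
#' @param radii_um circle radii (um).
#' @param ... passed to [preprocess_mask()].
#' @return a `sholl_profile` data frame.
#' @export
sholl_from_image <- function(limg, radii_um = seq(5, 38, by = 1), ...) {
  stopifnot(inherits(limg, "labeled_image"))
  mask <- preprocess_mask(limg, ...)
  sholl_profile(mask, limg$ground_truth$soma_center, radii_um)
}
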