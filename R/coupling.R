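#' 3D distances from the patched soma
#'
#' Plain Euclidean (Pythagorean) distance in micrometers; z must already be
#' scaled by the z-step.
#'
#' @param records data frame with `x`, `y`, `z` columns (um).
#' @param reference reference point, default the patched cell's position (or
#'   the origin).
#' @return numeric vector of distances (um).
#' @export
distances_3d <- function(records, reference = NULL) {
  if (is.null(reference)) {
    reference <- if (!is.null(records$is_patched) && any(records$is_patched))
      unlist(records[which(records$is_patched)[1], c("x", "y", "z")])
    else c(0, 0, 0)
  }
  sqrt((records$x - reference[1])^2 + (records$y - reference[2])^2 +
         (records$z - reference[3])^2)
}

#' Fit the gap-junction coupling length constant
#'
#' Least-squares line through `ln F` versus distance. The decay law
#' `F(d) = exp(-d / C_lambda)` has a unit prefactor, so the intercept is
#' fixed at zero by default (`C_lambda = -1 / slope`); a free-intercept
#' variant is available since published coupling plots show a generic linear
#' fit in semilog scale. Cells with non-positive fluorescence are excluded
#' with a warning; the patched cell (d = 0, F = 1) is retained and
#' contributes nothing under the fixed intercept.
#'
#' @param records `coupled_network` or data frame with `x`, `y`, `z`,
#'   `fluorescence` (normalized) and optionally `is_patched`.
#' @param fix_intercept fix the log-space intercept at 0 (default TRUE).
#' @return a `coupling_fit`: list with `length_constant_um`, `slope`,
#'   `intercept`, `r_squared`, `residuals`, `n_cells`.
#' @export
fit_length_constant <- function(records, fix_intercept = TRUE) {
  d <- distances_3d(records)
  f <- records$fluorescence
  bad <- f <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive fluorescence excluded")
    d <- d[!bad]; f <- f[!bad]
  }
  if (sum(d > 0) < 2) stop("need at least 2 usable cells with d > 0")
  lf <- log(f)
  if (fix_intercept) {
    slope <- sum(d * lf) / sum(d * d)
    intercept <- 0
  } else {
    co <- stats::coef(stats::lm(lf ~ d))
    intercept <- co[[1]]; slope <- co[[2]]
  }
  if (slope >= 0) stop("non-decaying fluorescence: slope >= 0")
  fitted <- intercept + slope * d
  resid <- lf - fitted
  ss_tot <- sum((lf - mean(lf))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(list(length_constant_um = -1 / slope, slope = slope,
                 intercept = intercept, r_squared = r2, residuals = resid,
                 n_cells = length(d), fix_intercept = fix_intercept),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("coupling_fit: C_lambda = %.2f um (n = %d, R^2 = %.3f)\n",
              x$length_constant_um, x$n_cells, x$r_squared))
  invisible(x)
}

#' Count dye-coupled cells
#'
#' Number of non-patched cells whose normalized somatic fluorescence exceeds
#' a detection threshold (coupling studies report counts without one; the
#' default corresponds to twice a 1% background-equivalent noise floor).
#'
#' @param network `coupled_network` or compatible data frame.
#' @param detection_threshold minimum normalized fluorescence.
#' @return integer count.
#' @export
count_coupled <- function(network, detection_threshold = 0.02) {
  patched <- if (!is.null(network$is_patched)) network$is_patched
  else rep(FALSE, nrow(network))
  sum(!patched & network$fluorescence > detection_threshold)
}
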