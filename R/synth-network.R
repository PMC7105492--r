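#' Parameters for a synthetic dye-coupled astrocyte network
#'
#' The patched cell sits at the origin with unit somatic fluorescence; coupled
#' cells are placed uniformly at random in a ball of radius `max_distance_um`
#' and carry fluorescence `exp(-d / length_constant_um) * (1 + noise)`, the
#' exponential decay with 3D distance that defines the coupling length
#' constant.
#'
#' @param n_cells total number of cells including the patched one (>= 1).
#' @param length_constant_um ground-truth coupling length constant (um).
#' @param max_distance_um maximum 3D distance of coupled cells from the
#'   patched soma (um).
#' @param min_distance_um minimum distance of coupled somata from the patched
#'   one (somata do not overlap).
#' @param noise_sd multiplicative fluorescence noise SD (fraction).
#' @param seed RNG seed.
#' @return a `coupling_params` list.
#' @export
coupling_params <- function(n_cells = 13,
                            length_constant_um = 19.9,
                            max_distance_um = 80,
                            min_distance_um = 10,
                            noise_sd = 0,
                            seed = 42) {
  stopifnot(n_cells >= 1, length_constant_um > 0,
            max_distance_um > min_distance_um)
  structure(list(n_cells = n_cells, length_constant_um = length_constant_um,
                 max_distance_um = max_distance_um,
                 min_distance_um = min_distance_um,
                 noise_sd = noise_sd, seed = seed),
            class = "coupling_params")
}

#' Generate a synthetic dye-coupled network
#'
#' @param params a [coupling_params()] object.
#' @return a `coupled_network`: data frame with columns `cell_id`, `x`, `y`,
#'   `z` (um), `fluorescence` (normalized to the patched soma), `is_patched`;
#'   ground truth (length constant, exact distances) in attributes.
#' @export
gen_coupled_network <- function(params) {
  stopifnot(inherits(params, "coupling_params"))
  p <- params
  n <- p$n_cells
  df <- with_seed(p$seed, {
    k <- n - 1L
    # Uniform in a spherical shell [min_distance, max_distance].
    u <- stats::runif(k)
    r <- (p$min_distance_um^3 +
            u * (p$max_distance_um^3 - p$min_distance_um^3))^(1 / 3)
    ct <- stats::runif(k, -1, 1)
    ph <- stats::runif(k, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    x <- r * st * cos(ph); y <- r * st * sin(ph); z <- r * ct
    f <- exp(-r / p$length_constant_um)
    if (p$noise_sd > 0) f <- f * (1 + stats::rnorm(k, 0, p$noise_sd))
    data.frame(cell_id = 0:k,
               x = c(0, x), y = c(0, y), z = c(0, z),
               fluorescence = c(1, f),
               is_patched = c(TRUE, rep(FALSE, k)))
  })
  attr(df, "ground_truth") <- list(
    length_constant_um = p$length_constant_um,
    distances_um = sqrt(df$x^2 + df$y^2 + df$z^2))
  attr(df, "params") <- p
  class(df) <- c("coupled_network", "data.frame")
  df
}
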