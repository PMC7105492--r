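#' Parameters for a synthetic fEPSP amplitude time course
#'
#' Pre-HFS amplitudes fluctuate around 100% of baseline; after the tetanus
#' the mean amplitude approaches `100 * potentiation_factor` with a
#' monoexponential onset. Noise is multiplicative with a stated coefficient
#' of variation, the usual behavior of field-potential amplitudes.
#'
#' @param baseline_minutes stable baseline duration before HFS.
#' @param post_minutes recording duration after HFS.
#' @param sample_interval_s sweep interval (one fEPSP per interval).
#' @param potentiation_factor asymptotic post/pre amplitude ratio (> 0).
#' @param onset_tau_min onset time constant (minutes).
#' @param amplitude_noise_cv coefficient of variation of amplitudes.
#' @param seed RNG seed.
#' @return an `ltp_series_params` list.
#' @export
ltp_series_params <- function(baseline_minutes = 15,
                              post_minutes = 60,
                              sample_interval_s = 20,
                              potentiation_factor = 1.68,
                              onset_tau_min = 5,
                              amplitude_noise_cv = 0,
                              seed = 42) {
  stopifnot(potentiation_factor > 0, baseline_minutes > 0, post_minutes > 0)
  structure(list(baseline_minutes = baseline_minutes,
                 post_minutes = post_minutes,
                 sample_interval_s = sample_interval_s,
                 potentiation_factor = potentiation_factor,
                 onset_tau_min = onset_tau_min,
                 amplitude_noise_cv = amplitude_noise_cv, seed = seed),
            class = "ltp_series_params")
}

#' Generate a synthetic fEPSP amplitude series with an HFS marker
#'
#' @param params an [ltp_series_params()] object.
#' @return data frame with `time_min` (0 = HFS) and `amplitude` (% of the
#'   noiseless baseline); attributes `hfs_time_min` and `ground_truth`.
#' @export
gen_ltp_series <- function(params) {
  stopifnot(inherits(params, "ltp_series_params"))
  p <- params
  dt <- p$sample_interval_s / 60
  time_min <- seq(-p$baseline_minutes, p$post_minutes, by = dt)
  mean_amp <- ifelse(time_min < 0, 100,
                     100 * (1 + (p$potentiation_factor - 1) *
                              (1 - exp(-time_min / p$onset_tau_min))))
  amp <- with_seed(p$seed, {
    if (p$amplitude_noise_cv > 0)
      mean_amp * (1 + stats::rnorm(length(mean_amp), 0, p$amplitude_noise_cv))
    else mean_amp
  })
  out <- data.frame(time_min = time_min, amplitude = amp)
  attr(out, "hfs_time_min") <- 0
  attr(out, "ground_truth") <- list(
    potentiation_factor = p$potentiation_factor,
    late_mean_pct = 100 * p$potentiation_factor)
  out
}
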