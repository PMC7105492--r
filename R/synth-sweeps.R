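#' Parameters for synthetic stimulus-evoked astrocytic sweeps
#'
#' Sweeps are built by strict linear superposition of per-stimulus kernels:
#' a fast glutamate-transporter-like kernel, a slow potassium-like kernel
#' (both only in the no-drug condition), and a small fast residual potassium
#' kernel that survives receptor blockade. Each kernel has the
#' rise-times-decay form `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`,
#' normalized to unit peak and applied with inward-negative sign. Because the
#' superposition is exactly linear, the five-stimulus trace minus the
#' four-stimulus trace equals the fifth-stimulus kernels sample-exactly
#' before noise.
#'
#' @param sampling_rate Hz.
#' @param stim_times stimulus onset times (s), sorted; default 5 x 50 Hz
#'   starting at 0.1 s.
#' @param duration_s sweep duration (s).
#' @param n_sweeps sweeps per condition (averaged downstream).
#' @param glut_kernel c(amplitude_pA, rise_ms, decay_ms) of the transporter
#'   kernel.
#' @param k_kernel same for the slow potassium kernel.
#' @param residual_k_kernel same for the blocker-insensitive potassium
#'   kernel (non-facilitating by design).
#' @param glut_fac,k_fac per-stimulus amplitude multipliers (length =
#'   number of stimuli).
#' @param glut_tau_mult,k_tau_mult per-stimulus decay-tau multipliers.
#' @param holding_pA constant holding current added to every sweep.
#' @param noise_sd additive Gaussian noise SD (pA).
#' @param conditions subset of c("none", "blockers", "tboa") to synthesize.
#' @param baseline_window window (s) preceding the first stimulus used for
#'   baseline subtraction.
#' @param seed RNG seed.
#' @return a `sweep_params` list.
#' @export
sweep_params <- function(sampling_rate = 5000,
                         stim_times = 0.1 + (0:4) * 0.02,
                         duration_s = 1.6,
                         n_sweeps = 10,
                         glut_kernel = c(200, 1, 8),
                         k_kernel = c(100, 20, 300),
                         residual_k_kernel = c(30, 5, 80),
                         glut_fac = rep(1, length(stim_times)),
                         k_fac = rep(1, length(stim_times)),
                         glut_tau_mult = rep(1, length(stim_times)),
                         k_tau_mult = rep(1, length(stim_times)),
                         holding_pA = -20,
                         noise_sd = 0,
                         conditions = c("none", "blockers", "tboa"),
                         baseline_window = c(0, 0.09),
                         seed = 42) {
  stopifnot(!is.unsorted(stim_times), sampling_rate > 0,
            length(glut_fac) == length(stim_times),
            length(k_fac) == length(stim_times))
  structure(list(sampling_rate = sampling_rate, stim_times = stim_times,
                 duration_s = duration_s, n_sweeps = n_sweeps,
                 glut_kernel = glut_kernel, k_kernel = k_kernel,
                 residual_k_kernel = residual_k_kernel,
                 glut_fac = glut_fac, k_fac = k_fac,
                 glut_tau_mult = glut_tau_mult, k_tau_mult = k_tau_mult,
                 holding_pA = holding_pA, noise_sd = noise_sd,
                 conditions = conditions, baseline_window = baseline_window,
                 seed = seed),
            class = "sweep_params")
}

#' Rise-times-decay kernel normalized to unit peak
#'
#' `w(t) = (1 - exp(-t/tau_r)) * exp(-t/tau_d)` for `t >= 0`, scaled so its
#' maximum is 1.
#'
#' @param t_s time from kernel onset (s); values before onset give 0.
#' @param rise_ms,decay_ms time constants in milliseconds.
#' @return numeric vector of kernel values.
#' @export
biexp_kernel <- function(t_s, rise_ms, decay_ms) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  w <- ifelse(t_s >= 0, (1 - exp(-t_s / tr)) * exp(-t_s / td), 0)
  tpk <- tr * log(1 + td / tr)
  peak <- (1 - exp(-tpk / tr)) * exp(-tpk / td)
  w / peak
}

# Noiseless superposed response (negative-going) for the first `n_stim`
# stimuli of a condition's kernel set.
superpose_kernels <- function(time, p, condition, n_stim) {
  resp <- numeric(length(time))
  kset <- switch(condition,
    none = list(list(k = p$glut_kernel, fac = p$glut_fac, tm = p$glut_tau_mult),
                list(k = p$k_kernel, fac = p$k_fac, tm = p$k_tau_mult)),
    blockers = list(list(k = p$glut_kernel, fac = p$glut_fac,
                         tm = p$glut_tau_mult),
                    list(k = p$residual_k_kernel,
                         fac = rep(1, length(p$stim_times)),
                         tm = rep(1, length(p$stim_times)))),
    tboa = list(list(k = p$residual_k_kernel,
                     fac = rep(1, length(p$stim_times)),
                     tm = rep(1, length(p$stim_times)))),
    stop("unknown condition: ", condition))
  for (s in seq_len(n_stim)) {
    t0 <- p$stim_times[s]
    for (kk in kset) {
      resp <- resp - kk$k[1] * kk$fac[s] *
        biexp_kernel(time - t0, kk$k[2], kk$k[3] * kk$tm[s])
    }
  }
  resp
}

#' Generate stimulus-evoked astrocytic sweep sets
#'
#' For every requested condition and stimulus count (1, 4, 5), builds
#' `n_sweeps` noisy sweeps around the noiseless superposition. Ground truth
#' carries the noiseless traces and the per-stimulus amplitude and decay-tau
#' tables.
#'
#' @param params a [sweep_params()] object.
#' @return a `sweep_set`: list with `time` (s), `sampling_rate`,
#'   `stim_times`, `baseline_window`, `traces` (named list
#'   `<condition>_<n_stim>` of samples-by-sweeps matrices), and
#'   `ground_truth`.
#' @export
gen_astro_sweeps <- function(params) {
  stopifnot(inherits(params, "sweep_params"))
  p <- params
  time <- seq(0, p$duration_s - 1 / p$sampling_rate, by = 1 / p$sampling_rate)
  n_stim_levels <- intersect(c(1L, 4L, 5L), seq_along(p$stim_times))
  noiseless <- list(); traces <- list()
  for (cond in p$conditions) {
    for (ns in n_stim_levels) {
      key <- paste0(cond, "_", ns)
      noiseless[[key]] <- p$holding_pA + superpose_kernels(time, p, cond, ns)
    }
  }
  traces <- with_seed(p$seed, {
    lapply(noiseless, function(v) {
      m <- matrix(v, nrow = length(v), ncol = p$n_sweeps)
      if (p$noise_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, p$noise_sd), nrow(m))
      m
    })
  })
  gt <- list(
    noiseless = noiseless,
    glut = list(amp_pA = p$glut_kernel[1] * p$glut_fac,
                rise_ms = p$glut_kernel[2],
                decay_ms = p$glut_kernel[3] * p$glut_tau_mult),
    k = list(amp_pA = p$k_kernel[1] * p$k_fac,
             rise_ms = p$k_kernel[2],
             decay_ms = p$k_kernel[3] * p$k_tau_mult),
    residual_k = list(amp_pA = rep(p$residual_k_kernel[1],
                                   length(p$stim_times)),
                      rise_ms = p$residual_k_kernel[2],
                      decay_ms = rep(p$residual_k_kernel[3],
                                     length(p$stim_times))))
  structure(list(time = time, sampling_rate = p$sampling_rate,
                 stim_times = p$stim_times,
                 baseline_window = p$baseline_window,
                 traces = traces, ground_truth = gt, params = p),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("sweep_set: %d condition trace(s), %d samples at %g Hz\n",
              length(x$traces), length(x$time), x$sampling_rate))
  invisible(x)
}

#' Generate a passive voltage-step current response
#'
#' Emulates the -5 mV monitoring step of an astrocyte in voltage clamp: an
#' ohmic plateau `dV / R` plus a fast capacitive transient, with additive
#' current noise.
#'
#' @param r_mohm ground-truth input resistance (megaohm).
#' @param dv_mv voltage step (mV), default -5.
#' @param tau_rc_ms capacitive transient time constant (ms).
#' @param cap_scale capacitive peak as a multiple of the plateau current.
#' @param sampling_rate Hz.
#' @param t_step_s step onset (s).
#' @param step_dur_s step duration (s).
#' @param duration_s sweep duration (s).
#' @param holding_pA holding current.
#' @param noise_sd_frac noise SD as a fraction of the plateau amplitude.
#' @param seed RNG seed.
#' @return list with `time`, `current_pA`, `step_window`, `baseline_window`,
#'   `dv_mv`, and `ground_truth$r_mohm`.
#' @export
gen_step_response <- function(r_mohm = 30, dv_mv = -5, tau_rc_ms = 4,
                              cap_scale = 5, sampling_rate = 5000,
                              t_step_s = 0.1, step_dur_s = 0.2,
                              duration_s = 0.4, holding_pA = -15,
                              noise_sd_frac = 0.02, seed = 42) {
  stopifnot(r_mohm > 0)
  time <- seq(0, duration_s - 1 / sampling_rate, by = 1 / sampling_rate)
  di_pA <- dv_mv / r_mohm * 1000      # mV / MOhm = nA -> pA
  on <- time >= t_step_s & time < t_step_s + step_dur_s
  i <- rep(holding_pA, length(time))
  tr <- (time[on] - t_step_s)
  i[on] <- holding_pA + di_pA +
    (cap_scale - 1) * di_pA * exp(-tr / (tau_rc_ms / 1000))
  i <- with_seed(seed, i + stats::rnorm(length(i), 0,
                                        abs(noise_sd_frac * di_pA)))
  list(time = time, current_pA = i,
       step_window = c(t_step_s, t_step_s + step_dur_s),
       baseline_window = c(0, t_step_s - 0.01),
       dv_mv = dv_mv,
       ground_truth = list(r_mohm = r_mohm, di_pA = di_pA))
}
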