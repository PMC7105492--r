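#' Baseline-subtract and average a sweep set
#'
#' Per condition: mean across sweeps minus the mean of the pre-stimulus
#' baseline window.
#'
#' @param sweeps a `sweep_set` (see [gen_astro_sweeps()]).
#' @return the sweep set with each `traces` entry replaced by a single
#'   averaged, baseline-subtracted vector.
#' @export
baseline_subtract_average <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  bw <- sweeps$baseline_window
  sel <- sweeps$time >= bw[1] & sweeps$time <= bw[2]
  if (!any(sel)) stop("baseline window contains no samples")
  sweeps$traces <- lapply(sweeps$traces, function(m) {
    m <- as.matrix(m)
    avg <- rowMeans(m)
    avg - mean(avg[sel])
  })
  sweeps
}

#' Isolate the fifth-stimulus response by subtraction
#'
#' Pointwise difference of the five-stimulus and four-stimulus traces. For
#' linearly superposed responses this recovers the fifth-stimulus component
#' sample-exactly.
#'
#' @param trace5,trace4 aligned numeric vectors.
#' @return numeric vector, same length.
#' @export
isolate_fifth_response <- function(trace5, trace4) {
  if (length(trace5) != length(trace4)) stop("trace length mismatch")
  trace5 - trace4
}

#' Fit a monoexponential decay
#'
#' Nonlinear least squares of `A * exp(-t / tau) + C` with log-linear
#' initialization. Non-convergence and ill-determined time constants are
#' flagged, never silently replaced.
#'
#' @param t time (s), from the start of the decay segment.
#' @param y signal values (any sign; `A` may be negative for inward
#'   currents).
#' @param with_offset fit the additive offset `C` (default TRUE).
#' @return a `monoexp_fit`: list with `amplitude`, `tau_s`, `offset`,
#'   `converged`, `flagged` (TRUE when the fit is unreliable), `rmse`, and
#'   the underlying model.
#' @export
fit_monoexp <- function(t, y, with_offset = TRUE) {
  stopifnot(length(t) == length(y))
  if (length(t) < 10) stop("need at least 10 samples")
  t <- t - t[1]
  c0 <- if (with_offset) mean(utils::tail(y, max(3L, length(y) %/% 10))) else 0
  a0 <- y[1] - c0
  if (abs(a0) < 1e-12) a0 <- if (stats::sd(y) > 0) stats::sd(y) else 1e-6
  z <- (y - c0) / a0
  # Log-linear init on the early, clean part of the decay (before the
  # signal sinks into the tail noise).
  iend <- which(z < 0.05)[1]
  idx <- seq_len(if (is.na(iend)) length(z) else max(10L, iend - 1L))
  ok <- idx[z[idx] > 1e-3]
  tau0 <- if (length(ok) >= 3) {
    sl <- stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[[2]]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  span <- diff(range(t))
  tau0 <- min(max(tau0, span / 1e4), span * 10)
  try_fit <- function(tau_start) tryCatch({
    if (with_offset)
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
                        start = list(A = a0, tau = tau_start, C = c0),
                        lower = c(-Inf, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, ftol = 1e-8, ptol = 1e-8))
    else
      minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                        start = list(A = a0, tau = tau_start),
                        lower = c(-Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, ftol = 1e-8, ptol = 1e-8))
  }, error = function(e) e)
  fit <- NULL
  for (ts in unique(c(tau0, span / 10, span / 100))) {
    fit <- try_fit(ts)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    return(structure(list(amplitude = NA_real_, tau_s = NA_real_,
                          offset = NA_real_, converged = FALSE,
                          flagged = TRUE, rmse = NA_real_, model = NULL,
                          message = conditionMessage(fit)),
                     class = "monoexp_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  tau <- co[["tau"]]
  flagged <- !is.na(se[["tau"]]) && se[["tau"]] > abs(tau)
  structure(list(amplitude = co[["A"]], tau_s = tau,
                 offset = if (with_offset) co[["C"]] else 0,
                 converged = TRUE, flagged = isTRUE(flagged),
                 rmse = sqrt(mean(stats::resid(fit)^2)), model = fit),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("monoexp_fit: A = %.3g, tau = %.4g s, C = %.3g%s\n",
              x$amplitude, x$tau_s, x$offset,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Measure the slow potassium current
#'
#' Amplitude = the extremum of the (inward-negative) trace in the window
#' from 200 ms after the last stimulus to the end of the sweep; when the
#' current is already decaying there (no interior extremum), the value at
#' +200 ms is taken -- at that point the response is no longer contaminated
#' by the fast transporter current or the field-potential transient. The
#' decay from the extremum is fitted monoexponentially.
#'
#' @param trace baseline-subtracted averaged current (pA, inward negative).
#' @param time sample times (s).
#' @param last_stim_time time of the last stimulus (s).
#' @param delay_s analysis delay after the last stimulus (s), default 0.2.
#' @return list with `amplitude_pA` (magnitude), `tau_decay_s`,
#'   `at_fallback` (TRUE when the +200 ms value was used), `peak_time_s`,
#'   and the decay `fit`.
#' @export
measure_IK <- function(trace, time, last_stim_time, delay_s = 0.2) {
  sel <- which(time >= last_stim_time + delay_s - 1e-6)
  if (length(sel) < 10) stop("analysis window outside trace")
  seg <- trace[sel]
  imin <- which.min(seg)
  at_fallback <- imin == 1L
  amp <- abs(seg[imin])
  fit <- fit_monoexp(time[sel[imin:length(sel)]], seg[imin:length(seg)])
  list(amplitude_pA = amp, tau_decay_s = fit$tau_s,
       at_fallback = at_fallback, peak_time_s = time[sel[imin]], fit = fit)
}

#' Reconstruct the transporter-insensitive residual potassium wave
#'
#' The residual current recorded under glutamate-transporter blockade is
#' reconstructed as a smooth wave from two monoexponential fits: a
#' saturating exponential over the rising segment and a decaying exponential
#' from the empirical peak, spliced at the peak with continuity enforced
#' (the rise limb is rescaled so both limbs meet at the peak).
#'
#' @param trace baseline-subtracted single-stimulus residual current
#'   (inward negative).
#' @param time sample times (s).
#' @param stim_time stimulus time (s); reconstruction is zero before onset.
#' @return list with `wave` (numeric vector over `time`), `peak_time_s`,
#'   `rise_tau_s`, `decay_tau_s`, `splice_mismatch` (|rise - decay| at the
#'   peak as a fraction of the peak, before rescaling).
#' @export
reconstruct_residual_IK <- function(trace, time, stim_time) {
  if (all(trace == 0)) {
    return(list(wave = numeric(length(time)), peak_time_s = NA_real_,
                rise_tau_s = NA_real_, decay_tau_s = NA_real_,
                splice_mismatch = 0))
  }
  post <- which(time >= stim_time)
  ipk <- post[which.min(trace[post])]
  peak <- trace[ipk]
  if (!is.finite(peak) || peak >= 0) stop("no identifiable inward peak")
  t_pk <- time[ipk]
  # Rising segment: from 2% to 100% of the peak magnitude.
  mag <- -trace
  onset <- post[post <= ipk][which(mag[post[post <= ipk]] >=
                                     0.02 * (-peak))][1]
  if (is.na(onset) || ipk - onset < 5) onset <- max(post[1], ipk - 5L)
  rise_idx <- onset:ipk
  rise_fit <- minpack.lm::nlsLM(
    y ~ P * (1 - exp(-(tt - t0) / tau)),
    data = list(y = trace[rise_idx], tt = time[rise_idx]),
    start = list(P = peak, t0 = time[onset], tau = (t_pk - time[onset]) / 3),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  decay_idx <- ipk:length(time)
  decay_fit <- fit_monoexp(time[decay_idx], trace[decay_idx])
  rise_co <- stats::coef(rise_fit)
  rise_val <- function(tt) {
    v <- rise_co[["P"]] * (1 - exp(-(tt - rise_co[["t0"]]) / rise_co[["tau"]]))
    ifelse(tt >= rise_co[["t0"]], v, 0)
  }
  decay_val <- function(tt) decay_fit$amplitude *
    exp(-(tt - t_pk) / decay_fit$tau_s) + decay_fit$offset
  mismatch <- abs(rise_val(t_pk) - decay_val(t_pk)) / abs(peak)
  scale <- decay_val(t_pk) / rise_val(t_pk)
  wave <- numeric(length(time))
  pre <- time < t_pk
  wave[pre] <- scale * rise_val(time[pre])
  wave[!pre] <- decay_val(time[!pre])
  wave[time < stim_time] <- 0
  list(wave = wave, peak_time_s = t_pk, rise_tau_s = rise_co[["tau"]],
       decay_tau_s = decay_fit$tau_s, splice_mismatch = mismatch)
}

#' Extract the pure glutamate transporter current
#'
#' Subtracts the reconstructed residual potassium wave from the
#' blocker-condition synaptic current; the remainder is the transporter
#' current. Its amplitude is taken at the extremum and the decay from the
#' extremum is fitted monoexponentially over `fit_window_s`.
#'
#' @param trace baseline-subtracted current with receptor blockers (inward
#'   negative).
#' @param time sample times (s).
#' @param residual reconstructed residual wave (same length), already
#'   aligned to the stimulus of interest.
#' @param stim_time stimulus time (s).
#' @param fit_window_s decay-fit duration after the peak (s).
#' @return list with `i_glut` (the subtracted trace), `amplitude_pA`
#'   (magnitude), `tau_decay_s`, `peak_time_s`, `fit`.
#' @export
extract_IGluT <- function(trace, time, residual, stim_time,
                          fit_window_s = 0.08) {
  if (length(trace) != length(residual)) stop("trace length mismatch")
  g <- trace - residual
  post <- which(time >= stim_time)
  if (max(abs(g[post])) < 1e-12) {
    return(list(i_glut = g, amplitude_pA = 0, tau_decay_s = NA_real_,
                peak_time_s = NA_real_, fit = NULL))
  }
  ipk <- post[which.min(g[post])]
  idx <- which(time >= time[ipk] & time <= time[ipk] + fit_window_s)
  fit <- fit_monoexp(time[idx], g[idx])
  list(i_glut = g, amplitude_pA = abs(g[ipk]), tau_decay_s = fit$tau_s,
       peak_time_s = time[ipk], fit = fit)
}

#' Input resistance from a voltage-step response
#'
#' `R = dV / dI` with `dI` the steady-state current deflection: mean over
#' the last `steady_s` of the step minus the pre-step baseline mean. An
#' unsettled plateau (residual slope) is flagged.
#'
#' @param trace current (pA).
#' @param time sample times (s).
#' @param step_window c(start, end) of the voltage step (s).
#' @param dv_mv step size (mV), default -5.
#' @param baseline_window pre-step baseline (s); default everything up to
#'   10 ms before the step.
#' @param steady_s duration of the steady-state averaging window (s).
#' @param slope_tol allowed plateau drift over `steady_s` as a fraction of
#'   `dI`.
#' @return list with `r_mohm`, `di_pA`, `settled`.
#' @export
input_resistance <- function(trace, time, step_window, dv_mv = -5,
                             baseline_window = NULL, steady_s = 0.02,
                             slope_tol = 0.05) {
  if (is.null(baseline_window)) baseline_window <- c(0, step_window[1] - 0.01)
  base <- mean(trace[time >= baseline_window[1] & time <= baseline_window[2]])
  st <- time >= step_window[2] - steady_s & time < step_window[2]
  if (sum(st) < 5) stop("steady-state window too short")
  di <- mean(trace[st]) - base
  sl <- stats::coef(stats::lm(trace[st] ~ time[st]))[[2]]
  settled <- abs(sl * steady_s) <= slope_tol * abs(di)
  if (!settled) warning("plateau not settled: residual slope exceeds tolerance")
  list(r_mohm = dv_mv / di * 1000, di_pA = di, settled = settled)
}

#' Charge transfer over peak and tail windows
#'
#' Trapezoidal area under the baseline-subtracted current in the stated
#' windows (pA s, reported as magnitudes). With a `reference` result, each
#' window's AUC is also expressed as a percentage of the untreated
#' baseline AUC, the usual drug-effect normalization.
#'
#' @param trace current (pA).
#' @param time sample times (s).
#' @param peaks_window,tail_window c(start, end) windows (s); must not
#'   overlap and must lie inside the trace.
#' @param baseline_window pre-depolarization window defining zero current.
#' @param reference optional `charge_result` from the untreated condition.
#' @return a `charge_result`: list with `auc_peaks`, `auc_tail` (pA s) and,
#'   when `reference` is given, `peaks_pct`, `tail_pct`.
#' @export
epsc_charge <- function(trace, time, peaks_window, tail_window,
                        baseline_window = NULL, reference = NULL) {
  rng <- range(time)
  win_ok <- function(w) w[1] < w[2] && w[1] >= rng[1] && w[2] <= rng[2]
  if (!win_ok(peaks_window) || !win_ok(tail_window))
    stop("analysis window out of range")
  if (max(peaks_window[1], tail_window[1]) <
      min(peaks_window[2], tail_window[2]))
    stop("peaks and tail windows overlap")
  if (!is.null(baseline_window)) {
    sel <- time >= baseline_window[1] & time <= baseline_window[2]
    trace <- trace - mean(trace[sel])
  }
  auc <- function(w) {
    s <- time >= w[1] & time <= w[2]
    abs(trapz(time[s], trace[s]))
  }
  out <- list(auc_peaks = auc(peaks_window), auc_tail = auc(tail_window))
  if (!is.null(reference)) {
    out$peaks_pct <- 100 * out$auc_peaks / reference$auc_peaks
    out$tail_pct <- 100 * out$auc_tail / reference$auc_tail
  }
  structure(out, class = "charge_result")
}

#' LTP magnitude from an fEPSP amplitude series
#'
#' Amplitudes are normalized so the pre-HFS baseline mean is 100%; the
#' magnitude is the mean normalized amplitude over the analysis window
#' (50-60 min after HFS by default, per the Methods convention; a
#' 40-50 min window is the published figure-legend variant).
#'
#' @param series data frame with `time_min` and `amplitude` (any units).
#' @param hfs_time_min tetanus time; default taken from the series
#'   attribute or 0.
#' @param window_min analysis window relative to HFS (min).
#' @param baseline_min baseline duration before HFS used for normalization.
#' @return an `ltp_result`: list with `magnitude_pct`, `window_min`,
#'   `normalized` (data frame `time_min`, `pct`).
#' @export
ltp_magnitude <- function(series, hfs_time_min = NULL,
                          window_min = c(50, 60), baseline_min = 15) {
  if (is.null(hfs_time_min))
    hfs_time_min <- attr(series, "hfs_time_min") %||% 0
  if (window_min[1] < 0) stop("analysis window precedes HFS")
  rel <- series$time_min - hfs_time_min
  base <- rel < 0 & rel >= -baseline_min
  if (!any(base)) stop("no baseline samples")
  norm <- 100 * series$amplitude / mean(series$amplitude[base])
  sel <- rel >= window_min[1] & rel <= window_min[2]
  if (!any(sel)) stop("analysis window contains no samples")
  structure(list(magnitude_pct = mean(norm[sel]), window_min = window_min,
                 normalized = data.frame(time_min = series$time_min,
                                         pct = norm)),
            class = "ltp_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input-output curve
#'
#' Sorted stimulus-response table with mean and SEM per stimulus level.
#'
#' @param stim_ua stimulation currents (uA).
#' @param response response amplitudes (paired with `stim_ua`).
#' @return data frame `stim_ua`, `n`, `mean`, `sem`.
#' @export
input_output <- function(stim_ua, response) {
  stopifnot(length(stim_ua) == length(response))
  lv <- sort(unique(stim_ua))
  do.call(rbind, lapply(lv, function(s) {
    r <- response[stim_ua == s]
    data.frame(stim_ua = s, n = length(r), mean = mean(r),
               sem = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0)
  }))
}
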