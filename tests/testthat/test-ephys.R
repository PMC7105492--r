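test_that("baseline subtraction and averaging behave linearly", {
  sp <- sweep_params(noise_sd = 0, n_sweeps = 2, conditions = "none",
                     seed = 1)
  ss <- gen_astro_sweeps(sp)
  avg <- baseline_subtract_average(ss)
  # constant offset (holding current) removed: baseline sits at zero
  bw <- ss$baseline_window
  sel <- ss$time >= bw[1] & ss$time <= bw[2]
  expect_lt(max(abs(avg$traces$none_1[sel])), 1e-10)
  # identical sweeps: the average equals either sweep minus baseline
  expect_equal(avg$traces$none_5,
               ss$traces$none_5[, 1] - mean(ss$traces$none_5[sel, 1]),
               tolerance = 1e-12)
  # noisy sweeps: average approaches the noiseless superposition as 1/sqrt(n)
  ssn <- gen_astro_sweeps(sweep_params(noise_sd = 5, n_sweeps = 40,
                                       conditions = "none", seed = 2))
  avgn <- baseline_subtract_average(ssn)
  ref <- ssn$ground_truth$noiseless$none_5 -
    mean(ssn$ground_truth$noiseless$none_5[sel])
  expect_lt(stats::sd(avgn$traces$none_5 - ref), 3 * 5 / sqrt(40))
})

test_that("fifth-response isolation is sample-exact for superposed kernels", {
  ss <- gen_astro_sweeps(sweep_params(noise_sd = 0, seed = 1))
  avg <- baseline_subtract_average(ss)
  expect_equal(isolate_fifth_response(avg$traces$none_5, avg$traces$none_5),
               numeric(length(avg$time)))
  d <- isolate_fifth_response(avg$traces$none_5, avg$traces$none_4)
  t5 <- avg$time - avg$stim_times[5]
  kernel <- -200 * biexp_kernel(t5, 1, 8) - 100 * biexp_kernel(t5, 20, 300)
  expect_equal(d, kernel, tolerance = 1e-9)
  expect_error(isolate_fifth_response(1:5, 1:4), "mismatch")

  # facilitation scales the isolated peak linearly
  ssf <- gen_astro_sweeps(sweep_params(glut_fac = c(1, 1, 1, 1, 1.5),
                                       k_kernel = c(0, 50, 300),
                                       noise_sd = 0, seed = 1))
  avf <- baseline_subtract_average(ssf)
  df <- isolate_fifth_response(avf$traces$none_5, avf$traces$none_4)
  expect_equal(min(df) / min(avf$traces$none_1), 1.5, tolerance = 1e-6)
})

test_that("potassium-current measurement uses the 200 ms rule", {
  fs <- 5000
  time <- seq(0, 1.5, by = 1 / fs)
  # decay already under way at +200 ms: fallback to the value there
  tr <- -80 * exp(-pmax(time - 0.1, 0) / 0.3) * (time >= 0.1)
  m <- measure_IK(tr, time, last_stim_time = 0.1)
  expect_true(m$at_fallback)
  expect_equal(m$amplitude_pA, 80 * exp(-0.2 / 0.3), tolerance = 1e-6)
  expect_equal(m$tau_decay_s, 0.3, tolerance = 1e-3)

  # kernel peaking 250 ms after the stimulus: the true peak is taken
  tr2 <- -60 * biexp_kernel(time - 0.1, 600, 300)
  m2 <- measure_IK(tr2, time, last_stim_time = 0.1)
  expect_false(m2$at_fallback)
  tpk <- 0.1 + 0.6 * log(1 + 0.3 / 0.6)
  expect_equal(m2$peak_time_s, tpk, tolerance = 0.01)
  expect_equal(m2$amplitude_pA, 60, tolerance = 1e-3)

  # generator potassium kernel: tau recovered within a millisecond
  ss <- gen_astro_sweeps(sweep_params(noise_sd = 0, conditions = "none",
                                      glut_kernel = c(200, 1, 8), seed = 1))
  avg <- baseline_subtract_average(ss)
  mk <- measure_IK(avg$traces$none_1, avg$time, avg$stim_times[1])
  expect_equal(mk$tau_decay_s, 0.3, tolerance = 1 / 300)

  expect_error(measure_IK(tr[1:600], time[1:600], 0.1), "window")
})

test_that("monoexponential fitting recovers parameters and flags noise", {
  t <- seq(0, 1, by = 1 / 5000)
  y <- 5 * exp(-t / 0.15)
  f <- fit_monoexp(t, y)
  expect_equal(f$tau_s, 0.15, tolerance = 1e-6)
  expect_equal(f$amplitude, 5, tolerance = 1e-6)

  y2 <- -40 * exp(-t / 0.08) + 7
  f2 <- fit_monoexp(t, y2)
  expect_equal(f2$tau_s, 0.08, tolerance = 1e-6)
  expect_equal(f2$offset, 7, tolerance = 1e-6)

  set.seed(5)
  fn <- fit_monoexp(t[1:200], rnorm(200))
  expect_true(!fn$converged || fn$flagged)
})

test_that("monoexponential tau bias stays below 2% at SNR 20", {
  taus <- c(0.01, 0.05, 0.2, 0.8)
  for (tau in taus) {
    t <- seq(0, 6 * tau, by = max(tau / 50, 1 / 5000))
    rec <- vapply(1:50, function(s) {
      set.seed(1000 + s)
      y <- 100 * exp(-t / tau) + rnorm(length(t), 0, 5)  # SNR 20
      fit_monoexp(t, y)$tau_s
    }, numeric(1))
    expect_lt(abs(mean(rec) - tau) / tau, 0.02)
  }
})

test_that("residual reconstruction is smooth, continuous, and accurate", {
  ss <- gen_astro_sweeps(sweep_params(noise_sd = 0, conditions = "tboa",
                                      seed = 1))
  avg <- baseline_subtract_average(ss)
  rec <- reconstruct_residual_IK(avg$traces$tboa_1, avg$time,
                                 avg$stim_times[1])
  peak <- max(abs(avg$traces$tboa_1))
  rms <- sqrt(mean((rec$wave - avg$traces$tboa_1)^2))
  expect_lt(rms / peak, 0.02)
  # splice continuity of the constructed wave
  ipk <- which.min(abs(avg$time - rec$peak_time_s))
  expect_lt(abs(rec$wave[ipk] - rec$wave[ipk - 1]) / peak, 0.01)

  z <- reconstruct_residual_IK(numeric(100), seq(0, 1, length.out = 100), 0.1)
  expect_equal(z$wave, numeric(100))
})

test_that("transporter-current extraction recovers amplitude and decay", {
  ss <- gen_astro_sweeps(sweep_params(noise_sd = 0,
                                      conditions = c("blockers", "tboa"),
                                      seed = 1))
  avg <- baseline_subtract_average(ss)
  rec <- reconstruct_residual_IK(avg$traces$tboa_1, avg$time,
                                 avg$stim_times[1])
  # residual equal to the trace: extraction returns a flat zero
  g0 <- extract_IGluT(avg$traces$tboa_1, avg$time, avg$traces$tboa_1,
                      avg$stim_times[1])
  expect_equal(g0$amplitude_pA, 0)

  g1 <- extract_IGluT(avg$traces$blockers_1, avg$time, rec$wave,
                      avg$stim_times[1])
  expect_equal(g1$tau_decay_s, 0.008, tolerance = 0.5 / 8)
  expect_equal(g1$amplitude_pA, 200, tolerance = 0.03)

  # decay-ratio recovery at the reported control value
  est <- vapply(1:8, function(s) {
    sw <- gen_astro_sweeps(sweep_params(
      glut_tau_mult = c(1, 1, 1, 1, 1.28), noise_sd = 5,
      conditions = c("blockers", "tboa"), seed = s))
    tau_glut_ratio_from_sweeps(sw)
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.28) / 1.28, 0.05)
})

test_that("input resistance obeys Ohm's law", {
  st <- gen_step_response(r_mohm = 30, noise_sd_frac = 0, seed = 1)
  r <- input_resistance(st$current_pA, st$time, st$step_window,
                        dv_mv = st$dv_mv)
  expect_equal(r$r_mohm, 30, tolerance = 1e-6)
  # doubled current deflection halves the resistance
  tr2 <- (st$current_pA - mean(st$current_pA[st$time < 0.09])) * 2
  r2 <- input_resistance(tr2, st$time, st$step_window, dv_mv = st$dv_mv)
  expect_equal(r2$r_mohm, 15, tolerance = 1e-6)
  # noisy RC transient plus plateau: within 2% of ground truth
  stn <- gen_step_response(r_mohm = 42, noise_sd_frac = 0.02, seed = 3)
  rn <- input_resistance(stn$current_pA, stn$time, stn$step_window)
  expect_equal(rn$r_mohm, 42, tolerance = 0.02)
})

test_that("charge transfer integrates windows and normalizes to baseline", {
  fs <- 1000
  time <- seq(0, 2, by = 1 / fs)
  # rectangular pulse: AUC = height x width
  tr <- ifelse(time >= 0.5 & time <= 0.9, -30, 0)
  ch <- epsc_charge(tr, time, peaks_window = c(0.4, 1.0),
                    tail_window = c(1.2, 1.8))
  expect_equal(ch$auc_peaks, 30 * 0.4, tolerance = 1e-2)
  expect_equal(ch$auc_tail, 0)

  # drug trace at 70% of baseline: both fractions 70%
  base <- -40 * biexp_kernel(time - 0.3, 5, 300)
  drug <- 0.7 * base
  ref <- epsc_charge(base, time, c(0.3, 0.6), c(0.8, 1.9))
  d <- epsc_charge(drug, time, c(0.3, 0.6), c(0.8, 1.9), reference = ref)
  expect_equal(d$peaks_pct, 70, tolerance = 1e-9)
  expect_equal(d$tail_pct, 70, tolerance = 1e-9)

  # tail-only scaling (0.69) moves the tail fraction to 69% and leaves the
  # peaks fraction essentially untouched
  peaks_comp <- -150 * biexp_kernel(time - 0.3, 2, 30)
  tail_comp <- -20 * biexp_kernel(time - 0.3, 200, 500)
  untreated <- peaks_comp + tail_comp
  treated <- peaks_comp + 0.69 * tail_comp
  refu <- epsc_charge(untreated, time, c(0.3, 0.4), c(1.0, 1.9))
  trt <- epsc_charge(treated, time, c(0.3, 0.4), c(1.0, 1.9),
                     reference = refu)
  expect_equal(trt$tail_pct, 69, tolerance = 0.01)
  expect_gt(trt$peaks_pct, 95)

  expect_error(epsc_charge(tr, time, c(0.4, 1.0), c(0.9, 1.8)), "overlap")
  expect_error(epsc_charge(tr, time, c(-1, 0.5), c(1, 1.5)), "range")
})

test_that("charge transfer is additive over adjacent windows", {
  time <- seq(0, 2, by = 1e-3)
  tr <- -35 * biexp_kernel(time - 0.2, 10, 400)
  a <- epsc_charge(tr, time, c(0.2, 0.8), c(0.8, 1.6))
  whole <- epsc_charge(tr, time, c(0.2, 1.6), c(1.7, 1.9))
  expect_equal(a$auc_peaks + a$auc_tail, whole$auc_peaks, tolerance = 1e-3)
})

test_that("LTP magnitude normalizes to baseline and hits reported values", {
  flat <- gen_ltp_series(ltp_series_params(potentiation_factor = 1,
                                           amplitude_noise_cv = 0))
  expect_equal(ltp_magnitude(flat)$magnitude_pct, 100, tolerance = 1e-9)

  # post-HFS series at 1.47 x baseline reads 147%
  s <- gen_ltp_series(ltp_series_params(potentiation_factor = 1.47,
                                        onset_tau_min = 1e-6,
                                        amplitude_noise_cv = 0))
  expect_equal(ltp_magnitude(s)$magnitude_pct, 147, tolerance = 1e-6)

  # reported CR magnitude under 5% noise across 9 series
  est <- vapply(1:9, function(k) {
    ser <- gen_ltp_series(ltp_series_params(potentiation_factor = 1.68,
                                            amplitude_noise_cv = 0.05,
                                            seed = k))
    ltp_magnitude(ser)$magnitude_pct
  }, numeric(1))
  expect_lt(abs(mean(est) - 168), 6)

  expect_error(ltp_magnitude(flat, window_min = c(-10, 0)), "precedes")
})

test_that("input-output tables summarize paired observations", {
  one <- input_output(c(100), c(0.4))
  expect_equal(nrow(one), 1)
  dup <- input_output(c(100, 100, 200, 200), c(0.4, 0.4, 0.8, 0.8))
  expect_true(all(dup$sem == 0))
  # linear ground truth recovered by regression across levels
  set.seed(2)
  stim <- rep(seq(100, 400, by = 50), each = 6)
  resp <- 0.003 * stim + rnorm(length(stim), 0, 0.02)
  io <- input_output(stim, resp)
  sl <- stats::coef(stats::lm(io$mean ~ io$stim_ua))[[2]]
  expect_equal(sl, 0.003, tolerance = 0.05)
})
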