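test_that("astrocyte image honors the volume-fraction contract pixel by pixel", {
  # vf = 0: neuropil equals background exactly
  img0 <- gen_astrocyte_image(imaging_params(leaflet_vf = 0, noise_sd = 0,
                                             seed = 1))
  pl <- img0$planes[[1]]
  gt <- img0$ground_truth
  px <- img0$pixel_size_um
  g <- astrocr:::pixel_grid_um(nrow(pl), ncol(pl), px)
  rs <- sqrt(outer((g$x - gt$soma_center[1])^2, rep(1, ncol(pl)), "+") +
               outer(rep(1, nrow(pl)), (g$y - gt$soma_center[2])^2))
  neuropil <- rs > gt$soma_radius_um + 3 & !gt$branch_mask
  expect_lt(max(abs(pl[neuropil] - gt$f_0)), 1e-2 * (gt$f_max - gt$f_0))

  # vf = 1: neuropil saturates at the soma peak
  img1 <- gen_astrocyte_image(imaging_params(leaflet_vf = 1, noise_sd = 0,
                                             seed = 1))
  pl1 <- img1$planes[[1]]
  bg_d <- sqrt(outer((g$x - gt$bg_circle_center[1])^2, rep(1, ncol(pl)), "+") +
                 outer(rep(1, nrow(pl)), (g$y - gt$bg_circle_center[2])^2))
  sel1 <- neuropil & bg_d > gt$bg_circle_diameter_um / 2 + 1
  expect_equal(unname(range(pl1[sel1])), rep(gt$f_max, 2), tolerance = 1e-6)

  # intermediate vf: per-pixel arithmetic recovers it everywhere
  imgv <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.045,
                                             noise_sd = 0, seed = 1))
  vfpix <- (imgv$planes[[1]][sel1] - gt$f_0) / (gt$f_max - gt$f_0)
  expect_equal(unname(range(vfpix)), c(0.045, 0.045), tolerance = 1e-9)

  # dye-free circle holds pure background
  hole <- bg_d < gt$bg_circle_diameter_um / 2 - 1
  expect_true(all(abs(imgv$planes[[1]][hole] - gt$f_0) < 1e-9))

  # frame too small is rejected
  expect_error(gen_astrocyte_image(imaging_params(frame_size_um = c(40, 40))),
               "too small")
})

test_that("coupled networks follow the exponential decay law exactly", {
  # two cells at d = C_lambda: F = exp(-1)
  p <- coupling_params(n_cells = 2, length_constant_um = 20,
                       min_distance_um = 20 - 1e-9,
                       max_distance_um = 20 + 1e-9, noise_sd = 0, seed = 5)
  net <- gen_coupled_network(p)
  expect_equal(net$fluorescence[2], exp(-1), tolerance = 1e-9)

  # noiseless: ln F is exactly linear in d with slope -1/C_lambda
  net2 <- gen_coupled_network(coupling_params(n_cells = 10, noise_sd = 0,
                                              seed = 3))
  d <- distances_3d(net2)[-1]
  lf <- log(net2$fluorescence[-1])
  expect_equal(lf, -d / 19.9, tolerance = 1e-12)

  # bit-identical regeneration under a fixed seed
  a <- gen_coupled_network(coupling_params(n_cells = 10, noise_sd = 0.05,
                                           seed = 11))
  b <- gen_coupled_network(coupling_params(n_cells = 10, noise_sd = 0.05,
                                           seed = 11))
  expect_identical(a$fluorescence, b$fluorescence)
  expect_identical(a$x, b$x)
})

test_that("puncta frames place the expected number of hard-core discs", {
  # density 0 -> blank background-only frame
  blank <- gen_puncta_frame(puncta_params(density_per_um2 = 0, noise_sd = 0))
  expect_equal(blank$ground_truth$n_true, 0)
  expect_lt(diff(range(blank$planes[[1]])), 3)  # just the smooth ramp

  # single centered disc -> exactly one ground-truth record
  one <- gen_puncta_frame(puncta_params(density_per_um2 = 1 / 2500,
                                        diameter_um = 1.5, noise_sd = 0))
  expect_equal(one$ground_truth$n_true, 1)

  # control-density frame: realized count within 3*sqrt(600) of 600
  fr <- gen_puncta_frame(puncta_preset("cx43", seed = 2))
  expect_lt(abs(fr$ground_truth$n_true - 600), 3 * sqrt(600))
  # hard-core: no pair closer than the stated separation
  ctr <- fr$ground_truth$centers_um
  dmin <- min(dist(ctr))
  expect_gte(dmin, fr$params$min_separation_um - 1e-9)

  # infeasible combination is rejected with a message
  expect_error(gen_puncta_frame(puncta_params(density_per_um2 = 0.05,
                                              diameter_um = 1.4,
                                              min_separation_um = 6)),
               "infeasible|coverage")
})

test_that("sweep sets superpose kernels linearly and record ground truth", {
  sp <- sweep_params(noise_sd = 0, seed = 1)
  ss <- gen_astro_sweeps(sp)
  # 5-stim minus 4-stim equals the fifth-stimulus kernels sample-exactly
  d5 <- ss$ground_truth$noiseless$none_5 - ss$ground_truth$noiseless$none_4
  t5 <- ss$time - ss$stim_times[5]
  fifth <- -sp$glut_kernel[1] * biexp_kernel(t5, sp$glut_kernel[2],
                                             sp$glut_kernel[3]) -
    sp$k_kernel[1] * biexp_kernel(t5, sp$k_kernel[2], sp$k_kernel[3])
  expect_equal(d5, fifth, tolerance = 1e-10)

  # unit facilitation: every stimulus response has the shape of the first
  tr1 <- ss$ground_truth$noiseless$tboa_1 - sp$holding_pA
  n_shift <- round((ss$stim_times[2] - ss$stim_times[1]) * sp$sampling_rate)
  d45 <- (ss$ground_truth$noiseless$tboa_5 -
            ss$ground_truth$noiseless$tboa_4)[(n_shift * 4 + 1):length(tr1)]
  expect_equal(d45, tr1[seq_along(d45)], tolerance = 1e-10)

  # decay-tau multiplier is recorded as ground truth
  sp2 <- sweep_params(k_tau_mult = c(1, 1, 1, 1, 0.59))
  ss2 <- gen_astro_sweeps(sp2)
  expect_equal(ss2$ground_truth$k$decay_ms[5] / ss2$ground_truth$k$decay_ms[1],
               0.59)
})

test_that("LTP series potentiate as configured and regenerate bit-identically", {
  flat <- gen_ltp_series(ltp_series_params(potentiation_factor = 1,
                                           amplitude_noise_cv = 0))
  expect_true(all(abs(flat$amplitude - 100) < 1e-12))

  pot <- gen_ltp_series(ltp_series_params(potentiation_factor = 1.68,
                                          amplitude_noise_cv = 0))
  late <- pot$time_min >= 50 & pot$time_min <= 60
  expect_equal(mean(pot$amplitude[late]), 168, tolerance = 1e-3)

  a <- gen_ltp_series(ltp_series_params(amplitude_noise_cv = 0.05, seed = 9))
  b <- gen_ltp_series(ltp_series_params(amplitude_noise_cv = 0.05, seed = 9))
  expect_identical(a$amplitude, b$amplitude)
})

test_that("generators are pure functions of (params, seed)", {
  a <- gen_astrocyte_image(imaging_params(noise_sd = 8, seed = 4))
  b <- gen_astrocyte_image(imaging_params(noise_sd = 8, seed = 4))
  expect_identical(a$planes, b$planes)
  a2 <- gen_puncta_frame(puncta_preset("cx30_proximal", seed = 4))
  b2 <- gen_puncta_frame(puncta_preset("cx30_proximal", seed = 4))
  expect_identical(a2$planes, b2$planes)
  a3 <- gen_astro_sweeps(sweep_params(noise_sd = 3, seed = 4))
  b3 <- gen_astro_sweeps(sweep_params(noise_sd = 3, seed = 4))
  expect_identical(a3$traces, b3$traces)
})

test_that("ground truth round-trips through the serialization layer", {
  img <- gen_astrocyte_image(imaging_params(noise_sd = 5, seed = 3))
  f <- file.path(tempdir(), "img_rt.tiff")
  write_labeled_image(img, f)
  back <- read_labeled_image(f)
  for (nm in names(img$ground_truth)) {
    expect_equal(back$ground_truth[[nm]], img$ground_truth[[nm]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_lt(max(abs(back$planes[[1]] - pmax(img$planes[[1]], 0))),
            1e-4 * max(img$planes[[1]]))

  ss <- gen_astro_sweeps(sweep_params(noise_sd = 2, n_sweeps = 2, seed = 4))
  f2 <- file.path(tempdir(), "sweeps_rt.csv")
  write_sweep_set(ss, f2)
  back2 <- read_sweep_set(f2)
  expect_equal(back2$ground_truth$noiseless, ss$ground_truth$noiseless,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(back2$traces$none_5), unname(ss$traces$none_5),
               tolerance = 1e-9, ignore_attr = TRUE)

  net <- gen_coupled_network(coupling_params(seed = 2))
  f3 <- file.path(tempdir(), "net_rt.csv")
  write_coupled_network(net, f3)
  back3 <- read_coupled_network(f3)
  expect_equal(back3$fluorescence, net$fluorescence, tolerance = 1e-12)
})
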