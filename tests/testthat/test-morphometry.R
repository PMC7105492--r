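test_that("mask preprocessing handles degenerate and identity inputs", {
  expect_error(preprocess_mask(list(), pixel_size_um = 0.25), "empty")

  zero <- preprocess_mask(list(matrix(0, 64, 64)), pixel_size_um = 0.25,
                          ced = NULL)
  expect_false(any(zero))

  # input already at 0.25 um/px: no resampling (dimensions preserved)
  m <- matrix(runif(64 * 64), 64, 64)
  bm <- preprocess_mask(list(m), pixel_size_um = 0.25, ced = NULL)
  expect_identical(dim(bm), dim(m))
  # resampling halves/doubles dimensions otherwise
  bm2 <- preprocess_mask(list(m), pixel_size_um = 0.5, ced = NULL)
  expect_identical(dim(bm2), c(128L, 128L))
})

test_that("masks cover the rendered branches", {
  img <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.032,
                                            noise_sd = 10, seed = 3))
  mask <- preprocess_mask(img)
  bm <- img$ground_truth$branch_mask
  expect_gte(sum(mask & bm) / sum(bm), 0.9)
})

test_that("sholl counts match geometry on constructed masks", {
  px <- 0.25
  empty <- structure(matrix(FALSE, 121, 121), pixel_size_um = px)
  ctr <- c(60.5, 60.5) * px
  sp <- sholl_profile(empty, ctr, radii_um = 1:10)
  expect_true(all(sp$intersections == 0))

  # six straight arms: six intersections at every radius inside the arms
  sm <- star_mask(6, size_px = 321, arm_px = 160, px_um = px)
  c6 <- c(161, 161) * px - 0.125
  sp6 <- sholl_profile(sm, c6, radii_um = seq(5, 38, by = 1))
  expect_true(all(sp6$intersections == 6))

  # solid disk: one intersection below its radius, zero beyond
  g <- expand.grid(i = 1:121, j = 1:121)
  disk <- matrix(sqrt((g$i - 61)^2 + (g$j - 61)^2) <= 40, 121, 121)
  disk <- structure(disk, pixel_size_um = px)
  cd <- c(61, 61) * px - 0.125
  spd <- sholl_profile(disk, cd, radii_um = c(2, 5, 8))
  expect_true(all(spd$intersections == 1))
  expect_true(all(sholl_profile(disk, cd, radii_um = c(11.5, 13))$intersections
                  == c(0, 0)))

  # radius beyond the frame: missing, not zero
  far <- sholl_profile(disk, cd, radii_um = c(5, 20))
  expect_true(is.na(far$intersections[2]))
  expect_false(is.na(far$intersections[1]))
})

test_that("circle-walk counts equal the connected-component oracle", {
  set.seed(71)
  for (arms in c(3, 5, 8)) {
    sm <- star_mask(arms, size_px = 121, arm_px = 55)
    ctr <- c(61, 61) * 0.25 - 0.125
    for (r in seq(3, 13, by = 0.8)) {
      expect_identical(
        sholl_profile(sm, ctr, radii_um = r)$intersections,
        as.integer(sholl_oracle(sm, ctr, r)))
    }
  }
  # speckled masks (<= 128 px frames): equality must hold on arbitrary
  # foreground, not just clean stars
  set.seed(72)
  for (s in 1:3) {
    sm <- star_mask(4, size_px = 121, arm_px = 55)
    flip <- sample(length(sm), 900)
    sm[flip] <- !sm[flip]
    ctr <- c(61, 61) * 0.25 - 0.125
    for (r in seq(3, 14, by = 1.3)) {
      expect_identical(sholl_profile(sm, ctr, radii_um = r)$intersections,
                       as.integer(sholl_oracle(sm, ctr, r)))
    }
  }
})

test_that("radial profiles respect symmetry and sample branches", {
  # constant image -> constant profiles
  const <- matrix(7, 201, 201)
  pr <- radial_profiles(const, c(25, 25), 0.25)
  expect_length(pr, 8)
  for (p in pr) expect_true(all(abs(p$F - 7) < 1e-12))

  # radially symmetric image -> all 8 profiles identical
  g <- expand.grid(i = 1:201, j = 1:201)
  r <- sqrt((g$i - 101)^2 + (g$j - 101)^2)
  sym <- matrix(exp(-r / 30), 201, 201)
  ctr <- c(101, 101) * 0.25 - 0.125
  ps <- radial_profiles(sym, ctr, 0.25)
  ref <- ps[[1]]$F
  for (p in ps[-1]) {
    n <- min(length(ref), length(p$F))
    expect_equal(p$F[1:n], ref[1:n], tolerance = 5e-3)
  }

  # a line along a ground-truth branch reads the branch intensity
  img <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.03, noise_sd = 0,
                                            seed = 2))
  th <- img$ground_truth$branch_angles[1] * 180 / pi
  on_branch <- radial_profiles(img$planes[[1]], img$ground_truth$soma_center,
                               img$pixel_size_um, n_lines = 1,
                               angle0_deg = th)[[1]]
  off_branch <- radial_profiles(img$planes[[1]], img$ground_truth$soma_center,
                                img$pixel_size_um, n_lines = 1,
                                angle0_deg = th + 30)[[1]]
  at15 <- which.min(abs(on_branch$distance_um - 15))
  expect_gt(on_branch$F[at15], off_branch$F[at15] +
              0.5 * (img$ground_truth$f_max - img$ground_truth$f_0))

  expect_error(radial_profiles(const, c(999, 999), 0.25), "outside")
})

test_that("branch excision flags exactly the above-threshold excursions", {
  d <- seq(0, 40, by = 0.25)
  base <- rep(20, length(d))
  prof <- function(F) structure(data.frame(distance_um = d, F = F,
                                           excised = FALSE),
                                class = c("intensity_profile", "data.frame"))
  f_max <- 220; f_0 <- 10  # dynamic range 210

  flat <- excise_branches(prof(base), f_max, f_0)
  expect_false(any(flat$excised))

  # rectangular bump at half dynamic range (2 um wide, a branch caliber
  # the 5 um median baseline can bridge): bump flagged, flanks kept
  bump <- base; bump[d >= 15 & d <= 16.9] <- 20 + 0.5 * 210
  ex <- excise_branches(prof(bump), f_max, f_0)
  expect_true(all(ex$excised[d >= 15.4 & d <= 16.5]))
  expect_false(any(ex$excised[d < 13 | d > 19]))

  # bump below the 10% threshold is untouched
  small <- base; small[d >= 15 & d <= 16.9] <- 20 + 0.05 * 210
  expect_false(any(excise_branches(prof(small), f_max, f_0)$excised))
})

test_that("background estimation finds the dye-free circle", {
  uni <- matrix(7, 101, 101)
  est <- estimate_background(uni, 0.25, diameter_um = 10)
  expect_equal(est$f0, 7, tolerance = 1e-12)

  img <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.04, noise_sd = 5,
                                            seed = 6))
  est2 <- estimate_background(img$planes[[1]], img$pixel_size_um)
  gt <- img$ground_truth
  off <- sqrt(sum((est2$center_um - gt$bg_circle_center)^2))
  expect_lt(off, gt$bg_circle_diameter_um / 2)  # chosen circle overlaps it
  expect_equal(est2$f0, gt$f_0, tolerance = 0.05 * gt$f_0)

  # fully excluded plane: no feasible circle
  expect_error(estimate_background(uni, 0.25, exclusion_mask =
                                     matrix(TRUE, 101, 101)), "feasible")
})

test_that("volume-fraction estimation hits the boundary cases and ground truth", {
  d <- seq(0, 35, by = 0.25)
  prof <- function(F) structure(data.frame(distance_um = d, F = F,
                                           excised = FALSE),
                                class = c("intensity_profile", "data.frame"))
  p0 <- lapply(1:8, function(k) prof(rep(10, length(d))))
  expect_equal(estimate_vf(p0, f_0 = 10, f_max = 200)$mean_vf, 0)
  p1 <- lapply(1:8, function(k) prof(rep(200, length(d))))
  expect_equal(estimate_vf(p1, f_0 = 10, f_max = 200)$mean_vf, 1)
  expect_error(estimate_vf(p1, f_0 = 200, f_max = 10), "exceed")

  img <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.045, noise_sd = 0,
                                            seed = 1))
  expect_equal(vf_from_image(img)$mean_vf, 0.045, tolerance = 0.002 / 0.045)
})

test_that("volume fraction is invariant to affine intensity rescaling", {
  img <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.035, noise_sd = 8,
                                            seed = 9))
  v1 <- vf_from_image(img)$mean_vf
  img$planes[[1]] <- 3.7 * img$planes[[1]] + 55
  v2 <- vf_from_image(img)$mean_vf
  expect_equal(v2, v1, tolerance = 1e-9)
})

test_that("volume-fraction recovery stays unbiased under realistic noise", {
  # noiseless: exact to interpolation error across the vf range
  for (vf in c(0.01, 0.05, 0.10)) {
    img <- gen_astrocyte_image(imaging_params(leaflet_vf = vf, noise_sd = 0,
                                              seed = 2))
    expect_equal(vf_from_image(img)$mean_vf, vf, tolerance = 0.002 / vf)
  }
  # 5%-of-peak noise: bias below 10% of the true value over seeds
  vf <- 0.045
  est <- vapply(1:12, function(s) {
    img <- gen_astrocyte_image(imaging_params(leaflet_vf = vf, noise_sd = 10,
                                              seed = s))
    vf_from_image(img)$mean_vf
  }, numeric(1))
  expect_lt(abs(mean(est) - vf), 0.1 * vf)
})
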