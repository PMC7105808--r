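test_that("initial-volume discard retains the right series and shifts onsets", {
  proto <- acquisition_protocol()
  sc <- default_scenario(networks = character(0), motion_component = FALSE,
                         csf_component = FALSE, motion = "none")
  sub <- simulate_subject(proto, scenario = sc, seed = 1)
  vol <- discard_initial(sub$raw, 4)
  expect_equal(dim(vol$data)[4], 304L)
  expect_equal(vol$data, sub$raw$data[, , , 5:308], ignore_attr = TRUE)
  # n = 0 leaves the series untouched
  expect_identical(discard_initial(sub$raw, 0)$data, sub$raw$data)
  # paradigm bookkeeping: onsets move back by n * TR
  par <- build_paradigm()
  small <- volume4d(array(rnorm(2 * 2 * 2 * 5), c(2, 2, 2, 5)))
  out <- discard_initial(small, 4, paradigm = par)
  expect_equal(dim(out$vol$data)[4], 1L)
  expect_equal(out$paradigm$events$onset, par$events$onset - 7.2)
  expect_error(discard_initial(small, 5), "cannot discard")
})

test_that("realignment recovers injected translations and is idempotent", {
  sc <- default_scenario(networks = character(0), motion_component = FALSE,
                         csf_component = FALSE, motion = "none")
  sub <- simulate_subject(small_protocol(n_recorded = 90L), scenario = sc,
                          seed = 2)
  vol <- discard_initial(sub$raw, 4)
  # motion-free input: estimates stay below 0.1 voxel
  re <- realign_translational(vol)
  est_vox <- sweep(re$trace$params[, 4:6], 2, vol$voxel_mm, `/`)
  expect_lt(max(abs(est_vox)), 0.1)
  # the reference volume's estimate is exactly zero
  expect_equal(est_vox[re$trace$reference_index, ], c(0, 0, 0),
               ignore_attr = TRUE)
  # inject a +1 voxel x-shift on a block of volumes and recover it
  shifted <- vol
  for (t in 40:70) {
    shifted$data[, , , t] <- stfica:::shift_volume3d(vol$data[, , , t],
                                                     c(1, 0, 0))
  }
  re2 <- realign_translational(shifted)
  est2 <- sweep(re2$trace$params[, 4:6], 2, vol$voxel_mm, `/`)
  truth <- matrix(0, dim(vol$data)[4], 3)
  truth[40:70, 1] <- 1
  # estimates are relative to the reference volume's own position
  truth <- sweep(truth, 2, truth[re2$trace$reference_index, ])
  expect_lt(max(abs(est2 - truth)), 0.25)
  # realignment is idempotent: a second pass estimates < 0.05 voxel
  re3 <- realign_translational(re2$vol)
  est3 <- sweep(re3$trace$params[, 4:6], 2, vol$voxel_mm, `/`)
  expect_lt(max(abs(est3)), 0.05)
  expect_error(realign_translational(
    volume4d(array(0, c(4, 4, 4, 6)))), "zero")
})

test_that("displacement metrics follow the rigid-body geometry", {
  # zero motion: all displacements zero, subject included
  tr0 <- motion_trace(matrix(0, 10, 6), 5)
  d0 <- displacement_and_exclusion(tr0)
  expect_equal(d0$abs_mean, 0)
  expect_equal(d0$rel_mean, 0)
  expect_false(d0$exclude)
  expect_equal(d0$abs_disp[5], 0)
  expect_length(d0$rel_disp, 9L)
  # alternating (0.3, 0, 0.4) mm translations: every transition is 0.5 mm
  p <- matrix(0, 20, 6)
  p[seq(2, 20, by = 2), 4] <- 0.3
  p[seq(2, 20, by = 2), 6] <- 0.4
  d1 <- displacement_and_exclusion(motion_trace(p, 1))
  expect_equal(d1$rel_disp, rep(0.5, 19))
  # rotations contribute their 80 mm arc in quadrature
  p2 <- matrix(0, 2, 6)
  p2[2, 1] <- 0.01        # 0.8 mm arc
  p2[2, 4] <- 0.6
  d2 <- displacement_and_exclusion(motion_trace(p2, 1))
  expect_equal(d2$rel_disp, sqrt(0.8^2 + 0.6^2))
  # exclusion triggers at the documented limits
  p3 <- matrix(0, 11, 6)
  p3[seq(2, 11, by = 2), 4] <- 1.3   # rel_mean 1.3 mm
  d3 <- displacement_and_exclusion(motion_trace(p3, 1))
  expect_gte(d3$rel_mean, 1)
  expect_true(d3$exclude)
  # monotone: scaling translations up never flips exclude -> include
  verdicts <- sapply(c(1, 1.5, 2, 4), function(s) {
    ps <- p3; ps[, 4:6] <- ps[, 4:6] * s
    displacement_and_exclusion(motion_trace(ps, 1))$exclude
  })
  expect_true(all(diff(as.integer(verdicts)) >= 0))
  expect_error(displacement_and_exclusion(motion_trace(matrix(0, 0, 6), 1)))
})

test_that("intensity masking recovers a synthetic head", {
  # bright ellipsoid on dark background
  d <- c(20L, 20L, 14L)
  truth <- stfica:::head_mask_for_grid(d)
  set.seed(9)
  arr <- array(rnorm(prod(d) * 8, 0, 2), c(d, 8))
  arr <- arr + as.numeric(truth) * 100
  vol <- volume4d(arr, voxel_mm = c(3, 3, 3))
  m <- brain_mask(vol)
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.95)
  expect_type(m, "logical")
  expect_identical(dim(m), d)
  # degenerate flat input errors
  expect_error(brain_mask(volume4d(array(0, c(4, 4, 4, 3)))), "constant")
})

test_that("smoothing matches the requested FWHM and preserves mass", {
  # delta impulse on 1 mm voxels, 5 mm FWHM kernel
  d <- c(33L, 33L, 33L)
  arr <- array(0, c(d, 1))
  arr[17, 17, 17, 1] <- 1
  vol <- volume4d(arr, voxel_mm = c(1, 1, 1))
  vol$mask <- array(TRUE, d)
  sm <- smooth_and_normalize(vol, fwhm_mm = 5, target_grand_mean = 1)
  prof <- sm$data[, 17, 17, 1]
  prof <- prof / max(prof)
  # measure the half-maximum width by linear interpolation
  above <- which(prof >= 0.5)
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (0.5 - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f_hi <- hi + (prof[hi] - 0.5) / (prof[hi] - prof[hi + 1])
  expect_equal(f_hi - f_lo, 5, tolerance = 0.25)
  # fwhm 0 leaves the data unchanged up to the grand-mean factor
  vol2 <- volume4d(array(runif(4 * 4 * 4 * 3, 1, 2), c(4, 4, 4, 3)))
  vol2$mask <- array(TRUE, c(4L, 4L, 4L))
  out2 <- smooth_and_normalize(vol2, fwhm_mm = 0, target_grand_mean = 10000)
  ratio <- out2$data / vol2$data
  expect_lt(diff(range(ratio)), 1e-9)
  # grand mean lands exactly on target
  expect_equal(mean(out2$data), 10000, tolerance = 1e-6)
  # interior mass is preserved by smoothing (kernel rows sum to one)
  blob <- array(0, c(d, 1))
  blob[13:21, 13:21, 13:21, 1] <- 1
  vb <- volume4d(blob, voxel_mm = c(1, 1, 1))
  vb$mask <- array(TRUE, d)
  sb <- smooth_and_normalize(vb, fwhm_mm = 3, target_grand_mean = mean(blob))
  expect_equal(sum(sb$data), sum(blob), tolerance = 0.01 * sum(blob))
})

test_that("grand-mean normalization scales the whole set by one factor", {
  sub <- simulate_subject(small_protocol(), seed = 3)
  vol <- discard_initial(sub$raw, 4)
  vol$mask <- brain_mask(vol)
  out <- smooth_and_normalize(vol, fwhm_mm = 5)
  expect_equal(mean(stfica:::vol_matrix(out)), 10000, tolerance = 1e-6)
  # single multiplicative factor: ratio to the smoothed-but-unscaled data
  out2 <- smooth_and_normalize(vol, fwhm_mm = 5, target_grand_mean = 20000)
  expect_equal(out2$data, out$data * 2, tolerance = 1e-9)
})
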