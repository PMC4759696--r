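test_that("attenuation compensation is bounded, inclusive-tail and flags empty A-lines", {
  set.seed(8)
  vol <- array(runif(32 * 6 * 5), c(32, 6, 5))
  comp <- compensate_attenuation(vol, n = 2)
  expect_true(all(comp$data >= 0 & comp$data <= 0.5))
  # deepest nonzero voxel of every A-line maps to exactly 0.5
  expect_true(all(comp$data[32, , ] == 0.5))

  # all-zero A-line: zeros, flagged
  vol[, 2, 3] <- 0
  comp2 <- compensate_attenuation(vol, n = 2)
  expect_true(all(comp2$data[, 2, 3] == 0))
  expect_true(comp2$flagged[2, 3])
  expect_false(comp2$flagged[1, 1])
  expect_error(compensate_attenuation(vol - 1), "nonnegative")
})

test_that("compensation of an exponential A-line plateaus at the geometric-series constant", {
  # closed form: for I(z) = I0 exp(-alpha z) sampled at pitch Delta, the
  # inclusive-tail compensated signal is (1 - exp(-n alpha Delta)) / 2
  # everywhere above the bottom boundary
  n <- 2; a_delta <- 0.0025            # n * alpha * Delta = 0.005
  nz <- 4096
  I <- exp(-a_delta * (seq_len(nz) - 1))
  vol <- array(I, c(nz, 1, 1))
  comp <- compensate_attenuation(vol, n = n)$data[, 1, 1]
  const_inclusive <- (1 - exp(-n * a_delta)) / 2
  top <- comp[seq_len(nz / 2)]
  expect_true(all(abs(top - const_inclusive) / const_inclusive < 0.01))
  # the exclusive-tail form differs only by exp(n alpha Delta); at this decay
  # the plateau matches it within 1% as well
  expect_true(all(abs(top - (exp(n * a_delta) - 1) / 2) /
                    ((exp(n * a_delta) - 1) / 2) < 0.01))
  expect_equal(comp[nz], 0.5)
})

test_that("compensation is monotone in I(z) with the tail held fixed", {
  v <- c(0.2, 0.5, 0.3, 0.8, 0.1)
  comp_at <- function(x) {
    vol <- array(c(v[1], x, v[3:5]), c(5, 1, 1))
    compensate_attenuation(vol, n = 2)$data[2, 1, 1]
  }
  xs <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(vapply(xs, comp_at, 0)) > 0))
})

test_that("surface detection recovers flat and sinusoidal phantom surfaces", {
  # flat surface
  ph <- generate_phantom(small_spec(), seed = 19)
  amp <- structural_amplitude(ph$volume)
  surf <- detect_surface(amp)
  expect_lte(max(abs(surf$surface_vox - ph$truth$surface_vox)), 1)

  # sinusoidal topography
  ph2 <- generate_phantom(small_spec(topography_amplitude_um = 24,
                                     topography_period_um = 480), seed = 19)
  amp2 <- structural_amplitude(ph2$volume)
  surf2 <- detect_surface(amp2)
  expect_lte(max(abs(surf2$surface_vox - ph2$truth$surface_vox)), 1)

  # pure noise: every column flagged
  set.seed(2)
  noise <- array(abs(rnorm(48 * 8 * 8, sd = 1e-3)), c(48, 8, 8))
  expect_warning(s3 <- detect_surface(noise), "flagged")
  expect_true(all(s3$flagged))
})

test_that("EDJ segmentation finds the epidermis thickness and flags flat profiles", {
  ph <- generate_phantom(small_spec(), seed = 29)
  amp <- structural_amplitude(ph$volume)
  comp <- compensate_attenuation(amp^2, n = 2)
  surf <- detect_surface(amp)
  edj <- segment_edj(comp, surf, axial_pitch_um = 8)
  # phantom epidermis is 120 um = 15 voxels thick
  err <- abs(edj$edj_vox - ph$truth$edj_vox)
  expect_lte(stats::median(err), 1)
  expect_lte(max(err), 2)
  expect_true(all(edj$edj_vox >= surf$surface_vox))

  # no epidermis contrast: columns flagged
  ph2 <- generate_phantom(small_spec(epidermis_multiplier = 1), seed = 29)
  amp2 <- structural_amplitude(ph2$volume)
  comp2 <- compensate_attenuation(amp2^2, n = 2)
  surf2 <- detect_surface(amp2)
  edj2 <- suppressWarnings(segment_edj(comp2, surf2, axial_pitch_um = 8))
  expect_gt(mean(edj2$flagged), 0.5)

  # window beyond the volume depth errors
  expect_error(segment_edj(comp, surf, axial_pitch_um = 8,
                           window_um = c(40, 2000)), "window")
})

test_that("flattening is an exact roll for constant references and invertible", {
  set.seed(10)
  vol <- array(rnorm(24 * 6 * 5), c(24, 6, 5))
  ref <- matrix(7, 6, 5)
  flat <- flatten_volume(vol, ref, target = 12)
  expect_equal(flat$data[6:24, , ], vol[1:19, , ])
  expect_true(all(flat$valid[6:24, , ]))
  expect_false(any(flat$valid[1:5, , ]))

  # flatten then unflatten restores the valid region
  ref2 <- matrix(sample(5:12, 30, replace = TRUE), 6, 5)
  flat2 <- flatten_volume(vol, ref2)
  back <- unflatten_volume(flat2)
  expect_equal(back$data[back$valid], vol[back$valid])

  # phantom with wavy EDJ flattens to constant reference depth
  ph <- generate_phantom(small_spec(topography_amplitude_um = 24,
                                    topography_period_um = 480), seed = 37)
  amp <- structural_amplitude(ph$volume)
  fl <- flatten_volume(amp, ph$truth$edj_vox)
  # ground-truth EDJ voxels all land on the target plane
  probe <- array(0, dim(amp))
  for (ix in 1:48) for (iy in 1:48) probe[ph$truth$edj_vox[ix, iy], ix, iy] <- 1
  flp <- flatten_volume(probe, ph$truth$edj_vox)
  plane <- apply(flp$data, 1, sum)
  expect_equal(plane[fl$target], 48 * 48)
})

test_that("en-face equalization is a probability integral transform", {
  set.seed(12)
  sl <- matrix(rexp(64 * 64), 64, 64)
  eq <- enface_equalize(sl)
  expect_false(eq$flagged)
  v <- sort(eq$data)
  n <- length(v)
  # output ECDF uniform: KS statistic at most 2/sqrt(N)
  ks <- max(abs(v - (seq_len(n) - 0.5) / n))
  expect_lt(ks, 2 / sqrt(n))
  # rank order preserved
  expect_equal(order(eq$data), order(sl))
  # idempotent on continuous input
  eq2 <- enface_equalize(eq$data)
  expect_equal(eq2$data, eq$data)

  # strictly increasing ramp stays strictly increasing
  ramp <- matrix(seq_len(20), 4, 5)
  eqr <- enface_equalize(ramp)
  expect_true(all(diff(as.vector(eqr$data)) > 0))

  # constant slice: 0.5, flagged
  eqc <- enface_equalize(matrix(3, 4, 4))
  expect_true(eqc$flagged)
  expect_true(all(eqc$data == 0.5))
})

test_that("sMIP reduces to min, mean and the hand-sorted average", {
  # hand example: column [5, 1, 3, 2], k = 2 -> (1 + 2) / 2
  flat <- list(data = array(c(5, 1, 3, 2), c(4, 1, 1)),
               valid = array(TRUE, c(4, 1, 1)), target = 1L)
  class(flat) <- "flat_volume"
  m <- smip(flat, c(0, 32), axial_pitch_um = 8, k = 2, equalize = FALSE)
  expect_equal(m$data[1, 1], 1.5)

  set.seed(14)
  for (i in 1:25) {
    nz <- sample(4:12, 1)
    vol <- array(runif(nz * 5 * 4), c(nz, 5, 4))
    fl <- list(data = vol, valid = array(TRUE, dim(vol)), target = 1L)
    class(fl) <- "flat_volume"
    slab <- c(0, nz * 8)
    m1 <- smip(fl, slab, 8, k = 1, equalize = FALSE)
    expect_identical(m1$data, apply(vol, c(2, 3), min))
    mk <- smip(fl, slab, 8, k = nz, equalize = FALSE)
    expect_identical(mk$data, apply(vol, c(2, 3), mean))
    # monotone nondecreasing in k per column
    ks <- seq_len(nz)
    vals <- vapply(ks, function(k)
      smip(fl, slab, 8, k = k, equalize = FALSE)$data[3, 2], 0)
    expect_true(all(diff(vals) >= 0))
  }
  expect_error(smip(flat, c(0, 32), 8, k = 9), "out of range")
  expect_error(smip(flat, c(0, 32), 8, k = 0), "out of range")
})

test_that("lymph mask extraction finds a dark tube and filters specks", {
  # constant map -> empty mask with a warning
  expect_warning(m0 <- extract_lymph_mask(matrix(1, 16, 16)), "constant")
  expect_false(any(m0$mask))

  # dark band in bright speckle-like background
  set.seed(15)
  img <- matrix(runif(64 * 64, 0.2, 0.4), 64, 64)
  img[, 30:36] <- runif(64 * 7, 0.001, 0.02)
  m <- extract_lymph_mask(img)
  truthband <- matrix(FALSE, 64, 64); truthband[, 30:36] <- TRUE
  expect_gt(dice(m$mask, truthband), 0.95)

  # isolated specks below min_size are removed
  img2 <- matrix(0.3, 64, 64)
  img2[, 10:16] <- 0.01          # real vessel, 7 * 64 px
  img2[40, 50] <- 0.01           # 2-px speck
  img2[41, 50] <- 0.01
  m2 <- extract_lymph_mask(img2, min_size = 10)
  expect_false(any(m2$mask[40:41, 50]))
  expect_true(all(m2$mask[, 10:16]))

  # elongation filter drops a compact blob but keeps the elongated vessel
  img3 <- matrix(0.3, 64, 64)
  img3[, 10:13] <- 0.01
  blob <- expand.grid(r = 28:38, c = 40:50)
  img3[as.matrix(blob)] <- 0.01
  m3 <- extract_lymph_mask(img3, elongation_filter = TRUE, elongation_ratio = 1.8)
  expect_true(all(m3$mask[, 10:13]))
  expect_false(any(m3$mask[28:38, 40:50]))
})

test_that("full OLAG chain recovers phantom lymph lumens slab by slab", {
  ph <- generate_phantom(small_spec(), seed = 7)
  amp <- structural_amplitude(ph$volume)
  comp <- compensate_attenuation(amp^2, n = 2)
  surf <- detect_surface(amp)
  edj <- segment_edj(comp, surf, axial_pitch_um = 8)
  flat <- flatten_volume(comp$data, edj$edj_vox)
  # the small phantom's lumen sits ~210 um below the EDJ (z = 460 um)
  mp <- smip(flat, c(100, 300), axial_pitch_um = 8)
  mk <- extract_lymph_mask(mp)
  gt <- gt_slab_projection(ph$truth, c(100, 300), 8)
  expect_gt(dice(mk$mask, gt), 0.7)
})
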