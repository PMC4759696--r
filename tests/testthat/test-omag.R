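speckle_frame <- function(nz, nx, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)) / sqrt(2),
         nz, nx)
}

test_that("registration recovers constructed and injected shifts exactly", {
  f1 <- speckle_frame(96, 48, seed = 2)
  # identical frames -> zero shifts
  reg0 <- register_repeats(list(f1, f1, f1))
  expect_identical(reg0$shifts, c(0L, 0L, 0L))

  # constructed: frame 2 = frame 1 pushed 3 voxels deeper -> aligning shift -3
  f2 <- f1; f2[] <- 0; f2[4:96, ] <- f1[1:93, ]
  reg <- register_repeats(list(f1, f2))
  expect_identical(reg$shifts[2], -3L)
  expect_equal(reg$frames[[2]][reg$valid_rows, ], f1[reg$valid_rows, ])

  # exhaustive-search oracle on a random shift
  set.seed(7)
  for (s in sample(-16:16, 5)) {
    fs <- f1; fs[] <- 0
    if (s >= 0) fs[(1 + s):96, ] <- f1[1:(96 - s), ] else fs[1:(96 + s), ] <- f1[(1 - s):96, ]
    reg <- register_repeats(list(f1, fs), max_shift = 24)
    expect_identical(reg$shifts[2], -as.integer(s))
  }
})

test_that("phantom-injected bulk shifts are recovered from the ground truth", {
  set.seed(31)
  shifts <- c(0L, sample(-8:8, 3, replace = TRUE))
  ph <- generate_phantom(small_spec(bulk_shifts_vox = shifts), seed = 17)
  frames <- lapply(1:4, function(r) ph$volume$data[, , r, 20])
  reg <- register_repeats(frames, max_shift = 16)
  expect_identical(reg$shifts, -shifts)
})

test_that("frames of unequal shape or too few repeats error", {
  f <- speckle_frame(10, 8)
  expect_error(register_repeats(list(f)), "2")
  expect_error(register_repeats(list(f, f[1:8, ])), "identical dimensions")
  expect_error(compute_flow(list(f)), "2 repeats")
  expect_warning(register_repeats(list(f, matrix(0 + 0i, 10, 8))), "all-zero")
})

test_that("flow is the mean absolute adjacent complex difference", {
  f <- speckle_frame(10, 8, seed = 3)
  # identical repeats -> zero flow
  expect_equal(compute_flow(list(f, f, f)), matrix(0, 10, 8))

  # alternating +a / -a at one voxel over R = 8 repeats -> flow = 2|a|
  a <- 0.7 + 0.3i
  frames <- lapply(1:8, function(r) {
    m <- matrix(0 + 0i, 4, 4)
    m[2, 3] <- if (r %% 2 == 1) a else -a
    m
  })
  fl <- compute_flow(frames)
  expect_equal(fl[2, 3], 2 * Mod(a))
  expect_equal(sum(fl) - fl[2, 3], 0)

  # amplitude-only mode: plain real differences
  r1 <- matrix(1, 3, 3); r2 <- matrix(2, 3, 3)
  expect_equal(compute_flow(list(r1, r2)), matrix(1, 3, 3))
})

test_that("static voxels under complex noise give mean flow sigma*sqrt(pi)", {
  # Monte-Carlo oracle: the difference of two CN(0, 2 sigma^2) noises is
  # Rayleigh with scale sigma*sqrt(2); its mean is sigma*sqrt(pi).
  sigma <- 0.05
  n <- 100 * 100
  set.seed(99)
  base <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), 100, 100)
  frames <- lapply(1:2, function(r)
    base + sigma * matrix(complex(real = rnorm(n), imaginary = rnorm(n)), 100, 100))
  fl <- compute_flow(frames)
  se <- sigma * sqrt(2) * sqrt((4 - pi) / 2) / sqrt(n)
  expect_equal(mean(fl), sigma * sqrt(pi), tolerance = 3 * se / (sigma * sqrt(pi)))
})

test_that("flow is invariant to a global phase rotation", {
  frames <- lapply(1:4, function(r) speckle_frame(20, 16, seed = r))
  fl1 <- compute_flow(frames)
  phi <- exp(1i * 1.234)
  fl2 <- compute_flow(lapply(frames, function(f) f * phi))
  expect_equal(fl1, fl2)
})

test_that("gaussian smoothing is normalized, local and sum-preserving", {
  vol <- array(0, c(4, 16, 16))
  vol[2, 8, 8] <- 1
  sm <- smooth_angiogram(vol)
  # impulse response: the 3x3 kernel replica, summing to 1
  expect_equal(sum(sm[2, , ]), 1, tolerance = 1e-12)
  expect_equal(sum(sm[2, 7:9, 7:9]), 1, tolerance = 1e-12)
  expect_gt(sm[2, 8, 8], sm[2, 7, 8])
  # constant volume unchanged
  cvol <- array(2.5, c(3, 8, 8))
  expect_equal(smooth_angiogram(cvol), cvol)
  # reflective borders preserve the total
  set.seed(4)
  rv <- array(runif(5 * 12 * 12), c(5, 12, 12))
  expect_equal(sum(smooth_angiogram(rv)), sum(rv), tolerance = 1e-6)
  expect_error(smooth_angiogram(rv, size = 4), "odd")
})

test_that("MIP en-face equals the brute-force maximum", {
  set.seed(5)
  vol <- array(runif(8 * 8 * 8), c(8, 8, 8))
  oracle <- apply(vol, c(2, 3), max)
  expect_equal(mip_enface(vol), oracle)

  # single nonzero voxel
  v1 <- array(0, c(8, 8, 8)); v1[5, 3, 6] <- 2
  m <- mip_enface(v1)
  expect_equal(m[3, 6], 2)
  expect_equal(sum(m), 2)

  # constant volume
  expect_equal(mip_enface(array(3, c(4, 4, 4))), matrix(3, 4, 4))

  # depth-range restriction and empty range errors
  expect_equal(mip_enface(v1, z_from = 6, z_to = 9), matrix(0, 8, 8))
  expect_error(mip_enface(vol, z_from = 5, z_to = 5), "empty")
})

test_that("depth-encoded MIP matches brute-force argmax with shallow ties", {
  set.seed(6)
  vol <- array(runif(8 * 8 * 8), c(8, 8, 8))
  dm <- depth_encoded_mip(vol)
  oracle_v <- apply(vol, c(2, 3), max)
  oracle_z <- apply(vol, c(2, 3), which.max)
  expect_equal(dm$value, oracle_v)
  expect_equal(dm$depth_vox, oracle_z)

  # distinct depths map to distinct depth values
  v2 <- array(0, c(128, 4, 4)); v2[10, 1, 1] <- 1; v2[100, 2, 1] <- 1
  d2 <- depth_encoded_mip(v2)
  expect_identical(d2$depth_vox[1, 1], 10L)
  expect_identical(d2$depth_vox[2, 1], 100L)

  # all-zero volume: depth 1 by tie-break, flagged
  d0 <- depth_encoded_mip(array(0, c(4, 3, 3)))
  expect_true(all(d0$depth_vox == 1L))
  expect_true(all(d0$flat))
})

test_that("a static noise-free phantom yields exactly zero flow and high blood contrast", {
  ph <- generate_phantom(small_spec(blood_tubes = list(), noise_sigma = 0),
                         seed = 23)
  ang <- omag_angiogram(ph$volume)
  expect_equal(max(ang$flow), 0)

  ph2 <- generate_phantom(small_spec(), seed = 23)
  ang2 <- omag_angiogram(ph2$volume)
  blood <- ph2$truth$blood_mask
  ratio <- mean(ang2$flow[blood]) / mean(ang2$flow[!blood])
  expect_gt(ratio, 10)
})
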