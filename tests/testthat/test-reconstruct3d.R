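test_that("linear intensity matching recovers exact gains and offsets", {
  set.seed(2)
  base <- matrix(runif(32 * 32, 50, 150), 32, 32)
  vol <- array(0, c(32, 32, 2))
  vol[, , 1] <- base
  vol[, , 2] <- 2 * base + 3
  out <- linear_intensity_match(vol, measured = c(TRUE, TRUE))
  fits <- attr(out, "fits")
  expect_equal(fits$gain[2], 2, tolerance = 1e-9)
  expect_equal(fits$offset[2], 3, tolerance = 1e-9)
  expect_equal(out[, , 2], base, tolerance = 1e-9)
  # the reference slice is unchanged: dynamic range preserved
  expect_identical(out[, , 1], base)
})

test_that("a drift-free channel fits gains near one", {
  set.seed(3)
  vol <- array(rep(matrix(runif(24 * 24, 10, 90), 24, 24), 5), c(24, 24, 5))
  vol <- vol + array(rnorm(length(vol), 0, 0.5), dim(vol))
  out <- linear_intensity_match(vol, measured = rep(TRUE, 5))
  fits <- attr(out, "fits")
  expect_true(all(abs(fits$gain - 1) < 0.01))
  expect_true(all(abs(fits$offset) < 1))
})

test_that("intensity matching removes the phantom's rostro-caudal drift", {
  spec <- tiny_spec()
  gt <- generate_label_volume(spec)
  prof <- list(means = c(60, 110, 170, 220), noise_sd = 1, background = 0)
  nz <- 10
  vol <- array(0, c(48, 48, nz))
  for (z in 1:nz)
    vol[, , z] <- render_section(gt$labels[, , z], gt$vessels[, , z], prof,
                                 "nissl", z - 1L, drift_rate = 0.5,
                                 noise_seed = z)$pixels
  mask <- array(gt$labels > 0, dim(gt$labels))
  jump <- function(v) {
    mean(sapply(2:nz, function(z) {
      ov <- mask[, , z] & mask[, , z - 1]
      abs(mean(v[, , z][ov]) - mean(v[, , z - 1][ov]))
    }))
  }
  before <- jump(vol)
  out <- linear_intensity_match(vol, rep(TRUE, nz), mask = mask)
  expect_gte(before / jump(out), 10)
})

test_that("NLM interpolation conserves constants and sums weights to one", {
  d <- c(16, 16, 7)
  vol <- array(5, d)
  guide <- array(rnorm(prod(d)), d)
  measured <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  out <- nlm_interpolate(vol, guide, measured)
  # weights are normalized, so a constant channel stays exactly constant
  expect_equal(array(out, d), array(5, d), tolerance = 1e-9)
  expect_equal(attr(out, "provenance"),
               rep(c("measured", "interpolated"), length.out = 7))
})

test_that("gaps beyond the search depth fall back to the nearest slice", {
  d <- c(8, 8, 11)
  vol <- array(0, d)
  vol[, , 1] <- 1; vol[, , 11] <- 2
  guide <- array(1, d)
  measured <- c(TRUE, rep(FALSE, 9), TRUE)
  out <- nlm_interpolate(vol, guide, measured, search_depth = 3)
  prov <- attr(out, "provenance")
  expect_equal(prov[6], "missing")
  expect_true(all(out[, , 6] %in% c(1, 2)))
})

test_that("guided NLM beats linear z-interpolation across a moving step edge", {
  # a step edge whose position advances with z, rendered in two contrasts
  d <- c(32, 32, 9)
  guide <- array(0, d); chan <- array(0, d)
  for (z in 1:9) {
    edge <- 8 + 2 * z
    guide[1:edge, , z] <- 100
    chan[1:edge, , z] <- 37
  }
  measured <- rep(TRUE, 9); measured[5] <- FALSE
  truth <- chan[, , 5]
  out <- nlm_interpolate(chan, guide, measured, patch_radius = 2,
                         search_depth = 2)
  linear <- (chan[, , 4] + chan[, , 6]) / 2
  mse_nlm <- mean((out[, , 5] - truth)^2)
  mse_lin <- mean((linear - truth)^2)
  expect_lt(mse_nlm, mse_lin)
})

test_that("assembly resamples once, matches intensity, and flags provenance", {
  ds <- tiny_dataset()
  st <- run_reconstruction(ds, registration_params(
    iterations_per_scale = c(8, 6, 4)), n_iterations = 1)
  mcv <- assemble_volume(st)
  expect_s3_class(mcv, "multi_contrast_volume")
  expect_true(all(c("blockface", "nissl", "bielschowsky") %in%
                  names(mcv$channels)))
  # provenance: nissl measured on even slices, interpolated on odd
  prov <- mcv$provenance["nissl", ]
  expect_equal(unname(prov[seq(1, 9, by = 2)]), rep("measured", 5))
  expect_equal(unname(prov[seq(2, 10, by = 2)]), rep("interpolated", 5))
  # voxels outside the blockface tissue take the background value
  bg <- ds$sections[[grep("nissl", names(ds$sections))[1]]]$section$pixels[1, 1]
  expect_equal(mcv$channels$nissl$voxels[1, 1, 1], bg)
})

test_that("assembling an undistorted phantom reproduces the rendered truth", {
  spec <- phantom_spec(grid_shape = c(48, 48, 8), vessel_count = 0,
                       distortion_amplitude = 0, affine_jitter = NULL,
                       drift_rate = 0,
                       sampling_plan = list(nissl = list(interval = 1,
                                                         offset = 0)),
                       seed = 55)
  ds <- build_phantom_dataset(spec)
  st <- run_reconstruction(ds, registration_params(
    iterations_per_scale = c(5, 4, 3)), n_iterations = 1)
  mcv <- assemble_volume(st, intensity_match = FALSE)
  rng <- diff(range(ds$sections[["s002_nissl"]]$undistorted$pixels))
  for (z in 1:8) {
    truth <- ds$sections[[sprintf("s%03d_nissl", z - 1)]]$undistorted$pixels
    got <- mcv$channels$nissl$voxels[, , z]
    inside <- ds$labels[, , z] > 0
    expect_lt(mean(abs(got - truth)[inside]), 0.02 * rng)
  }
})
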