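stripes <- function(angle_deg, n = 96, period = 8) {
  g <- expand.grid(x = 1:n, y = 1:n)
  th <- angle_deg * pi / 180
  # stripes RUNNING along direction th: intensity varies perpendicular to th
  phase <- (-sin(th) * g$x + cos(th) * g$y) * 2 * pi / period
  matrix(100 + 50 * sin(phase), n, n)
}

test_that("structure tensor recovers stripe orientation and anisotropy", {
  img <- stripes(30)
  om <- structure_tensor(img, sigma_grad = 1, sigma_window = 3)
  inner <- om$orientation[20:76, 20:76]
  modal <- median(inner, na.rm = TRUE)
  expect_lt(min(abs(modal - 30), abs(modal - 210), abs(modal + 150)), 2)
  expect_gt(median(om$anisotropy[20:76, 20:76], na.rm = TRUE), 0.9)
})

test_that("isotropic noise has low anisotropy", {
  img <- with_seed(19, matrix(rnorm(96 * 96), 96, 96))
  om <- structure_tensor(img, sigma_grad = 1, sigma_window = 5)
  expect_lt(median(om$anisotropy[om$defined]), 0.5)
  om8 <- structure_tensor(img, sigma_grad = 1, sigma_window = 8)
  expect_lt(median(om8$anisotropy[om8$defined]), 0.35)
})

test_that("rotating the image by 90 degrees rotates orientations by 90", {
  img <- stripes(30)
  om <- structure_tensor(img)
  rot <- t(img)[, ncol(img):1]  # 90-degree rotation
  omr <- structure_tensor(rot)
  a <- median(om$orientation[20:76, 20:76], na.rm = TRUE)
  b <- median(omr$orientation[20:76, 20:76], na.rm = TRUE)
  dd <- abs(((b - a) %% 180) - 90)
  expect_lt(min(dd, 180 - 90 - dd + 90), 2.5)
})

test_that("orientation and anisotropy are invariant to affine intensity rescaling", {
  img <- stripes(55)
  om1 <- structure_tensor(img)
  om2 <- structure_tensor(3.7 * img - 120)
  expect_equal(om1$orientation, om2$orientation, tolerance = 1e-6)
  expect_equal(om1$anisotropy, om2$anisotropy, tolerance = 1e-6)
})

test_that("tensor aggregation respects transforms", {
  ds <- tiny_dataset()
  st <- init_alignment(ds)
  # constant 45-degree stripes on every section, identity transforms
  maps <- list()
  for (k in names(st$sections)) {
    om <- structure_tensor(stripes(45, n = 48))
    maps[[k]] <- om
  }
  agg <- aggregate_to_blockface(maps, st)
  o <- agg$orientation$voxels[12:36, 12:36, ]  # away from frame effects
  vals <- o[!is.na(o)]
  expect_gt(length(vals), 1000)
  expect_lt(max(abs(vals - 45)), 2)

  # a pure 90-degree rotation transform reorients the aggregate
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  ctr <- c(24.5, 24.5)
  rotA <- cbind(R, ctr - R %*% ctr)
  for (k in names(st$sections))
    st$sections[[k]]$transform <- transform2d(c(48, 48), affine = rotA)
  agg2 <- aggregate_to_blockface(maps, st)
  v2 <- agg2$orientation$voxels
  v2 <- v2[!is.na(v2)]
  expect_lt(median(abs(((v2 - 135 + 90) %% 180) - 90)), 2.5)
})

test_that("vessel density traces the true tube and conserves mass", {
  # straight tube along z at a known in-plane position
  spec <- phantom_spec(grid_shape = c(48, 48, 10), vessel_count = 0,
                       distortion_amplitude = 0, affine_jitter = NULL,
                       sampling_plan = list(nissl = list(interval = 1,
                                                         offset = 0)),
                       seed = 71)
  ds <- build_phantom_dataset(spec)
  # inject a synthetic straight vessel into every section and its features
  st <- init_alignment(ds)
  g <- expand.grid(x = 1:48, y = 1:48)
  tube <- matrix((g$x - 20)^2 + (g$y - 30)^2 <= 4, 48, 48)
  for (k in names(st$sections)) {
    st$sections[[k]]$features$vessel_mask <- tube
  }
  dens <- vessel_density(st, smoothing_sigma = 400)
  expect_true(all(dens$voxels >= 0 & dens$voxels <= 1))
  raw <- attr(dens, "raw")
  for (z in 1:10) {
    peak <- which(dens$voxels[, , z] == max(dens$voxels[, , z]),
                  arr.ind = TRUE)[1, ]
    expect_lt(sqrt(sum((peak - c(20, 30))^2)), 1.5)
    # smoothing preserves the in-plane integral away from borders
    expect_equal(sum(dens$voxels[, , z]), sum(raw[, , z]), tolerance = 0.01)
  }

  # no vessels anywhere -> zero map with a warning
  for (k in names(st$sections))
    st$sections[[k]]$features$vessel_mask <- matrix(FALSE, 48, 48)
  expect_warning(d0 <- vessel_density(st), "no vessels")
  expect_true(all(d0$voxels == 0))
})
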