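test_that("mutual information matches the brute-force joint-histogram oracle", {
  # 4x4 two-level images with known joint counts
  a <- matrix(c(0, 0, 1, 1,  0, 0, 1, 1,  0, 1, 0, 1,  1, 1, 0, 0), 4, 4)
  b <- matrix(c(0, 1, 1, 0,  0, 0, 1, 1,  1, 1, 0, 0,  1, 0, 0, 1), 4, 4)
  # independent oracle: explicit joint histogram over 2 levels
  joint <- matrix(0, 2, 2)
  for (i in 1:16) joint[a[i] + 1, b[i] + 1] <- joint[a[i] + 1, b[i] + 1] + 1
  p <- joint / 16
  pa <- rowSums(p); pb <- colSums(p)
  oracle <- 0
  for (i in 1:2) for (j in 1:2)
    if (p[i, j] > 0) oracle <- oracle + p[i, j] * log2(p[i, j] / (pa[i] * pb[j]))
  expect_equal(mutual_information(a, b, bins = 2), oracle, tolerance = 1e-12)

  # 8x8 random two-level rasters
  set.seed(42)
  for (rep in 1:5) {
    a8 <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b8 <- matrix(rbinom(64, 1, 0.6), 8, 8)
    joint <- matrix(0, 2, 2)
    for (i in 1:64) joint[a8[i] + 1, b8[i] + 1] <- joint[a8[i] + 1, b8[i] + 1] + 1
    p <- joint / 64; pa <- rowSums(p); pb <- colSums(p)
    oracle <- sum(p[p > 0] * log2(p[p > 0] / outer(pa, pb)[p > 0]))
    expect_equal(mutual_information(a8, b8, bins = 2), oracle,
                 tolerance = 1e-12)
    expect_equal(mutual_information(a8, b8, bins = 2),
                 mutual_information(b8, a8, bins = 2), tolerance = 1e-12)
  }
})

test_that("MI of an image with itself is its own histogram entropy", {
  set.seed(7)
  a <- matrix(runif(64 * 64), 64, 64)
  bins <- 16
  h <- tabulate(pmin(bins, 1 + floor((a - min(a)) / diff(range(a)) * bins)),
                bins)
  p <- h / sum(h)
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mutual_information(a, a, bins), entropy, tolerance = 1e-12)
})

test_that("MI of independent noise vanishes and constants give zero", {
  set.seed(13)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  expect_lt(mutual_information(a, b, bins = 8), 0.05)
  expect_identical(mutual_information(matrix(1, 8, 8), a[1:8, 1:8]), 0)
  # support mask restricts the sample
  m <- matrix(FALSE, 64, 64); m[1:32, ] <- TRUE
  expect_equal(mutual_information(a, a, 8, support_mask = m),
               mutual_information(a[1:32, ], a[1:32, ], 8))
})

test_that("apply_transform handles identity, integer shifts, and inversion", {
  set.seed(5)
  img <- matrix(runif(40 * 40, 0, 100), 40, 40)
  tid <- transform2d(c(40, 40))
  expect_equal(apply_transform(img, tid), img)

  tsh <- transform2d(c(40, 40), affine = cbind(diag(2), c(3, -2)))
  out <- apply_transform(img, tsh, background = -1)
  expect_equal(out[1:37, 3:40], img[4:40, 1:38])

  # warp then numeric inverse returns close to the original (smooth image,
  # so the comparison probes the transform rather than interpolation of
  # pixel noise)
  pf <- pair_fixture()
  smooth_img <- smooth_gauss(pf$moving$pixels, 2)
  d <- distort_section(section_image(smooth_img, 200), 5, NULL, seed = 8)
  w <- d$section$pixels
  back <- apply_transform(w, invert_transform(d$transform),
                          background = w[1, 1])
  interior <- matrix(FALSE, 128, 128); interior[15:114, 15:114] <- TRUE
  rng <- diff(range(smooth_img))
  expect_lt(mean(abs(back - smooth_img)[interior]), 0.01 * rng)
})

test_that("compose_transform matches sequential application pointwise", {
  t1 <- transform2d(c(20, 20), affine = cbind(diag(2), c(2, 1)))
  tid <- transform2d(c(20, 20))
  c1 <- compose_transform(tid, t1)
  g <- expand.grid(x = 1:20, y = 1:20)
  m1 <- histostack:::tf_map(c1, g$x, g$y)
  m2 <- histostack:::tf_map(t1, g$x, g$y)
  expect_equal(m1$x, m2$x, tolerance = 1e-9)
  expect_equal(m1$y, m2$y, tolerance = 1e-9)

  t2 <- transform2d(c(20, 20), affine = cbind(diag(2), c(-1, 3)))
  cc <- compose_transform(t1, t2)
  mm <- histostack:::tf_map(cc, g$x, g$y)
  expect_equal(mm$x, g$x + 1, tolerance = 1e-9)
  expect_equal(mm$y, g$y + 4, tolerance = 1e-9)

  # smooth random pair: compose-then-apply equals sequential apply
  set.seed(3)
  f1 <- array(c(smooth_gauss(matrix(rnorm(400), 20, 20), 4),
                smooth_gauss(matrix(rnorm(400), 20, 20), 4)), c(20, 20, 2))
  ts <- transform2d(c(20, 20), field = f1 / max(abs(f1)) * 2)
  img <- matrix(runif(400), 20, 20)
  seq_app <- apply_transform(apply_transform(img, t1), ts)
  one_app <- apply_transform(img, compose_transform(ts, t1))
  # compare away from the border, where sequential application mixes in
  # out-of-domain background that single-pass composition does not see
  expect_equal(one_app[6:15, 6:15], seq_app[6:15, 6:15], tolerance = 0.05)

  expect_error(compose_transform(ts, transform2d(c(10, 10))), "grid mismatch")
})

test_that("registration requires a positively weighted target", {
  img <- matrix(runif(64), 8, 8)
  expect_error(register_pair(img, list(weighted_target(img, 0))),
               "positive weight")
})

test_that("registering an image to itself recovers the identity", {
  pf <- pair_fixture()
  tr <- register_pair(pf$fixed$pixels,
                      list(weighted_target(pf$fixed$pixels, 1)))
  expect_lt(mean_displacement(tr, pf$tissue), 0.1)
})

test_that("the metric trace never decreases across a level's iterations for the kept iterate", {
  pf <- pair_fixture()
  d <- distort_section(pf$moving, 6, NULL, seed = 4)
  tr <- register_pair(d$section$pixels,
                      list(weighted_target(pf$fixed$pixels, 1)),
                      registration_params(iterations_per_scale = 10))
  trace <- attr(tr, "trace")
  for (lv in unique(trace$level)) {
    sc <- trace$score[trace$level == lv]
    expect_gte(max(sc), sc[1] - 1e-9)
  }
  expect_true(is.finite(attr(tr, "score")))
})
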