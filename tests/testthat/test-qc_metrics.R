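test_that("boundary distance matches closed forms and the brute-force oracle", {
  mask <- matrix(FALSE, 32, 32); mask[8:24, 8:24] <- TRUE
  expect_equal(as.numeric(boundary_distance(mask, mask, 200)), 0)

  # concentric discs of radius r and r + dr: distance ~ dr
  g <- expand.grid(x = 1:64, y = 1:64)
  d2 <- matrix((g$x - 32.5)^2 + (g$y - 32.5)^2, 64, 64)
  a <- d2 <= 20^2
  b <- d2 <= 25^2
  bd <- as.numeric(boundary_distance(a, b, 1))
  expect_equal(bd, 5, tolerance = 0.25)

  # arbitrary masks vs an exhaustive nearest-point double loop
  set.seed(8)
  m1 <- matrix(FALSE, 64, 64); m1[10:40, 12:50] <- TRUE
  m2 <- matrix(FALSE, 64, 64); m2[14:46, 8:44] <- TRUE
  got <- as.numeric(boundary_distance(m1, m2, 1))
  contour_of <- function(m) {
    n <- nrow(m)
    er <- m
    er[2:n, ] <- er[2:n, ] & m[1:(n - 1), ]
    er[1:(n - 1), ] <- er[1:(n - 1), ] & m[2:n, ]
    er[, 2:n] <- er[, 2:n] & m[, 1:(n - 1)]
    er[, 1:(n - 1)] <- er[, 1:(n - 1)] & m[, 2:n]
    er[1, ] <- FALSE; er[n, ] <- FALSE; er[, 1] <- FALSE; er[, n] <- FALSE
    which(m & !er, arr.ind = TRUE)
  }
  ca <- contour_of(m1); cb <- contour_of(m2)
  da <- apply(ca, 1, function(p) sqrt(min((cb[, 1] - p[1])^2 +
                                          (cb[, 2] - p[2])^2)))
  db <- apply(cb, 1, function(p) sqrt(min((ca[, 1] - p[1])^2 +
                                          (ca[, 2] - p[2])^2)))
  expect_equal(got, (mean(da) + mean(db)) / 2, tolerance = 1e-9)

  expect_error(boundary_distance(matrix(FALSE, 8, 8), m1[1:8, 1:8]), "empty")
})

test_that("vessel matching is greedy mutual-nearest with a distance ceiling", {
  a <- data.frame(x = c(10, 20, 30), y = c(10, 20, 30))
  r <- vessel_distance(a, a, max_match = 1000, pixel_size = 200)
  expect_equal(r$distance, 0)
  expect_equal(r$n_matches, 3L)

  r0 <- vessel_distance(a, data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(r0$n_matches, 0L)
  expect_true(is.na(r0$distance))

  # known jitter: mean matched distance tracks the jitter scale
  set.seed(4)
  n <- 30
  base <- data.frame(x = runif(n, 10, 110), y = runif(n, 10, 110))
  jit <- base + matrix(rnorm(2 * n, 0, 1), n, 2)
  names(jit) <- c("x", "y")
  r1 <- vessel_distance(base, jit, max_match = 5 * 200, pixel_size = 200)
  expect_equal(r1$n_matches, n)
  # E|N2(0, I)| = sqrt(pi/2) ~ 1.25 px; accept [0.8, 1.8] x pixel size
  expect_gte(r1$distance, 0.8 * 200)
  expect_lte(r1$distance, 1.8 * 200)

  # ceiling excludes far pairs
  far <- data.frame(x = base$x + 100, y = base$y)
  rf <- vessel_distance(base, far, max_match = 1000, pixel_size = 200)
  expect_equal(rf$n_matches, 0L)
})

test_that("the QC profile reacts to induced misalignment monotonically", {
  ds <- tiny_dataset()
  st <- run_reconstruction(ds, registration_params(
    iterations_per_scale = c(8, 6, 4)), n_iterations = 1)
  qc0 <- qc_profile(st)
  expect_true(all(c("within", "across") %in% qc0$records$kind))
  base_mean <- mean(qc0$records$boundary_distance_um)

  # shift one slice by k pixels; its records grow by about k pixels
  key <- "s004_nissl"
  recorded <- c()
  for (k in c(2, 5, 10)) {
    st2 <- st
    tshift <- transform2d(st$dim, affine = cbind(diag(2), c(k, 0)))
    st2$sections[[key]]$transform <-
      compose_transform(tshift, st$sections[[key]]$transform)
    st2 <- histostack:::refresh_section(st2, key)
    qck <- qc_profile(st2)
    rec <- qck$records[qck$records$stain_a == "nissl" &
                       qck$records$slice_index %in% c(2, 4) &
                       qck$records$kind == "within", ]
    recorded <- c(recorded, mean(rec$boundary_distance_um))
  }
  expect_true(all(diff(recorded) > 0))
  expect_equal(recorded[3] - base_mean, 10 * 200, tolerance = 0.5 * 10 * 200)
})

test_that("missing structure is flagged by the distance threshold", {
  ds <- tiny_dataset()
  st <- run_reconstruction(ds, registration_params(
    iterations_per_scale = c(8, 6, 4)), n_iterations = 1)
  key <- "s006_nissl"
  s <- st$sections[[key]]
  # erase a large part of the tissue (mimicking lost cerebellar cortex)
  px <- s$resampled
  px[1:34, ] <- px[1, 1]  # lose most of the tissue, as with a torn section
  st$sections[[key]]$resampled <- px
  st$sections[[key]]$features <- section_features(
    section_image(px, st$pixel_size, s$stain, s$slice))
  # the desk-size grid only spans ~8 mm of tissue, so the flagging
  # mechanism is exercised at a proportionally lower threshold; the 2-mm
  # default is checked at full phantom scale in the acceptance suite
  qc <- qc_profile(st, flag_threshold = 800)
  flagged <- qc$flagged
  expect_true(any(flagged$slice_index %in% c(4, 6)))
})

test_that("the QC statistic is symmetric in slice order", {
  mask <- matrix(FALSE, 32, 32); mask[8:24, 8:24] <- TRUE
  mask2 <- matrix(FALSE, 32, 32); mask2[10:28, 6:22] <- TRUE
  expect_equal(as.numeric(boundary_distance(mask, mask2)),
               as.numeric(boundary_distance(mask2, mask)))
})
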