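test_that("label volume generation is deterministic and respects vessel count", {
  spec <- tiny_spec()
  a <- generate_label_volume(spec)
  b <- generate_label_volume(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$vessels, b$vessels)
  expect_true(all(a$labels %in% 0:spec$n_tissue_classes))
  expect_gte(length(unique(as.vector(a$labels[a$labels > 0]))), 2)
  # background surrounds the brain: the volume border is background
  expect_true(all(a$labels[1, , ] == 0))
  expect_true(all(a$labels[, 1, ] == 0))

  none <- phantom_spec(grid_shape = c(48, 48, 10), vessel_count = 0,
                       seed = 5)
  expect_true(all(!generate_label_volume(none)$vessels))
})

test_that("vessel tubes are non-intersecting: 26-connected components equal the count", {
  spec <- phantom_spec(grid_shape = c(64, 64, 12), vessel_count = 5,
                       vessel_radius_range = c(2, 4), seed = 9)
  gt <- generate_label_volume(spec)
  expect_equal(count_components_26(gt$vessels), 5)
})

test_that("grid too small for vessels fails with a clear message", {
  spec <- phantom_spec(grid_shape = c(32, 32, 8), vessel_count = 3,
                       vessel_radius_range = c(4, 8), seed = 1)
  expect_error(generate_label_volume(spec), "too small")
})

test_that("rendering is an exact class lookup without noise and drift", {
  spec <- tiny_spec()
  gt <- generate_label_volume(spec)
  prof <- list(means = c(10, 20, 30, 40), noise_sd = 0, background = -5)
  s <- render_section(gt$labels[, , 3], gt$vessels[, , 3], prof,
                      "nissl", 2L, 0, 1L)
  lab <- gt$labels[, , 3]
  ves <- gt$vessels[, , 3]
  tissue <- lab > 0 & !ves
  expect_equal(s$pixels[tissue], prof$means[lab[tissue]])
  expect_true(all(s$pixels[!tissue] == -5))
})

test_that("drift is linear in slice index over tissue", {
  spec <- tiny_spec()
  gt <- generate_label_volume(spec)
  prof <- list(means = c(10, 20, 30, 40), noise_sd = 0, background = 0)
  lab <- gt$labels[, , 5]; ves <- gt$vessels[, , 5]
  s0 <- render_section(lab, ves, prof, "nissl", 0L, 0.5, 1L)
  s10 <- render_section(lab, ves, prof, "nissl", 10L, 0.5, 1L)
  tissue <- lab > 0 & !ves
  expect_equal(mean(s10$pixels[tissue] - s0$pixels[tissue]), 5.0,
               tolerance = 1e-12)
})

test_that("rendering noise has the requested standard deviation", {
  lab <- matrix(1L, 120, 120)
  ves <- matrix(FALSE, 120, 120)
  prof <- list(means = c(100), noise_sd = 2, background = 0)
  s <- render_section(lab, ves, prof, "nissl", 0L, 0, 77L)
  expect_equal(sd(s$pixels), 2, tolerance = 0.2)  # >= 1e4 pixels, 10%
})

test_that("a class missing from the profile is an explicit failure", {
  lab <- matrix(c(1L, 5L), 4, 4)
  prof <- list(means = c(10, 20), noise_sd = 0, background = 0)
  expect_error(render_section(lab, lab * 0, prof), "missing from")
})

test_that("distortion honours amplitude, determinism, and invertibility", {
  pf <- pair_fixture()
  sec <- pf$moving
  # amplitude 0, no jitter: identity
  d0 <- distort_section(sec, 0, NULL, seed = 2)
  expect_equal(d0$section$pixels, sec$pixels)
  expect_null(d0$transform$field)
  # amplitude 10: mean |displacement| in [9, 11]
  d10 <- distort_section(sec, 10, NULL, seed = 2)
  mag <- sqrt(d10$transform$field[, , 1]^2 + d10$transform$field[, , 2]^2)
  expect_gte(mean(mag), 9)
  expect_lte(mean(mag), 11)
  # determinism
  d10b <- distort_section(sec, 10, NULL, seed = 2)
  expect_identical(d10$section$pixels, d10b$section$pixels)
  # invertibility: numeric inverse composes to near identity
  inv <- invert_transform(d10$transform)
  comp <- compose_transform(d10$transform, inv)
  interior <- matrix(FALSE, 128, 128); interior[20:108, 20:108] <- TRUE
  expect_lt(mean_displacement(comp, interior), 0.1)
})

test_that("warped section equals applying the returned transform to the original", {
  pf <- pair_fixture()
  d <- distort_section(pf$moving, 6, list(max_rotation_deg = 1.5,
                                          max_translation_px = 2), seed = 4)
  redo <- apply_transform(pf$moving$pixels, d$transform,
                          background = pf$moving$pixels[1, 1])
  expect_equal(redo, d$section$pixels)
})

test_that("dataset assembly follows the sampling plan and damage list", {
  spec <- phantom_spec(grid_shape = c(48, 48, 30), vessel_count = 0,
                       sampling_plan = list(nissl = list(interval = 3,
                                                         offset = 0)),
                       damaged_slices = integer(0), seed = 21)
  ds <- build_phantom_dataset(spec)
  expect_length(ds$blockface, 30)
  expect_length(ds$sections, 10)  # "1:3" over 30 slices

  spec2 <- tiny_spec()
  spec2$damaged_slices <- 4L
  ds2 <- build_phantom_dataset(spec2)
  keys <- names(ds2$sections)
  expect_false(any(grepl("^s004_", keys)))
  expect_length(ds2$blockface, 10)  # blockface keeps the damaged slice

  # string intervals parse like the printed sampling notation
  expect_equal(sampled_slices(list(interval = "1:6", offset = 1), 30),
               seq(1, 29, by = 6))
})

test_that("default sampling plan covers every slice with at least one stain", {
  plan <- default_sampling_plan()
  nz <- 60
  covered <- logical(nz)
  for (st in names(plan))
    covered[sampled_slices(plan[[st]], nz) + 1] <- TRUE
  expect_true(all(covered))
})

test_that("dataset generation is bit-reproducible under a fixed seed", {
  a <- build_phantom_dataset(tiny_spec())
  b <- build_phantom_dataset(tiny_spec())
  expect_identical(a$labels, b$labels)
  k <- names(a$sections)[5]
  expect_identical(a$sections[[k]]$section$pixels,
                   b$sections[[k]]$section$pixels)
  expect_identical(a$sections[[k]]$true_transform$field,
                   b$sections[[k]]$true_transform$field)
})

test_that("phantom writes to disk as plain formats with a manifest", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_phantom(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "truth", "labels.nii.gz")))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$seed, ds$spec$seed)
  lab <- read_volume(file.path(dir, "truth", "labels.nii.gz"))
  expect_equal(array(as.numeric(ds$labels), dim(ds$labels)), lab$voxels)
})
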