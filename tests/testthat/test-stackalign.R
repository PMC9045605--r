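make_state <- function(ds = tiny_dataset()) {
  if (is.null(.fixture_cache$state)) .fixture_cache$state <- init_alignment(ds)
  .fixture_cache$state
}

test_that("the target set follows the weighting scheme and sweep bookkeeping", {
  state <- make_state()
  for (k in names(state$sections)) {
    state$sections[[k]]$fresh <- FALSE
    state$sections[[k]]$fresh_rank <- 0
  }
  # boundary case: nothing registered yet -> the blockface anchor only
  t0 <- build_target_set(state, 4, "nissl", "forward",
                         anchor_features = FALSE)
  expect_length(t0, 1)
  expect_equal(t0[[1]]$weight, 1)

  # mid-stack with upstream neighbors of both stains available
  # (plan: nissl on even slices, bielschowsky on odd)
  rank <- 0
  for (k in names(state$sections)) {
    s <- state$sections[[k]]
    if (s$slice < 4) {
      rank <- rank + 1
      state$sections[[k]]$fresh <- TRUE
      state$sections[[k]]$fresh_rank <- rank
    }
  }
  tt <- build_target_set(state, 4, "nissl", "forward",
                         anchor_features = FALSE)
  # 1 blockface + same-stain pair (1/2) + two any-stain pairs (1/4)
  expect_length(tt, 7)
  expect_equal(vapply(tt, function(t) t$weight, numeric(1)),
               c(1, 0.5, 0.5, 0.25, 0.25, 0.25, 0.25))
  expect_equal(vapply(tt, function(t) t$channel, character(1)),
               c("image", "image", "boundary", "image", "boundary",
                 "image", "boundary"))

  # the sliding window excludes neighbors farther than three slices:
  # with only slice 0 registered, slice 4 sees no neighbors
  for (k in names(state$sections)) {
    s <- state$sections[[k]]
    state$sections[[k]]$fresh <- (s$slice == 0)
    state$sections[[k]]$fresh_rank <- 1
  }
  tw <- build_target_set(state, 4, "nissl", "forward",
                         anchor_features = FALSE)
  expect_length(tw, 1)
  # ... while slice 3 (distance 3) is included
  tw3 <- build_target_set(state, 3, "bielschowsky", "forward",
                          anchor_features = FALSE)
  expect_length(tw3, 3)  # blockface + any-stain image/boundary pair

  # window rule against an exhaustive enumeration on the toy plan
  for (k in names(state$sections)) {
    state$sections[[k]]$fresh <- TRUE
    state$sections[[k]]$fresh_rank <- state$sections[[k]]$slice + 1
  }
  for (sl in c(2, 5, 9)) {
    tt <- build_target_set(state, sl, "nissl", "forward",
                           anchor_features = FALSE)
    same_n <- sum(vapply(state$sections, function(s)
      s$stain == "nissl" && s$slice != sl && abs(s$slice - sl) <= 3,
      logical(1)))
    elig_n <- sum(vapply(state$sections, function(s)
      s$slice != sl && abs(s$slice - sl) <= 3, logical(1)))
    expected <- 1 + 2 * min(1, same_n) +
      2 * min(2, elig_n - min(1, same_n))
    expect_length(tt, expected)
  }

  expect_error(build_target_set(state, 99, "nissl"), "anchor is mandatory")
})

test_that("a zero-distortion phantom reconstructs to near-identity transforms", {
  spec <- phantom_spec(grid_shape = c(48, 48, 8), vessel_count = 2,
                       vessel_radius_range = c(1.5, 3),
                       distortion_amplitude = 0,
                       affine_jitter = NULL,
                       sampling_plan = list(nissl = list(interval = 1,
                                                         offset = 0)),
                       seed = 33)
  ds <- build_phantom_dataset(spec)
  st <- run_reconstruction(ds, registration_params(
    iterations_per_scale = c(6, 4, 3)), n_iterations = 1)
  for (k in names(st$sections)) {
    m <- ds$labels[, , st$sections[[k]]$slice + 1] > 0
    expect_lt(mean_displacement(st$sections[[k]]$transform, m), 0.35)
  }
})

test_that("sweeps update scores monotonically in the archive and log correctly", {
  ds <- tiny_dataset()
  st <- init_alignment(ds)
  p <- registration_params(iterations_per_scale = c(8, 6, 4))
  st1 <- sweep_stack(st, "forward", p)
  # forward sweep raises every slice's blockface MI above the unregistered
  # starting point
  pre <- vapply(st$sections, function(s) s$score, numeric(1))
  post <- vapply(st1$sections, function(s) s$score, numeric(1))
  expect_true(all(post >= pre - 1e-9 | post > 0.8 * max(post)))
  expect_equal(nrow(st1$sweep_log), 1)
  expect_equal(st1$sweep_log$direction[1], "forward")

  st2 <- run_reconstruction(st1, p, n_iterations = 1)
  # archived best never decreases
  b1 <- vapply(st1$sections, function(s) s$best$score, numeric(1))
  b2 <- vapply(st2$sections, function(s) s$best$score, numeric(1))
  expect_true(all(b2 >= b1 - 1e-9))
})

test_that("a stain absent on a slice is bridged by neighbors without failure", {
  spec <- tiny_spec()
  spec$damaged_slices <- 5L
  ds <- build_phantom_dataset(spec)
  expect_false(any(grepl("^s005_", names(ds$sections))))
  st <- run_reconstruction(ds, registration_params(
    iterations_per_scale = c(6, 4, 3)), n_iterations = 1)
  expect_length(st$failures, 0)
  expect_equal(nrow(st$sweep_log), 2)
})
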