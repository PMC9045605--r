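# Shared fixtures: small phantoms built in code and memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 10), vessel_count = 3,
               vessel_radius_range = c(1.5, 3),
               distortion_amplitude = 4, distortion_smoothness = 12,
               affine_jitter = list(max_rotation_deg = 1,
                                    max_translation_px = 2),
               sampling_plan = list(nissl = list(interval = 2, offset = 0),
                                    bielschowsky = list(interval = 2,
                                                        offset = 1)),
               seed = 101L, ...)
}

tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- build_phantom_dataset(tiny_spec())
  }
  .fixture_cache$tiny
}

# mid-size single-slice pair for registration tests
pair_fixture <- function() {
  if (is.null(.fixture_cache$pair)) {
    spec <- phantom_spec(grid_shape = c(128, 128, 8), vessel_count = 4,
                         seed = 3)
    gt <- generate_label_volume(spec)
    prof <- default_stain_profiles(4)
    z <- 4
    fixed <- render_section(gt$labels[, , z], gt$vessels[, , z],
                            prof$blockface, "blockface", z - 1L, 0, 11)
    moving <- render_section(gt$labels[, , z], gt$vessels[, , z],
                             prof$nissl, "nissl", z - 1L, 0, 12)
    .fixture_cache$pair <- list(fixed = fixed, moving = moving,
                                tissue = gt$labels[, , z] > 0)
  }
  .fixture_cache$pair
}

# independent 3D 26-connected component count (flood fill), used as the
# oracle for vessel tube counting
count_components_26 <- function(vol) {
  vol <- vol > 0
  d <- dim(vol)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(vol & lab == 0L)
  while (length(idx_all) > 0) {
    nxt <- nxt + 1L
    queue <- idx_all[1]
    lab[queue] <- nxt
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      z <- (i - 1L) %/% (d[1] * d[2]) + 1L
      r <- (i - 1L) %% (d[1] * d[2])
      y <- r %/% d[1] + 1L
      x <- r %% d[1] + 1L
      nb <- cbind(x + offs[, 1], y + offs[, 2], z + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- ni[vol[ni] & lab[ni] == 0L]
      lab[new] <- nxt
      queue <- c(queue, new)
    }
    idx_all <- which(vol & lab == 0L)
  }
  nxt
}
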