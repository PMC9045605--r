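# Assemble registered sections into multi-contrast 3D volumes: chained
# linear interslice intensity matching and guided nonlocal-means
# interpolation of per-stain sampling gaps.

#' Chained linear interslice intensity matching
#'
#' Each measured slice is fitted against its already-matched predecessor by
#' least squares over the overlapping tissue voxels
#' (`slice = gain * predecessor + offset`) and corrected by the inverse map,
#' chained rostral -> caudal with the first measured slice as the unchanged
#' reference, so the channel's original dynamic range is preserved. Linear
#' (not histogram) matching deliberately accepts a residual small drift
#' rather than distorting the staining intensities nonlinearly.
#'
#' @param vol 3D array or `volume3d` (one stain channel on the common grid).
#' @param measured logical vector per slice: which slices carry measured
#'   data.
#' @param mask optional 3D logical tissue mask; correction is estimated and
#'   applied on tissue voxels only.
#' @param min_pixels slices whose overlap has fewer tissue voxels are passed
#'   through unmatched.
#' @return corrected array (or `volume3d`), with attribute `fits`: a
#'   data.frame of per-slice `gain` and `offset` (the fitted forward map).
#' @export
linear_intensity_match <- function(vol, measured, mask = NULL,
                                   min_pixels = 100) {
  isvol <- inherits(vol, "volume3d")
  a <- if (isvol) vol$voxels else vol
  d <- dim(a)
  stopifnot(length(measured) == d[3])
  mz <- which(measured)
  if (length(mz) < 2) stop("linear_intensity_match: need >= 2 measured slices")
  if (is.null(mask)) mask <- array(TRUE, d)
  fits <- data.frame(slice = mz, gain = 1, offset = 0)
  ref <- mz[1]
  prev <- ref
  for (i in seq_along(mz)[-1]) {
    z <- mz[i]
    ov <- mask[, , z] & mask[, , prev]
    if (sum(ov) < min_pixels) {
      hs_log("linear_intensity_match: slice ", z - 1L,
             " has too little tissue overlap; passed through")
      prev <- z
      next
    }
    y <- a[, , z][ov]; x <- a[, , prev][ov]
    if (stats::var(x) < 1e-12 || stats::var(y) < 1e-12) { prev <- z; next }
    fit <- stats::lm.fit(cbind(y, 1), x)  # predecessor ~ current
    g_inv <- fit$coefficients[1]; o_inv <- fit$coefficients[2]
    # forward map current = gain * predecessor + offset
    fits$gain[i] <- 1 / g_inv
    fits$offset[i] <- -o_inv / g_inv
    sl <- a[, , z]
    sl[mask[, , z]] <- g_inv * sl[mask[, , z]] + o_inv
    a[, , z] <- sl
    prev <- z
  }
  out <- if (isvol) { vol$voxels <- a; vol } else a
  attr(out, "fits") <- fits
  out
}

# mean-over-patch filter (separable box) used for NLM patch distances
box_mean <- function(m, radius) {
  if (radius <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  K <- function(n) {
    B <- matrix(0, n, n)
    for (o in -radius:radius) {
      i <- seq_len(n); j <- i + o
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- 1
    }
    B / rowSums(B)
  }
  K(n1) %*% m %*% t(K(n2))
}

#' Guided nonlocal-means interpolation of missing slices
#'
#' Every pixel of a missing slice is a weight-normalized average of the same
#' pixel in measured slices of the channel within `search_depth`; the
#' weights are `wz * exp(-D / h^2)` where `D` is the mean squared
#' difference between the guide-volume patches (radius `patch_radius`)
#' around the missing and the measured location, and `wz` is a triangular
#' slice-distance prior. The guide is typically the blockface volume
#' (optionally augmented with other coaligned channels), so contrast is
#' inferred across stains from shared geometry; where the guide is
#' uninformative the distance prior makes the estimate fall back to
#' ordinary linear-in-z interpolation.
#'
#' @param vol 3D array or `volume3d` with measured slices filled.
#' @param guide 3D array or `volume3d` on the same grid, complete along z.
#' @param measured logical vector per slice.
#' @param patch_radius in-plane patch radius in pixels (default 2).
#' @param search_depth slices searched on each side (default 3).
#' @param h weight bandwidth in guide-intensity units; default
#'   `0.4 * range(guide)` (phantom-tuned).
#' @return interpolated array (or `volume3d`) with attribute `provenance`, a
#'   character vector per slice: `"measured"`, `"interpolated"`, or
#'   `"missing"` (gap wider than the search; filled from the nearest
#'   measured slice).
#' @export
nlm_interpolate <- function(vol, guide, measured, patch_radius = 2,
                            search_depth = 3, h = NULL) {
  isvol <- inherits(vol, "volume3d")
  a <- if (isvol) vol$voxels else vol
  g <- if (inherits(guide, "volume3d")) guide$voxels else guide
  d <- dim(a)
  stopifnot(all(dim(g) == d), length(measured) == d[3])
  if (is.null(h)) h <- 0.4 * diff(range(g))
  mz <- which(measured)
  stopifnot(length(mz) >= 1)
  provenance <- ifelse(measured, "measured", "interpolated")
  for (z in which(!measured)) {
    cand <- mz[abs(mz - z) <= search_depth]
    if (length(cand) == 0) {
      near <- mz[which.min(abs(mz - z))]
      a[, , z] <- a[, , near]
      provenance[z] <- "missing"
      hs_log("nlm_interpolate: slice ", z - 1L, " beyond search depth; ",
             "copied nearest measured slice")
      next
    }
    gz <- g[, , z]
    # patch distances per candidate, then per-pixel min-normalization: in
    # regions where the guide does not discriminate the weights become the
    # symmetric distance prior (plain linear-in-z interpolation); where it
    # does, the best-matching slice dominates
    Ds <- lapply(cand, function(zc)
      box_mean((gz - g[, , zc])^2, patch_radius))
    Dmin <- Reduce(pmin, Ds)
    wsum <- matrix(0, d[1], d[2])
    acc <- matrix(0, d[1], d[2])
    for (i in seq_along(cand)) {
      wz <- 1 - abs(cand[i] - z) / (search_depth + 1)
      w <- wz * exp(-(Ds[[i]] - Dmin) / h^2)
      wsum <- wsum + w
      acc <- acc + w * a[, , cand[i]]
    }
    a[, , z] <- acc / wsum
  }
  out <- if (isvol) { vol$voxels <- a; vol } else a
  attr(out, "provenance") <- provenance
  out
}

#' Assemble registered sections into a multi-contrast volume
#'
#' Per stain: each measured section is resampled exactly once onto the
#' blockface grid through its final composed transform, slices are
#' intensity-matched along the chain, per-stain gaps are filled by guided
#' nonlocal means with the blockface volume as guide, and voxels outside the
#' blockface tissue mask are set to the channel background.
#'
#' @param state completed `alignment_state` from [run_reconstruction()].
#' @param patch_radius,search_depth,h passed to [nlm_interpolate()].
#' @param intensity_match run [linear_intensity_match()] per channel.
#' @return object of class `multi_contrast_volume`: `channels` (named list
#'   of `volume3d`, one per stain, plus `blockface`), `provenance` (matrix
#'   stain x slice of `"measured"/"interpolated"/"missing"`).
#' @export
assemble_volume <- function(state, patch_radius = 2, search_depth = 3,
                            h = NULL, intensity_match = TRUE) {
  stopifnot(inherits(state, "alignment_state"))
  d <- state$dim
  nz_ids <- sort(as.integer(names(state$blockface)))
  nz <- length(nz_ids)
  bf <- array(0, c(d, nz))
  for (i in seq_len(nz))
    bf[, , i] <- state$blockface[[as.character(nz_ids[i])]]$pixels
  bf_mask <- array(FALSE, c(d, nz))
  for (i in seq_len(nz)) {
    m <- try(mask_background_2d(bf[, , i]), silent = TRUE)
    if (!inherits(m, "try-error")) bf_mask[, , i] <- m$mask | m$holes
  }
  stains <- unique(vapply(state$sections, function(s) s$stain, character(1)))
  vs <- rep(state$pixel_size, 3)
  channels <- list(blockface = volume3d(bf, vs))
  provenance <- matrix("interpolated", length(stains), nz,
                       dimnames = list(stains, as.character(nz_ids)))
  for (st in stains) {
    keys <- names(state$sections)[vapply(state$sections,
                                         function(s) s$stain == st,
                                         logical(1))]
    ch <- array(0, c(d, nz))
    measured <- logical(nz)
    bgv <- state$sections[[keys[1]]]$original$pixels[1, 1]
    ch[] <- bgv
    for (k in keys) {
      s <- state$sections[[k]]
      i <- match(s$slice, nz_ids)
      ch[, , i] <- s$resampled
      measured[i] <- TRUE
    }
    if (intensity_match && sum(measured) >= 2)
      ch <- linear_intensity_match(ch, measured, mask = bf_mask)
    fits <- attr(ch, "fits")
    ch <- nlm_interpolate(ch, bf, measured, patch_radius, search_depth, h)
    provenance[st, ] <- attr(ch, "provenance")
    ch[!bf_mask] <- bgv
    v <- volume3d(ch, vs)
    attr(v, "fits") <- fits
    channels[[st]] <- v
  }
  structure(list(channels = channels, provenance = provenance,
                 voxel_size = vs),
            class = "multi_contrast_volume")
}

#' @export
print.multi_contrast_volume <- function(x, ...) {
  cat("multi_contrast_volume:", paste(names(x$channels), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a multi-contrast volume: one NIfTI per channel + report JSON
#' @param mcv `multi_contrast_volume`.
#' @param dir output directory.
#' @export
write_multi_contrast <- function(mcv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(mcv$channels))
    write_volume(mcv$channels[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  jsonlite::write_json(
    list(channels = names(mcv$channels),
         provenance = as.data.frame(t(mcv$provenance))),
    file.path(dir, "assembly.json"), auto_unbox = TRUE)
  invisible(dir)
}
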