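# Microstructure maps from the fine-scale sections: structure-tensor
# orientation/anisotropy and 3D vessel density, aggregated onto the
# blockface grid.

#' Structure-tensor orientation and anisotropy of a section
#'
#' The tensor is the Gaussian(`sigma_window`)-smoothed outer product of
#' Gaussian-derivative(`sigma_grad`) gradients. Orientation is the angle of
#' the structure (minor-eigenvalue) eigenvector modulo 180 degrees — the
#' direction ALONG oriented texture such as fiber bundles; anisotropy is
#' `1 - lambda2/lambda1`. Pixels with negligible gradient energy (relative
#' threshold) are flagged undefined. Both outputs are invariant to affine
#' rescaling of the input intensities.
#'
#' @param section `section_image` or matrix.
#' @param sigma_grad gradient (derivative) scale in pixels.
#' @param sigma_window tensor integration scale in pixels.
#' @param energy_rel relative `lambda1` threshold below which orientation is
#'   undefined.
#' @return object of class `orientation_map`:
#'   `list(orientation, anisotropy, defined, tensor)`; orientation in
#'   degrees `[0, 180)`, `NA` where undefined; `tensor` is the `[x, y, 3]`
#'   array of (Jxx, Jxy, Jyy).
#' @export
structure_tensor <- function(section, sigma_grad = 1, sigma_window = 3,
                             energy_rel = 1e-3) {
  px <- if (inherits(section, "section_image")) section$pixels else section
  sm <- smooth_gauss(px, sigma_grad)
  g <- image_gradient(sm)
  Jxx <- smooth_gauss(g[, , 1]^2, sigma_window)
  Jxy <- smooth_gauss(g[, , 1] * g[, , 2], sigma_window)
  Jyy <- smooth_gauss(g[, , 2]^2, sigma_window)
  tr <- Jxx + Jyy
  dd <- sqrt(pmax(0, (Jxx - Jyy)^2 / 4 + Jxy^2))
  l1 <- tr / 2 + dd
  l2 <- tr / 2 - dd
  defined <- l1 > energy_rel * max(l1)
  # gradient-dominant direction, then +90 deg for the structure direction
  phi_g <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)
  orientation <- (phi_g * 180 / pi + 90) %% 180
  orientation[!defined] <- NA_real_
  anis <- ifelse(l1 > 0, 1 - l2 / pmax(l1, .Machine$double.eps), 0)
  anis[!defined] <- 0
  structure(list(orientation = orientation, anisotropy = anis,
                 defined = defined,
                 tensor = array(c(Jxx, Jxy, Jyy), c(dim(px), 3))),
            class = "orientation_map")
}

# unit structure tensor components (vx^2, vx*vy, vy^2) from orientation deg
orientation_to_tensor <- function(orientation_deg, anisotropy) {
  th <- orientation_deg * pi / 180
  vx <- cos(th); vy <- sin(th)
  w <- anisotropy
  w[is.na(w)] <- 0
  vx[is.na(th)] <- 0; vy[is.na(th)] <- 0
  list(Txx = w * vx * vx, Txy = w * vx * vy, Tyy = w * vy * vy)
}

#' Aggregate per-section orientation maps into blockface space
#'
#' For every blockface-grid pixel, the section's anisotropy-weighted unit
#' structure tensor is sampled at the transform-mapped location and
#' reoriented with the local Jacobian of the section's transform (a
#' structure direction d_in in section space corresponds to
#' `J^{-1} d_in` on the output grid, so tensors map as
#' `J^{-1} T J^{-T}`). Tensors are averaged (never angles, avoiding the
#' 0/180 wrap), then eigen-decomposed per voxel.
#'
#' @param maps named list of `orientation_map`s, keyed like
#'   `state$sections`.
#' @param state `alignment_state` carrying the per-section transforms.
#' @return `list(orientation, anisotropy)`: two `volume3d`s on the
#'   blockface grid (orientation `NA` where no section contributes).
#' @export
aggregate_to_blockface <- function(maps, state) {
  d <- state$dim
  nz_ids <- sort(as.integer(names(state$blockface)))
  nz <- length(nz_ids)
  Sxx <- array(0, c(d, nz)); Sxy <- array(0, c(d, nz))
  Syy <- array(0, c(d, nz)); cnt <- array(0, c(d, nz))
  g <- grid_coords(d)
  px <- as.vector(g$x); py <- as.vector(g$y)
  for (k in names(maps)) {
    s <- state$sections[[k]]
    om <- maps[[k]]
    zi <- match(s$slice, nz_ids)
    tc <- orientation_to_tensor(om$orientation, om$anisotropy)
    m <- tf_map(s$transform, px, py)
    Txx <- bilinear_sample(tc$Txx, m$x, m$y, 0)
    Txy <- bilinear_sample(tc$Txy, m$x, m$y, 0)
    Tyy <- bilinear_sample(tc$Tyy, m$x, m$y, 0)
    # local Jacobian of the map by central differences
    mx <- matrix(m$x, d[1], d[2]); my <- matrix(m$y, d[1], d[2])
    Jg <- list(image_gradient(mx), image_gradient(my))
    j11 <- as.vector(Jg[[1]][, , 1]); j12 <- as.vector(Jg[[1]][, , 2])
    j21 <- as.vector(Jg[[2]][, , 1]); j22 <- as.vector(Jg[[2]][, , 2])
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-6] <- 1e-6
    # rows of J^{-1}
    i11 <- j22 / det; i12 <- -j12 / det
    i21 <- -j21 / det; i22 <- j11 / det
    # T_out = J^{-1} T J^{-T}
    oxx <- i11 * (i11 * Txx + i12 * Txy) + i12 * (i11 * Txy + i12 * Tyy)
    oxy <- i21 * (i11 * Txx + i12 * Txy) + i22 * (i11 * Txy + i12 * Tyy)
    oyy <- i21 * (i21 * Txx + i22 * Txy) + i22 * (i21 * Txy + i22 * Tyy)
    # renormalize so reorientation does not change tensor magnitude
    sc <- sqrt(pmax(Txx + Tyy, 0) / pmax(oxx + oyy, .Machine$double.eps))
    sc[Txx + Tyy <= 0] <- 0
    Sxx[, , zi] <- Sxx[, , zi] + matrix(oxx * sc, d[1], d[2])
    Sxy[, , zi] <- Sxy[, , zi] + matrix(oxy * sc, d[1], d[2])
    Syy[, , zi] <- Syy[, , zi] + matrix(oyy * sc, d[1], d[2])
    cnt[, , zi] <- cnt[, , zi] + (Txx + Tyy > 0)
  }
  use <- cnt > 0
  Sxx[use] <- Sxx[use] / cnt[use]
  Sxy[use] <- Sxy[use] / cnt[use]
  Syy[use] <- Syy[use] / cnt[use]
  tr <- Sxx + Syy
  dd <- sqrt(pmax(0, (Sxx - Syy)^2 / 4 + Sxy^2))
  l1 <- tr / 2 + dd; l2 <- tr / 2 - dd
  # these tensors are built from structure directions (not gradients), so
  # the major eigenvector IS the aggregated orientation
  phi_g <- 0.5 * atan2(2 * Sxy, Sxx - Syy)
  orientation <- (phi_g * 180 / pi) %% 180
  # voxels with only numerically negligible tensor mass are undefined
  orientation[!use | l1 <= 1e-6 * max(l1, na.rm = TRUE)] <- NA_real_
  anis <- array(0, dim(l1))
  pos <- l1 > 0
  anis[pos] <- 1 - l2[pos] / l1[pos]
  vs <- rep(state$pixel_size, 3)
  list(orientation = volume3d(orientation, vs),
       anisotropy = volume3d(anis, vs))
}

#' 3D vessel density map from the registered sections
#'
#' Per-section vessel masks are transformed onto the blockface grid (linear
#' interpolation gives partial-volume fractions), accumulated across all
#' stains of each slice, divided by the number of contributing sections,
#' and Gaussian-smoothed with a mass-preserving kernel. Values are vessel
#' volume fractions in `[0, 1]`.
#'
#' @param state completed `alignment_state` (with per-section vessel masks
#'   in `features`).
#' @param smoothing_sigma smoothing in micrometers (isotropic; default
#'   400 um).
#' @return `volume3d`, with attribute `raw` (the unsmoothed fraction map).
#' @export
vessel_density <- function(state, smoothing_sigma = 400) {
  d <- state$dim
  nz_ids <- sort(as.integer(names(state$blockface)))
  nz <- length(nz_ids)
  acc <- array(0, c(d, nz)); cnt <- rep(0, nz)
  any_vessel <- FALSE
  for (k in names(state$sections)) {
    s <- state$sections[[k]]
    zi <- match(s$slice, nz_ids)
    vm <- s$features$vessel_mask
    if (is.null(vm)) next
    # features are refreshed from the resampled section after registration,
    # so the vessel mask already lives on the blockface grid
    acc[, , zi] <- acc[, , zi] + pmin(pmax(vm + 0, 0), 1)
    cnt[zi] <- cnt[zi] + 1
    if (any(vm)) any_vessel <- TRUE
  }
  if (!any_vessel)
    warning("vessel_density: no vessels detected in any section")
  for (zi in which(cnt > 0)) acc[, , zi] <- acc[, , zi] / cnt[zi]
  raw <- acc
  sig_vox <- smoothing_sigma / rep(state$pixel_size, 3)
  out <- smooth_gauss(acc, sig_vox)
  out <- pmin(pmax(out, 0), 1)
  v <- volume3d(out, rep(state$pixel_size, 3))
  attr(v, "raw") <- raw
  v
}
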