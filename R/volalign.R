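# Staged 3D alignment of an MRI volume to blockface space: an affine
# initialization followed by three deformable stages with decreasing
# regularization, MI-driven as in 2D, with optional exclusion of unreliable
# regions (ventricle-like holes) from the metric.

#' Construct a 3D transform (affine + displacement field)
#'
#' Pull-back convention as in 2D: the map for an output voxel p is
#' `A %*% c(p + u(p), 1)`.
#'
#' @param dim output grid `c(nx, ny, nz)`.
#' @param affine 3x4 matrix (defaults to identity).
#' @param field displacement array `[nx, ny, nz, 3]` in voxels, or `NULL`.
#' @return object of class `transform3d`.
#' @export
transform3d <- function(dim, affine = cbind(diag(3), c(0, 0, 0)),
                        field = NULL) {
  dim <- as.integer(dim)
  if (!is.null(field))
    stopifnot(length(dim(field)) == 4, all(dim(field)[1:3] == dim),
              dim(field)[4] == 3)
  structure(list(dim = dim, affine = affine, field = field),
            class = "transform3d")
}

# evaluate the 3D map on the full grid (vectors)
tf3_map <- function(t, px, py, pz) {
  if (!is.null(t$field)) {
    qx <- px + as.vector(t$field[, , , 1])
    qy <- py + as.vector(t$field[, , , 2])
    qz <- pz + as.vector(t$field[, , , 3])
  } else { qx <- px; qy <- py; qz <- pz }
  A <- t$affine
  list(x = A[1, 1] * qx + A[1, 2] * qy + A[1, 3] * qz + A[1, 4],
       y = A[2, 1] * qx + A[2, 2] * qy + A[2, 3] * qz + A[2, 4],
       z = A[3, 1] * qx + A[3, 2] * qy + A[3, 3] * qz + A[3, 4])
}

grid_coords3 <- function(d) {
  list(x = as.vector(slice.index(array(0L, d), 1)),
       y = as.vector(slice.index(array(0L, d), 2)),
       z = as.vector(slice.index(array(0L, d), 3)))
}

#' Resample a volume through a 3D transform
#' @param vol 3D array or `volume3d`.
#' @param t `transform3d`.
#' @param background fill value outside the domain.
#' @return array on the transform's output grid.
#' @export
apply_transform3d <- function(vol, t, background = 0) {
  a <- if (inherits(vol, "volume3d")) vol$voxels else vol
  g <- grid_coords3(t$dim)
  m <- tf3_map(t, g$x, g$y, g$z)
  array(trilinear_sample(a, m$x, m$y, m$z, background), t$dim)
}

#' Resample a volume to a target grid by trilinear interpolation
#'
#' Used to bring the MRI (e.g. 400-um isotropic) onto the 200-um blockface
#' grid before registration; voxel-centered field-of-view alignment.
#'
#' @param vol `volume3d`.
#' @param target `volume3d` whose grid and voxel size define the output.
#' @return `volume3d` on the target grid.
#' @export
resample_to_grid <- function(vol, target) {
  dt <- dim(target$voxels); dv <- dim(vol$voxels)
  g <- grid_coords3(dt)
  # physical position of target voxel centers, in source voxel coordinates
  sx <- target$voxel_size / vol$voxel_size
  x <- pmin(pmax((g$x - 0.5) * sx[1] + 0.5, 1), dv[1])  # clamp to edge
  y <- pmin(pmax((g$y - 0.5) * sx[2] + 0.5, 1), dv[2])
  z <- pmin(pmax((g$z - 0.5) * sx[3] + 0.5, 1), dv[3])
  volume3d(array(trilinear_sample(vol$voxels, x, y, z, 0), dt),
           target$voxel_size)
}

#' Regularization schedule for the staged 3D registration
#'
#' Three deformable stages with strictly decreasing field-smoothing sigma.
#'
#' @param sigmas length-3 decreasing vector of field smoothing sigmas
#'   (voxels).
#' @param iterations length-3 vector of iterations per stage.
#' @return object of class `regularization_schedule`.
#' @export
regularization_schedule <- function(sigmas = c(6, 3, 1.5),
                                    iterations = c(20, 20, 20)) {
  stopifnot(length(sigmas) == 3, length(iterations) == 3,
            all(diff(sigmas) < 0))
  structure(list(sigmas = sigmas, iterations = iterations),
            class = "regularization_schedule")
}

#' Skull-strip an MRI with the blockface mask
#'
#' Resamples the MRI through the given transform onto the blockface grid and
#' sets voxels outside the blockface tissue mask to background.
#'
#' @param mri `volume3d` or array.
#' @param blockface_mask `tissue_mask` (3D) or logical array.
#' @param t `transform3d` mapping blockface-grid coordinates into the MRI
#'   (identity by default).
#' @param background fill value.
#' @return array on the blockface grid.
#' @export
skull_strip <- function(mri, blockface_mask, t = NULL, background = 0) {
  m <- if (inherits(blockface_mask, "tissue_mask")) blockface_mask$mask
       else blockface_mask > 0
  if (!any(m)) stop("skull_strip: empty blockface mask")
  a <- if (inherits(mri, "volume3d")) mri$voxels else mri
  if (is.null(t)) t <- transform3d(dim(m))
  out <- apply_transform3d(a, t, background)
  out[!m] <- background
  out
}

mi3 <- function(a, b, bins, mask = NULL) mutual_information(a, b, bins, mask)

#' Staged MI-driven 3D registration of an MRI to the blockface volume
#'
#' Affine (translation) initialization at quarter resolution, then three
#' deformable stages with decreasing regularization, each initialized from
#' the previous; the metric is mutual information with an optional exclusion
#' mask zeroing unreliable regions. The deformable update is the same
#' conditional-mean remapped demons force as in 2D, in 3D.
#'
#' @param mri `volume3d` or array (resampled to the blockface grid first if
#'   a `volume3d` with different voxel size).
#' @param blockface `volume3d` or array, the fixed reference.
#' @param schedule [regularization_schedule()].
#' @param exclusion_mask optional array; zero excludes voxels from metric
#'   and force.
#' @param bins MI histogram bins.
#' @param step force step size.
#' @param keep_stages record the composed transform after each stage in
#'   attribute `stage_transforms` (for stage-wise evaluation).
#' @return `transform3d` with attributes `trace` (stage-wise metric values)
#'   and `score`.
#' @export
register_volume <- function(mri, blockface, schedule = regularization_schedule(),
                            exclusion_mask = NULL, bins = 32, step = 1.8,
                            keep_stages = FALSE) {
  fixed <- if (inherits(blockface, "volume3d")) blockface else volume3d(blockface)
  if (inherits(mri, "volume3d") &&
      !isTRUE(all.equal(mri$voxel_size, fixed$voxel_size)) )
    mri <- resample_to_grid(mri, fixed)
  mov <- if (inherits(mri, "volume3d")) mri$voxels else mri
  fix <- fixed$voxels
  d <- dim(fix)
  stopifnot(all(dim(mov) == d))
  sup <- if (is.null(exclusion_mask)) NULL else exclusion_mask > 0
  g <- grid_coords3(d)
  bg <- mean(mov)
  warp <- function(ux, uy, uz, A) {
    qx <- g$x + as.vector(ux); qy <- g$y + as.vector(uy)
    qz <- g$z + as.vector(uz)
    mx <- A[1, 1] * qx + A[1, 2] * qy + A[1, 3] * qz + A[1, 4]
    my <- A[2, 1] * qx + A[2, 2] * qy + A[2, 3] * qz + A[2, 4]
    mz <- A[3, 1] * qx + A[3, 2] * qy + A[3, 3] * qz + A[3, 4]
    array(trilinear_sample(mov, mx, my, mz, bg), d)
  }
  zero <- array(0, d)
  ux <- zero; uy <- zero; uz <- zero
  A <- cbind(diag(3), c(0, 0, 0))
  # ---- translation initialization on a decimated grid ----
  dec <- pmax(1L, as.integer(round(min(d) / 16)))
  sub <- list(seq(1, d[1], by = dec), seq(1, d[2], by = dec),
              seq(1, d[3], by = dec))
  fsub <- fix[sub[[1]], sub[[2]], sub[[3]]]
  span <- max(2L, as.integer(round(min(d) / 8)))
  step_t <- max(1, dec)
  offs <- sort(unique(c(0, seq(-span, span, by = step_t),
                        -seq(0, span, by = step_t))))
  best <- c(0, 0, 0); bestv <- -Inf
  for (tx in offs) {
    for (ty in offs) {
      for (tz in offs) {
        At <- cbind(diag(3), c(tx, ty, tz))
        w <- warp(zero, zero, zero, At)[sub[[1]], sub[[2]], sub[[3]]]
        v <- mi3(fsub, w, 16)
        if (v > bestv) { bestv <- v; best <- c(tx, ty, tz) }
      }
    }
  }
  A <- cbind(diag(3), best)
  trace <- data.frame(stage = 0L, iter = 0L,
                      score = mi3(fix, warp(ux, uy, uz, A), bins, sup))
  stage_transforms <- list()
  for (stage in 1:3) {
    sg <- schedule$sigmas[stage]
    best_u <- list(ux, uy, uz)
    w <- warp(ux, uy, uz, A)
    best_score <- mi3(fix, w, bins, sup)
    for (it in seq_len(schedule$iterations[stage])) {
      gr <- volume_gradient(w)
      dyn <- diff(range(w)) + 1e-12
      virt <- cond_mean_remap(as.vector(fix), as.vector(w), bins)
      nd <- (array(virt, d) - w) / dyn
      nd <- sign(nd) * pmax(abs(nd) - 0.75 / bins, 0)  # quantization deadzone
      ngx <- gr$gx / dyn; ngy <- gr$gy / dyn; ngz <- gr$gz / dyn
      den <- ngx^2 + ngy^2 + ngz^2 + nd^2 + 1e-8
      fx <- nd * ngx / den; fy <- nd * ngy / den; fz <- nd * ngz / den
      if (!is.null(sup)) { fx[!sup] <- 0; fy[!sup] <- 0; fz[!sup] <- 0 }
      ux <- smooth_gauss(ux + step * fx, sg)
      uy <- smooth_gauss(uy + step * fy, sg)
      uz <- smooth_gauss(uz + step * fz, sg)
      w <- warp(ux, uy, uz, A)
      score <- mi3(fix, w, bins, sup)
      trace <- rbind(trace, data.frame(stage = stage, iter = it,
                                       score = score))
      if (score > best_score) {
        best_score <- score; best_u <- list(ux, uy, uz)
      }
    }
    ux <- best_u[[1]]; uy <- best_u[[2]]; uz <- best_u[[3]]
    if (keep_stages)
      stage_transforms[[stage]] <-
        transform3d(d, affine = A, field = array(c(ux, uy, uz), c(d, 3)))
  }
  out <- transform3d(d, affine = A,
                     field = array(c(ux, uy, uz), c(d, 3)))
  attr(out, "trace") <- trace
  attr(out, "score") <- best_score
  if (keep_stages) attr(out, "stage_transforms") <- stage_transforms
  out
}

#' Mean endpoint error of an estimated 3D transform against a true warp
#'
#' @param t_est estimated `transform3d` (moving -> reference).
#' @param t_true true forward distortion `transform3d` (reference -> moving).
#' @param mask optional logical array.
#' @return mean `|T_true(T_est(p)) - p|` in voxels.
#' @export
endpoint_error3d <- function(t_est, t_true, mask = NULL) {
  g <- grid_coords3(t_est$dim)
  r <- tf3_map(t_est, g$x, g$y, g$z)
  if (!is.null(t_true$field)) {
    fx <- trilinear_sample(t_true$field[, , , 1], r$x, r$y, r$z, 0)
    fy <- trilinear_sample(t_true$field[, , , 2], r$x, r$y, r$z, 0)
    fz <- trilinear_sample(t_true$field[, , , 3], r$x, r$y, r$z, 0)
    qx <- r$x + fx; qy <- r$y + fy; qz <- r$z + fz
  } else { qx <- r$x; qy <- r$y; qz <- r$z }
  A <- t_true$affine
  mx <- A[1, 1] * qx + A[1, 2] * qy + A[1, 3] * qz + A[1, 4]
  my <- A[2, 1] * qx + A[2, 2] * qy + A[2, 3] * qz + A[2, 4]
  mz <- A[3, 1] * qx + A[3, 2] * qy + A[3, 3] * qz + A[3, 4]
  err <- sqrt((mx - g$x)^2 + (my - g$y)^2 + (mz - g$z)^2)
  if (!is.null(mask)) err <- err[as.vector(mask)]
  mean(err)
}
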