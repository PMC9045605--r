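# Transform2D: affine + dense displacement field in pull-back convention.
# The total map for an output-grid point p is  A %*% c(p + u(p), 1)  where
# u is the displacement field stored on the output grid.

#' Identity 2x3 affine matrix
#' @export
identity_affine <- function() cbind(diag(2), c(0, 0))

#' Construct a 2D transform (affine + displacement field)
#'
#' @param dim grid dimensions `c(nx, ny)` of the output (fixed) grid.
#' @param affine 2x3 matrix; defaults to identity.
#' @param field displacement array `[nx, ny, 2]` in pixels, or `NULL` for zero.
#' @return object of class `transform2d`.
#' @export
transform2d <- function(dim, affine = identity_affine(), field = NULL) {
  dim <- as.integer(dim)
  if (!is.null(field)) {
    stopifnot(length(dim(field)) == 3, all(dim(field)[1:2] == dim),
              dim(field)[3] == 2)
  }
  structure(list(dim = dim, affine = affine, field = field),
            class = "transform2d")
}

is_transform2d <- function(x) inherits(x, "transform2d")

#' @export
print.transform2d <- function(x, ...) {
  cat("transform2d on", x$dim[1], "x", x$dim[2], "grid\n")
  cat("affine:\n"); print(x$affine)
  if (!is.null(x$field))
    cat(sprintf("field: mean |u| = %.3f px, max |u| = %.3f px\n",
                mean(sqrt(x$field[, , 1]^2 + x$field[, , 2]^2)),
                max(sqrt(x$field[, , 1]^2 + x$field[, , 2]^2))))
  else cat("field: none\n")
  invisible(x)
}

# Evaluate the total map at arbitrary continuous output coordinates.
# Field values off-grid are obtained by bilinear interpolation and taper to 0
# outside the grid (affine-only extension).
tf_map <- function(t, x, y) {
  if (!is.null(t$field)) {
    ongrid <- length(x) == prod(t$dim) &&
      isTRUE(all.equal(x, as.vector(grid_coords(t$dim)$x), check.attributes = FALSE)) &&
      isTRUE(all.equal(y, as.vector(grid_coords(t$dim)$y), check.attributes = FALSE))
    if (ongrid) {
      qx <- x + as.vector(t$field[, , 1])
      qy <- y + as.vector(t$field[, , 2])
    } else {
      qx <- x + bilinear_sample(t$field[, , 1], x, y, background = 0)
      qy <- y + bilinear_sample(t$field[, , 2], x, y, background = 0)
    }
  } else {
    qx <- x; qy <- y
  }
  A <- t$affine
  list(x = A[1, 1] * qx + A[1, 2] * qy + A[1, 3],
       y = A[2, 1] * qx + A[2, 2] * qy + A[2, 3])
}

#' Resample an image through a 2D transform
#'
#' Pull-back resampling: `out[p] = image[T(p)]` with linear interpolation
#' (or nearest-neighbour for masks/labels). Out-of-domain pixels take the
#' background value.
#'
#' @param image input raster (matrix).
#' @param t `transform2d`.
#' @param interp `"linear"` or `"nearest"`.
#' @param background fill value.
#' @param out_dim optional output grid size; defaults to the transform grid.
#' @return resampled matrix on the output grid.
#' @export
apply_transform <- function(image, t, interp = c("linear", "nearest"),
                            background = 0, out_dim = NULL) {
  interp <- match.arg(interp)
  stopifnot(is_transform2d(t))
  d <- if (is.null(out_dim)) t$dim else as.integer(out_dim)
  g <- grid_coords(d)
  m <- tf_map(t, as.vector(g$x), as.vector(g$y))
  v <- if (interp == "linear") bilinear_sample(image, m$x, m$y, background)
       else nearest_sample(image, m$x, m$y, background)
  matrix(v, d[1], d[2])
}

#' Compose two 2D transforms
#'
#' `compose_transform(t1, t2)` is the transform whose resampling equals
#' applying `t2` to the image first, then `t1`: pointwise the map is
#' `p -> T2(T1(p))` in pull-back convention.
#'
#' @param t1,t2 `transform2d` objects on the same grid.
#' @return field-only `transform2d` equal to the composition.
#' @export
compose_transform <- function(t1, t2) {
  stopifnot(is_transform2d(t1), is_transform2d(t2))
  if (!all(t1$dim == t2$dim)) stop("compose_transform: grid mismatch")
  g <- grid_coords(t1$dim)
  q <- tf_map(t1, as.vector(g$x), as.vector(g$y))
  r <- tf_map(t2, q$x, q$y)
  field <- array(c(r$x - as.vector(g$x), r$y - as.vector(g$y)),
                 c(t1$dim, 2))
  transform2d(t1$dim, field = field)
}

#' Numerically invert a 2D transform
#'
#' Fixed-point iteration on the displacement; valid for smooth invertible
#' maps (positive Jacobian).
#'
#' @param t `transform2d`.
#' @param iters number of fixed-point iterations.
#' @return field-only `transform2d` approximating the inverse map.
#' @export
invert_transform <- function(t, iters = 30) {
  g <- grid_coords(t$dim)
  px <- as.vector(g$x); py <- as.vector(g$y)
  vx <- rep(0, length(px)); vy <- rep(0, length(py))
  for (i in seq_len(iters)) {
    m <- tf_map(t, px + vx, py + vy)
    vx <- vx - 0.7 * (m$x - px)
    vy <- vy - 0.7 * (m$y - py)
  }
  transform2d(t$dim, field = array(c(vx, vy), c(t$dim, 2)))
}

#' Mean displacement magnitude of a transform over its grid
#' @param t `transform2d`.
#' @param mask optional logical matrix restricting the average.
#' @return mean of `|T(p) - p|` in pixels.
#' @export
mean_displacement <- function(t, mask = NULL) {
  g <- grid_coords(t$dim)
  m <- tf_map(t, as.vector(g$x), as.vector(g$y))
  mag <- sqrt((m$x - as.vector(g$x))^2 + (m$y - as.vector(g$y))^2)
  if (!is.null(mask)) mag <- mag[as.logical(as.vector(mask))]
  mean(mag)
}

#' Mean endpoint error between an estimated and a true transform
#'
#' For a section distorted by true map `T_true`, a perfect recovery `R`
#' satisfies `T_true(R(p)) = p`; the endpoint error is the mean magnitude of
#' the residual over the (optionally masked) grid.
#'
#' @param t_est estimated `transform2d` (distorted section -> reference grid).
#' @param t_true true distortion `transform2d` (reference -> distorted).
#' @param mask optional logical matrix (e.g. tissue support).
#' @return mean endpoint error in pixels.
#' @export
endpoint_error <- function(t_est, t_true, mask = NULL) {
  g <- grid_coords(t_est$dim)
  px <- as.vector(g$x); py <- as.vector(g$y)
  r <- tf_map(t_est, px, py)
  m <- tf_map(t_true, r$x, r$y)
  err <- sqrt((m$x - px)^2 + (m$y - py)^2)
  if (!is.null(mask)) err <- err[as.logical(as.vector(mask))]
  mean(err)
}

# Serialization: affine as plain text, field as 2-channel NIfTI, JSON sidecar
# stating the convention.

#' Write a 2D transform to disk
#' @param t `transform2d`.
#' @param prefix file prefix; writes `<prefix>_affine.txt`,
#'   `<prefix>_field.nii.gz` (if a field is present) and `<prefix>.json`.
#' @export
write_transform2d <- function(t, prefix) {
  utils::write.table(t$affine, paste0(prefix, "_affine.txt"),
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(t$field))
    RNifti::writeNifti(t$field, paste0(prefix, "_field.nii.gz"))
  jsonlite::write_json(
    list(convention = "pullback: out(p) = in(A %*% (p + u(p)))",
         grid = t$dim, indexing = "1-based, voxel-centered, [x,y]",
         has_field = !is.null(t$field)),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a 2D transform written by [write_transform2d()]
#' @param prefix file prefix used when writing.
#' @return `transform2d`.
#' @export
read_transform2d <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  affine <- as.matrix(utils::read.table(paste0(prefix, "_affine.txt")))
  dimnames(affine) <- NULL
  field <- NULL
  if (isTRUE(meta$has_field)) {
    field <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_field.nii.gz"))),
                   c(meta$grid, 2))
  }
  transform2d(meta$grid, affine = affine, field = field)
}
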