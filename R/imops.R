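# Low-level raster operations shared by all modules.
#
# Conventions (fixed package-wide):
#  * 2D rasters are numeric matrices indexed [x, y] (EBImage convention).
#  * 3D volumes are arrays [x, y, z]; z is the slice index, rostral -> caudal.
#  * Continuous coordinates are 1-based pixel indices, voxel-centered.
#  * All transforms use the pull-back convention: they map output-grid
#    coordinates to input-image coordinates for resampling.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generation inside
#' the package never disturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Dense 1D Gaussian convolution matrix with renormalized (mass-preserving)
# truncation at the borders; applied by matrix product along each array
# axis. Cached, since the same (n, sigma) pairs recur throughout a
# registration run.
.kernel_cache <- new.env(parent = emptyenv())

gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  key <- paste0(n, "_", signif(sigma, 8))
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, ceiling(3 * sigma))
  i <- seq_len(n)
  K <- matrix(0, n, n)
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigma^2))
  for (k in seq_along(offs)) {
    j <- i + offs[k]
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[k]
  }
  K <- K / rowSums(K)
  if (length(.kernel_cache) < 400) .kernel_cache[[key]] <- K
  K
}

#' Separable Gaussian smoothing of a 2D or 3D array
#'
#' Border handling renormalizes the truncated kernel, so constant arrays are
#' exactly preserved.
#'
#' @param a matrix or 3D array.
#' @param sigma scalar or per-axis vector of standard deviations (pixels).
#' @return smoothed array, same dimensions.
#' @export
smooth_gauss <- function(a, sigma) {
  d <- dim(a)
  nd <- length(d)
  sigma <- rep(sigma, length.out = nd)
  if (all(sigma <= 0)) return(a)
  if (nd == 2) {
    if (sigma[1] > 0) a <- gauss_kernel_matrix(d[1], sigma[1]) %*% a
    if (sigma[2] > 0) a <- a %*% t(gauss_kernel_matrix(d[2], sigma[2]))
    return(a)
  }
  if (nd != 3) stop("smooth_gauss: only 2D or 3D arrays supported")
  if (sigma[1] > 0)
    a <- array(gauss_kernel_matrix(d[1], sigma[1]) %*% matrix(a, d[1]), d)
  if (sigma[2] > 0) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(gauss_kernel_matrix(d[2], sigma[2]) %*% matrix(a, d[2]), d[c(2, 1, 3)])
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(gauss_kernel_matrix(d[3], sigma[3]) %*% matrix(a, d[3]), d[c(3, 1, 2)])
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

#' Bilinear sampling of a 2D raster at continuous coordinates
#'
#' @param img matrix `[x, y]`.
#' @param x,y coordinate vectors (1-based pixel indices).
#' @param background fill value outside the image domain.
#' @return numeric vector of sampled intensities.
#' @export
bilinear_sample <- function(img, x, y, background = 0) {
  d <- dim(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  out <- rep(background, length(x))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2]
  if (!any(ok)) return(out)
  x0 <- pmin(pmax(x0[ok], 1L), d[1] - 1L)
  y0 <- pmin(pmax(y0[ok], 1L), d[2] - 1L)
  fx <- x[ok] - x0; fy <- y[ok] - y0
  i00 <- x0 + d[1] * (y0 - 1L)
  v <- (1 - fx) * (1 - fy) * img[i00] +
       fx       * (1 - fy) * img[i00 + 1L] +
       (1 - fx) * fy       * img[i00 + d[1]] +
       fx       * fy       * img[i00 + d[1] + 1L]
  out[ok] <- v
  out
}

#' Nearest-neighbour sampling of a 2D raster (for masks and labels)
#' @inheritParams bilinear_sample
#' @export
nearest_sample <- function(img, x, y, background = 0) {
  d <- dim(img)
  xi <- round(x); yi <- round(y)
  out <- rep(background, length(x))
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
  out[ok] <- img[cbind(xi[ok], yi[ok])]
  out
}

#' Trilinear sampling of a 3D volume at continuous coordinates
#' @param vol 3D array `[x, y, z]`.
#' @param x,y,z coordinate vectors.
#' @param background fill value outside the domain.
#' @export
trilinear_sample <- function(vol, x, y, z, background = 0) {
  d <- dim(vol)
  out <- rep(background, length(x))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(pmax(floor(x), 1L), d[1] - 1L)
  y0 <- pmin(pmax(floor(y), 1L), d[2] - 1L)
  z0 <- pmin(pmax(floor(z), 1L), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  sxy <- d[1] * d[2]
  i000 <- x0 + d[1] * (y0 - 1L) + sxy * (z0 - 1L)
  v00 <- (1 - fx) * vol[i000]       + fx * vol[i000 + 1L]
  v10 <- (1 - fx) * vol[i000 + d[1]] + fx * vol[i000 + d[1] + 1L]
  v01 <- (1 - fx) * vol[i000 + sxy] + fx * vol[i000 + sxy + 1L]
  v11 <- (1 - fx) * vol[i000 + d[1] + sxy] + fx * vol[i000 + d[1] + sxy + 1L]
  out[ok] <- (1 - fy) * ((1 - fz) * v00 + fz * v01) + fy * ((1 - fz) * v10 + fz * v11)
  out
}

# Full coordinate grid of a raster, as two matrices.
grid_coords <- function(d) {
  list(x = matrix(rep(seq_len(d[1]), d[2]), d[1], d[2]),
       y = matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]))
}

#' Bilinear resampling of a raster to a new grid size
#'
#' Decimation is preceded by Gaussian pre-smoothing (anti-aliasing); the
#' coordinate map preserves voxel-centered field-of-view alignment.
#'
#' @param img matrix.
#' @param newdim target `c(nx, ny)`.
#' @return resampled matrix.
#' @export
resize_bilinear <- function(img, newdim) {
  d <- dim(img)
  if (all(d == newdim)) return(img)
  f <- d / newdim
  s <- pmax(0, (f - 1) / 2)
  if (any(s > 0)) img <- smooth_gauss(img, s)
  g <- grid_coords(newdim)
  x <- (g$x - 0.5) * f[1] + 0.5
  y <- (g$y - 0.5) * f[2] + 0.5
  matrix(bilinear_sample(img, as.vector(x), as.vector(y),
                         background = mean(img)), newdim[1], newdim[2])
}

# Central-difference gradient of a raster; returns array [x, y, 2].
image_gradient <- function(img) {
  d <- dim(img)
  gx <- img; gy <- img
  gx[2:(d[1] - 1), ] <- (img[3:d[1], ] - img[1:(d[1] - 2), ]) / 2
  gx[1, ] <- img[2, ] - img[1, ]
  gx[d[1], ] <- img[d[1], ] - img[d[1] - 1, ]
  gy[, 2:(d[2] - 1)] <- (img[, 3:d[2]] - img[, 1:(d[2] - 2)]) / 2
  gy[, 1] <- img[, 2] - img[, 1]
  gy[, d[2]] <- img[, d[2]] - img[, d[2] - 1]
  array(c(gx, gy), c(d, 2))
}

# Central-difference gradient of a volume; returns list(gx, gy, gz).
volume_gradient <- function(vol) {
  d <- dim(vol)
  shift <- function(a, k, axis) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + k, 1L), d[axis])
    do.call(`[`, c(list(a), idx))
  }
  list(gx = (shift(vol, 1, 1) - shift(vol, -1, 1)) / 2,
       gy = (shift(vol, 1, 2) - shift(vol, -1, 2)) / 2,
       gz = (shift(vol, 1, 3) - shift(vol, -1, 3)) / 2)
}
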