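# Boundary and vessel feature maps: registration channels and QC landmarks.

# 8-connected contour of a binary mask (erosion by shifts; avoids S4
# container churn in the registration inner loop)
mask_contour <- function(mask) {
  mask <- mask > 0
  n1 <- nrow(mask); n2 <- ncol(mask)
  er <- mask
  er[2:n1, ] <- er[2:n1, ] & mask[1:(n1 - 1), ]
  er[1:(n1 - 1), ] <- er[1:(n1 - 1), ] & mask[2:n1, ]
  er[, 2:n2] <- er[, 2:n2] & mask[, 1:(n2 - 1)]
  er[, 1:(n2 - 1)] <- er[, 1:(n2 - 1)] & mask[, 2:n2]
  er[1, ] <- FALSE; er[n1, ] <- FALSE; er[, 1] <- FALSE; er[, n2] <- FALSE
  mask & !er
}

# strip the EBImage S4 container down to a plain matrix
ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `set`
distance_to_set <- function(set) {
  ebi_mat(EBImage::distmap(EBImage::Image(1 - (set > 0))))
}

#' Gaussian-of-distance boundary map of a tissue mask
#'
#' `exp(-d^2 / (2 sigma^2))` where `d` is the unsigned Euclidean distance to
#' the mask contour; equals 1 on contour pixels and decays monotonically
#' with distance, giving the registration metric a capture range around the
#' brain border.
#'
#' @param mask `tissue_mask` or binary matrix.
#' @param decay_sigma decay scale in micrometers (default 1000 um = 5
#'   blockface pixels at 200 um).
#' @param pixel_size micrometers per pixel (default 200).
#' @return matrix in `[0, 1]`.
#' @export
boundary_map <- function(mask, decay_sigma = 1000, pixel_size = 200) {
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  if (!any(mask > 0)) stop("boundary_map: empty mask")
  contour <- mask_contour(mask)
  d <- distance_to_set(contour)
  sigma_px <- decay_sigma / pixel_size
  exp(-d^2 / (2 * sigma_px^2))
}

# convex hull area of a pixel component, using all four pixel corners
pixel_hull_area <- function(xy) {
  pts <- rbind(xy + rep(c(-0.5, -0.5), each = nrow(xy)),
               xy + rep(c(-0.5,  0.5), each = nrow(xy)),
               xy + rep(c( 0.5, -0.5), each = nrow(xy)),
               xy + rep(c( 0.5,  0.5), each = nrow(xy)))
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(0)
  abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
}

#' Detect vessel cross-sections among the interior holes of a tissue mask
#'
#' Vessel candidates are background-intensity components inside the tissue
#' (the interior holes of the mask); they are kept when their equivalent
#' radius lies in `radius_range` and their solidity (area / convex hull
#' area) is at least `min_solidity` — the size and shape filters that
#' separate vessels from ventricle-scale holes and tears.
#'
#' @param section `section_image` or matrix (intensities; used for
#'   intensity-weighted centroids).
#' @param mask `tissue_mask` from [mask_background()] (its `holes` raster is
#'   the candidate set).
#' @param radius_range `c(min, max)` equivalent radius in pixels.
#' @param min_solidity minimum solidity (default 0.8).
#' @return `list(vessel_mask, centroids)`; centroids is a data.frame with
#'   columns `x`, `y` (pixel coordinates) and `radius`.
#' @export
detect_vessels <- function(section, mask, radius_range = c(1.5, 6),
                           min_solidity = 0.8) {
  px <- if (inherits(section, "section_image")) section$pixels else section
  stopifnot(inherits(mask, "tissue_mask"))
  holes <- mask$holes
  vessel_mask <- array(FALSE, dim(holes))
  centroids <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  if (!any(holes)) return(list(vessel_mask = vessel_mask, centroids = centroids))
  lab <- ebi_mat(EBImage::bwlabel(EBImage::Image(holes * 1)))
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    area <- length(idx)
    r_eq <- sqrt(area / pi)
    if (r_eq < radius_range[1] || r_eq > radius_range[2]) next
    xy <- cbind((idx - 1L) %% nrow(holes) + 1L,
                (idx - 1L) %/% nrow(holes) + 1L)
    hull <- pixel_hull_area(xy)
    solidity <- if (hull > 0) area / hull else 1
    if (solidity < min_solidity) next
    vals <- px[idx]
    w <- max(vals) - vals + 1e-6 * (max(vals) - min(vals) + 1)
    w <- w / sum(w)
    centroids <- rbind(centroids,
                       data.frame(x = sum(w * xy[, 1]), y = sum(w * xy[, 2]),
                                  radius = r_eq))
    vessel_mask[idx] <- TRUE
  }
  list(vessel_mask = vessel_mask, centroids = centroids)
}

#' Compute all feature maps for one section
#'
#' @param section `section_image` or matrix.
#' @param radius_range vessel radius filter (pixels).
#' @param decay_sigma boundary-map decay (micrometers).
#' @param pixel_size micrometers per pixel.
#' @return `list(mask, boundary, vessel_mask, centroids)`, or `NULL` when no
#'   foreground can be separated.
#' @export
section_features <- function(section, radius_range = c(1.5, 6),
                             decay_sigma = 1000, pixel_size = 200) {
  m <- try(mask_background(section), silent = TRUE)
  if (inherits(m, "try-error")) return(NULL)
  b <- boundary_map(m, decay_sigma, pixel_size)
  v <- detect_vessels(section, m, radius_range)
  list(mask = m, boundary = b, vessel_mask = v$vessel_mask,
       centroids = v$centroids)
}
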