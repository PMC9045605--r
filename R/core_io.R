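# Core containers and I/O: sections, volumes, masks; blockface restacking
# and automatic background masking.

#' Construct a SectionImage
#'
#' One digitized 2D section: a single-channel floating-point raster plus the
#' metadata needed to place it in the stack.
#'
#' @param pixels numeric matrix `[x, y]`.
#' @param pixel_size pixel size in micrometers (> 0).
#' @param stain one of `"blockface"`, `"nissl"`, `"bielschowsky"`,
#'   `"parvalbumin"`, `"calretinin"`, `"calbindin"`, `"other"`.
#' @param slice_index integer >= 0, rostral -> caudal coronal order.
#' @return object of class `section_image`.
#' @export
section_image <- function(pixels, pixel_size, stain = "other", slice_index = 0L) {
  stopifnot(is.matrix(pixels), length(pixels) > 0, all(is.finite(pixels)),
            is.numeric(pixel_size), pixel_size > 0)
  stain <- match.arg(stain, c("blockface", "nissl", "bielschowsky",
                              "parvalbumin", "calretinin", "calbindin", "other"))
  structure(list(pixels = pixels, pixel_size = pixel_size, stain = stain,
                 slice_index = as.integer(slice_index)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image: %d x %d px @ %g um, stain=%s, slice=%d\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$stain,
              x$slice_index))
  invisible(x)
}

#' Construct a Volume3D
#'
#' @param voxels 3D numeric array `[x, y, z]`; z is the slice axis.
#' @param voxel_size length-3 vector `(dx, dy, dz)` in micrometers.
#' @return object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size = c(200, 200, 200)) {
  stopifnot(length(dim(voxels)) == 3, all(voxel_size > 0))
  structure(list(voxels = voxels, voxel_size = rep(voxel_size, length.out = 3)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume3d: %d x %d x %d voxels @ (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  invisible(x)
}

#' Construct a TissueMask
#'
#' @param mask binary (logical or 0/1) raster, hole-filled foreground.
#' @param holes binary raster of interior holes (candidate vessels and
#'   ventricles), same dimensions.
#' @return object of class `tissue_mask`.
#' @export
tissue_mask <- function(mask, holes = NULL) {
  mask <- mask > 0
  if (is.null(holes)) holes <- array(FALSE, dim(mask)) else holes <- holes > 0
  stopifnot(all(dim(mask) == dim(holes)))
  structure(list(mask = mask, holes = holes), class = "tissue_mask")
}

#' Convert an RGB raster to grayscale with equal channel weights
#'
#' Each color channel contributes equally: output = (R + G + B) / 3.
#'
#' @param rgb 3D array `[x, y, 3]`.
#' @param pixel_size,stain,slice_index metadata passed to [section_image()].
#' @return `section_image` with the grayscale raster.
#' @export
to_grayscale <- function(rgb, pixel_size = 1, stain = "other", slice_index = 0L) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3)
    stop("to_grayscale: input must have exactly 3 channels, got ",
         if (length(d) == 3) d[3] else "a non-3D array")
  gray <- matrix((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3, d[1], d[2])
  section_image(gray, pixel_size, stain, slice_index)
}

#' Restack blockface sections into a 3D volume without registration
#'
#' Sections are stacked by `slice_index` (input order is irrelevant); slice z
#' of the volume is section z, unmodified. All blockface sections must share
#' one pixel size and raster size, and slice indices must form a complete
#' contiguous run.
#'
#' @param sections list of blockface `section_image`s.
#' @param slice_thickness section thickness in micrometers (default 200).
#' @return `volume3d` on the blockface grid.
#' @export
restack_blockface <- function(sections, slice_thickness = 200) {
  stopifnot(length(sections) > 0)
  idx <- vapply(sections, function(s) s$slice_index, integer(1))
  if (anyDuplicated(idx))
    stop("restack_blockface: duplicated slice indices: ",
         paste(sort(unique(idx[duplicated(idx)])), collapse = ", "))
  full <- seq(min(idx), max(idx))
  missing <- setdiff(full, idx)
  if (length(missing) > 0)
    stop("restack_blockface: missing slice indices: ",
         paste(missing, collapse = ", "))
  ord <- order(idx)
  sections <- sections[ord]
  d <- dim(sections[[1]]$pixels)
  ps <- sections[[1]]$pixel_size
  if (!all(vapply(sections, function(s) all(dim(s$pixels) == d) &&
                  isTRUE(all.equal(s$pixel_size, ps)), logical(1))))
    stop("restack_blockface: sections differ in raster size or pixel size")
  vox <- array(0, c(d, length(sections)))
  for (k in seq_along(sections)) vox[, , k] <- sections[[k]]$pixels
  volume3d(vox, c(ps, ps, slice_thickness))
}

# Otsu threshold on an arbitrary-range numeric vector.
otsu_threshold <- function(v, levels = 256) {
  r <- range(v)
  if (diff(r) == 0) stop("otsu_threshold: constant image")
  EBImage::otsu(EBImage::Image((v - r[1]) / diff(r)), range = c(0, 1),
                levels = levels) * diff(r) + r[1]
}

# 2D masking core shared by the section and volume methods. The background
# level is estimated from the frame border (sections are scanned with a
# clear margin); foreground is any sufficient deviation from it, which is
# robust for multi-class stains whose darkest tissue class sits close to a
# global-variance (Otsu) split.
mask_background_2d <- function(px, closing_size = 5) {
  if (diff(range(px)) == 0)
    stop("mask_background: degenerate (constant) image")
  n1 <- nrow(px); n2 <- ncol(px)
  border <- c(px[1:2, ], px[(n1 - 1):n1, ], px[, 1:2], px[, (n2 - 1):n2])
  bm <- stats::median(border)
  bs <- stats::mad(border)
  delta <- max(4 * bs, 0.02 * diff(range(px)))
  fg <- abs(px - bm) > delta
  img <- EBImage::Image(fg * 1)
  kern <- EBImage::makeBrush(closing_size, shape = "disc")
  img <- EBImage::closing(img, kern)
  lab <- EBImage::bwlabel(img)
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) == 0)
    stop("mask_background: no foreground component found")
  ebi_mat <- function(x) {
    m <- EBImage::imageData(x)
    dim(m) <- dim(m)[1:2]
    m
  }
  cc <- ebi_mat(lab) == which.max(tab)
  # closing stabilizes component labeling under noise but may pad concave
  # stretches of the outline; the mask keeps only raw foreground pixels of
  # the dominant component, with interior holes refilled
  core <- fg & ebi_mat(EBImage::fillHull(EBImage::Image(cc * 1))) > 0
  filled <- ebi_mat(EBImage::fillHull(EBImage::Image(core * 1))) > 0
  holes <- filled & !core
  tissue_mask(filled, holes)
}

#' Automatic background/foreground separation
#'
#' Otsu thresholding (background identified as the side dominating the image
#' border), morphological closing, largest connected component, hole filling.
#' Interior holes are retained separately as candidate vessels/ventricles.
#' For volumes the procedure is applied slice-wise.
#'
#' @param x `section_image`, plain matrix, or `volume3d`.
#' @param closing_size diameter (pixels) of the disc used for closing.
#' @return `tissue_mask` (3D rasters for volumes).
#' @export
mask_background <- function(x, closing_size = 5) {
  if (inherits(x, "section_image")) x <- x$pixels
  if (inherits(x, "volume3d")) {
    d <- dim(x$voxels)
    mask <- array(FALSE, d); holes <- array(FALSE, d)
    for (z in seq_len(d[3])) {
      m <- try(mask_background_2d(x$voxels[, , z], closing_size), silent = TRUE)
      if (!inherits(m, "try-error")) {
        mask[, , z] <- m$mask; holes[, , z] <- m$holes
      }
    }
    if (!any(mask)) stop("mask_background: no foreground found in any slice")
    return(tissue_mask(mask, holes))
  }
  mask_background_2d(x, closing_size)
}

#' Write a section as a 32-bit float TIFF with a YAML sidecar
#'
#' Intensities are affinely mapped to `[0, 1]` for storage; the mapping and
#' the section metadata are recorded in `<file>.yaml` so that reading
#' restores the original scale (to 32-bit float precision).
#'
#' @param section `section_image`.
#' @param file output path (`.tif`).
#' @export
write_section <- function(section, file) {
  px <- section$pixels
  r <- range(px)
  scale <- if (diff(r) > 0) diff(r) else 1
  tiff::writeTIFF(t((px - r[1]) / scale), file, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(offset = r[1], scale = scale,
                        pixel_size = section$pixel_size,
                        stain = section$stain,
                        slice_index = section$slice_index),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' Read a section written by [write_section()]
#' @param file path to the `.tif` file.
#' @return `section_image`.
#' @export
read_section <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  px <- t(tiff::readTIFF(file)) * meta$scale + meta$offset
  section_image(px, meta$pixel_size, meta$stain, meta$slice_index)
}

#' Write a volume as NIfTI-1 (float64, bit-exact round trip)
#' @param vol `volume3d`.
#' @param file output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, file) {
  a <- vol$voxels
  attr(a, "pixdim") <- vol$voxel_size / 1000  # NIfTI convention: mm
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), file)
  invisible(file)
}

#' Read a volume written by [write_volume()]
#' @param file path to the NIfTI file.
#' @return `volume3d`.
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  vs <- RNifti::pixdim(img)[1:3] * 1000
  volume3d(array(as.numeric(img), dim(img)), vs)
}
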