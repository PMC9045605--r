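# Synthetic serially-sectioned specimen with full ground truth: a smooth
# multi-class tissue volume with embedded tubular vessels, rendered per stain
# with noise and rostro-caudal intensity drift, distorted per slice with
# smooth invertible warps plus affine jitter, sampled with per-stain
# interleaved plans, and anchored by an undistorted blockface stack.

#' Specification of a synthetic serial-section phantom
#'
#' Defaults emulate the study conditions of a whole-specimen reconstruction
#' at desk scale: 200-um isotropic blockface grid, five stains interleaved so
#' that every slice carries at least one stain (the densest stain at a 1:3
#' interval, the others at 1:6 with staggered offsets), heavy smooth in-plane
#' distortions (mean displacement 10 px) with small affine jitter, and a slow
#' linear intensity drift along the stack.
#'
#' @param grid_shape `(nx, ny, nz)` voxels; minimum `(32, 32, 8)`.
#' @param voxel_size micrometers, isotropic (default 200).
#' @param n_tissue_classes number of tissue classes (>= 2), excluding
#'   background (class 0).
#' @param vessel_count number of tubular vessels.
#' @param vessel_radius_range `c(min, max)` radius in pixels.
#' @param stain_profiles named list per stain of
#'   `list(means = <per-class intensity>, noise_sd, background)`; the
#'   default provides distinct contrasts for five stains plus blockface.
#' @param sampling_plan named list per stain of `list(interval, offset)`;
#'   slice s carries the stain when `(s - offset) %% interval == 0`.
#' @param distortion_amplitude mean in-plane displacement magnitude (pixels).
#' @param distortion_smoothness Gaussian sigma (pixels) of the random
#'   displacement fields.
#' @param affine_jitter `list(max_rotation_deg, max_translation_px)`.
#' @param drift_rate intensity units per slice index.
#' @param damaged_slices slice indices omitted from all stains (blockface
#'   always present).
#' @param seed integer; identical spec + seed gives a bit-identical dataset.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 60),
                         voxel_size = 200,
                         n_tissue_classes = 4,
                         vessel_count = 8,
                         vessel_radius_range = c(2, 4),
                         stain_profiles = default_stain_profiles(n_tissue_classes),
                         sampling_plan = default_sampling_plan(),
                         distortion_amplitude = 10,
                         distortion_smoothness = 24,
                         affine_jitter = list(max_rotation_deg = 2,
                                              max_translation_px = 3),
                         drift_rate = 0.5,
                         damaged_slices = integer(0),
                         seed = 42L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= c(32, 32, 8)),
            n_tissue_classes >= 2, vessel_count >= 0,
            length(vessel_radius_range) == 2,
            distortion_amplitude >= 0)
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 n_tissue_classes = as.integer(n_tissue_classes),
                 vessel_count = as.integer(vessel_count),
                 vessel_radius_range = vessel_radius_range,
                 stain_profiles = stain_profiles,
                 sampling_plan = sampling_plan,
                 distortion_amplitude = distortion_amplitude,
                 distortion_smoothness = distortion_smoothness,
                 affine_jitter = affine_jitter,
                 drift_rate = drift_rate,
                 damaged_slices = as.integer(damaged_slices),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-stain intensity profiles
#'
#' Each stain maps tissue classes to distinct mean intensities so that the
#' contrasts are related only by unknown (non-monotone across stains)
#' lookups, as across real histological stains; the blockface profile
#' differs from all stains, forcing cross-contrast registration.
#'
#' @param n number of tissue classes.
#' @return named list of profiles, including `blockface`.
#' @export
default_stain_profiles <- function(n = 4) {
  base <- seq(60, 220, length.out = n)
  perm <- list(blockface    = base[((seq_len(n) + 1) %% n) + 1],
               nissl        = base,
               bielschowsky = rev(base),
               parvalbumin  = base[c(seq(2, n), 1)],
               calretinin   = 140 + 60 * sin(seq_len(n)),
               calbindin    = 100 + 100 * cos(seq_len(n) / 2))
  lapply(perm, function(m) list(means = m, noise_sd = 5, background = 0))
}

#' Default interleaved sampling plan
#'
#' The densest stain samples every third section; the remaining four sample
#' every sixth section at staggered offsets, so the union covers every slice.
#' Intervals may also be given as strings (`"1:3"`).
#'
#' @return named list per stain of `list(interval, offset)`.
#' @export
default_sampling_plan <- function() {
  list(nissl        = list(interval = 3, offset = 0),
       bielschowsky = list(interval = 6, offset = 1),
       parvalbumin  = list(interval = 6, offset = 2),
       calretinin   = list(interval = 6, offset = 4),
       calbindin    = list(interval = 6, offset = 5))
}

# "1:3" -> 3
parse_interval <- function(x) {
  if (is.character(x)) as.integer(sub("^1:", "", x)) else as.integer(x)
}

#' Slice indices sampled by a stain under a plan
#' @param plan_entry `list(interval, offset)`.
#' @param nz number of slices.
#' @param damaged slice indices to drop.
#' @return 0-based slice indices.
#' @export
sampled_slices <- function(plan_entry, nz, damaged = integer(0)) {
  interval <- parse_interval(plan_entry$interval)
  offset <- if (is.null(plan_entry$offset)) 0L else as.integer(plan_entry$offset)
  s <- seq(0, nz - 1)
  setdiff(s[(s - offset) %% interval == 0], damaged)
}

# deterministic per-(slice, stain) sub-seed
sub_seed <- function(seed, slice, k) {
  as.integer((as.numeric(seed) * 31 + slice * 7919 + k * 104729) %% 2147483629)
}

#' Generate the ground-truth label and vessel volumes
#'
#' Tissue geometry is built from thresholded band-limited noise inside an
#' approximately convex "brain" ellipsoid; vessels are smooth tubes running
#' along the slice axis with slow lateral wander, placed non-intersecting,
#' overwriting tissue labels.
#'
#' @param spec `phantom_spec`.
#' @return `list(labels, vessels)`: integer array (0 = background, 1..K =
#'   tissue classes) and logical vessel array.
#' @export
generate_label_volume <- function(spec) {
  d <- spec$grid_shape
  rmax <- max(spec$vessel_radius_range)
  margin <- ceiling(rmax + 8)
  if (spec$vessel_count > 0 && (d[1] < 2 * margin + 8 || d[2] < 2 * margin + 8))
    stop("generate_label_volume: grid in-plane size ", d[1], "x", d[2],
         " too small to place vessels of max radius ", rmax,
         " (needs > ", 2 * margin + 8, " pixels per axis)")
  with_seed(spec$seed, {
    # the brain is an elongated ellipsoid along the cutting axis: across one
    # or two section intervals the outline changes by well under a voxel,
    # as within a coronal block of a cerebral hemisphere
    g <- list(x = (slice.index(array(0, d), 1) - (d[1] + 1) / 2) / (0.42 * d[1]),
              y = (slice.index(array(0, d), 2) - (d[2] + 1) / 2) / (0.40 * d[2]),
              z = (slice.index(array(0, d), 3) - (d[3] + 1) / 2) / (1.4 * d[3]))
    bump <- smooth_gauss(array(stats::rnorm(prod(d)), d),
                         c(d[1], d[2], d[3]) / 10)
    bump <- 0.15 * bump / max(abs(bump), 1e-12)
    brain <- (g$x^2 + g$y^2 + g$z^2 + bump) < 1
    # interior architecture varies at the sub-millimeter scale along the
    # cutting axis (rostro-caudal) while staying smooth in-plane: between
    # two sampled sections of one stain the internal class boundaries move
    # by a few voxels, which is what cross-contrast interpolation must
    # bridge, while the outer outline (driven by the ellipsoid) stays
    # nearly static between neighbors
    tex <- smooth_gauss(array(stats::rnorm(prod(d)), d), c(6, 6, 4))
    qs <- stats::quantile(tex[brain],
                          probs = seq_len(spec$n_tissue_classes - 1) /
                                  spec$n_tissue_classes)
    labels <- array(0L, d)
    labels[brain] <- 1L + rowSums(outer(tex[brain], qs, `>`))
    vessels <- array(FALSE, d)
    if (spec$vessel_count > 0) {
      wander <- 5
      sep <- 2 * rmax + 2 * wander + 3
      centers <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(centers) < spec$vessel_count) {
        tries <- tries + 1
        if (tries > 2000)
          stop("generate_label_volume: cannot place ", spec$vessel_count,
               " non-intersecting vessels with separation ", sep,
               " on this grid; reduce vessel_count or enlarge the grid")
        cand <- c(stats::runif(1, margin, d[1] - margin),
                  stats::runif(1, margin, d[2] - margin))
        # keep the whole wander envelope inside the brain's mid-plane section
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > sep) {
          mid <- labels[, , max(1, round(d[3] / 2))]
          if (mid[round(cand[1]), round(cand[2])] > 0)
            centers <- rbind(centers, cand)
        }
      }
      gx <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
      gy <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
      # vessels must stay strictly interior to the tissue: precompute the
      # per-slice depth (distance to background) and pull any wandering
      # centerline back toward the slice centroid until its whole
      # cross-section is embedded
      depth <- vector("list", d[3])
      cent_z <- matrix(NA_real_, d[3], 2)
      for (z in seq_len(d[3])) {
        tz <- labels[, , z] > 0
        if (!any(tz)) next
        depth[[z]] <- distance_to_set(!tz)
        cent_z[z, ] <- colMeans(which(tz, arr.ind = TRUE))
      }
      for (v in seq_len(spec$vessel_count)) {
        r <- stats::runif(1, spec$vessel_radius_range[1],
                          spec$vessel_radius_range[2])
        a <- stats::runif(2, 0.3, 1) * wander
        ph <- stats::runif(2, 0, 2 * pi)
        fr <- stats::runif(2, 0.5, 1.5)
        for (z in seq_len(d[3])) {
          if (is.null(depth[[z]])) next
          cx <- centers[v, 1] + a[1] * sin(2 * pi * fr[1] * z / d[3] + ph[1])
          cy <- centers[v, 2] + a[2] * sin(2 * pi * fr[2] * z / d[3] + ph[2])
          need <- r + 1.5
          for (t in seq(0, 1, by = 0.05)) {
            px <- (1 - t) * cx + t * cent_z[z, 1]
            py <- (1 - t) * cy + t * cent_z[z, 2]
            ix <- min(max(round(px), 1L), d[1])
            iy <- min(max(round(py), 1L), d[2])
            if (depth[[z]][ix, iy] > need) { cx <- px; cy <- py; break }
          }
          disk <- (gx - cx)^2 + (gy - cy)^2 <= r^2
          vessels[, , z] <- vessels[, , z] | (disk & labels[, , z] > 0)
        }
      }
    }
    list(labels = labels, vessels = vessels)
  })
}

#' Render one section for a given stain
#'
#' Tissue pixels take the profile intensity of their class plus a linear
#' rostro-caudal drift and zero-mean Gaussian noise; vessel pixels and the
#' background class are rendered at the profile's exact background constant
#' (vessels are visible as background-intensity holes inside tissue).
#'
#' @param labels_slice integer matrix of class labels (0 = background).
#' @param vessels_slice logical matrix of vessel cross-sections.
#' @param stain_profile `list(means, noise_sd, background)`.
#' @param stain stain name recorded in the output.
#' @param slice_index 0-based slice index (drives the drift term).
#' @param drift_rate intensity units per slice.
#' @param noise_seed integer RNG seed for the noise draw.
#' @param pixel_size micrometers per pixel.
#' @return `section_image`.
#' @export
render_section <- function(labels_slice, vessels_slice, stain_profile,
                           stain = "other", slice_index = 0L, drift_rate = 0,
                           noise_seed = 1L, pixel_size = 200) {
  classes <- sort(unique(as.integer(labels_slice[labels_slice > 0])))
  if (length(classes) > 0 && max(classes) > length(stain_profile$means))
    stop("render_section: class ", max(classes),
         " missing from stain profile (profile has ",
         length(stain_profile$means), " classes)")
  px <- array(stain_profile$background, dim(labels_slice))
  tissue <- labels_slice > 0
  px[tissue] <- stain_profile$means[labels_slice[tissue]] +
    drift_rate * slice_index
  if (stain_profile$noise_sd > 0) {
    noise <- with_seed(noise_seed,
                       stats::rnorm(sum(tissue), 0, stain_profile$noise_sd))
    px[tissue] <- px[tissue] + noise
  }
  px[vessels_slice > 0] <- stain_profile$background
  section_image(px, pixel_size, stain, slice_index)
}

#' Apply a random smooth distortion plus affine jitter to a section
#'
#' The displacement field is Gaussian-smoothed white noise rescaled so its
#' mean magnitude equals `distortion_amplitude`; if the requested amplitude
#' would fold the warp (Jacobian not positive), it is rescaled down with a
#' warning. The exact transform used is returned alongside the warped image.
#'
#' @param section `section_image`.
#' @param distortion_amplitude mean displacement magnitude in pixels (>= 0).
#' @param affine_jitter `list(max_rotation_deg, max_translation_px)`; `NULL`
#'   for none.
#' @param seed integer RNG seed.
#' @param smoothness Gaussian sigma of the field (pixels).
#' @return `list(section, transform)`; `section` is the warped image,
#'   `transform` the exact `transform2d` used (pull-back), so that
#'   `apply_transform(original, transform)` reproduces the warped image.
#' @export
distort_section <- function(section, distortion_amplitude, affine_jitter = NULL,
                            seed = 1L, smoothness = 24) {
  stopifnot(distortion_amplitude >= 0)
  d <- dim(section$pixels)
  with_seed(seed, {
    field <- NULL
    if (distortion_amplitude > 0) {
      ux <- smooth_gauss(matrix(stats::rnorm(prod(d)), d[1], d[2]), smoothness)
      uy <- smooth_gauss(matrix(stats::rnorm(prod(d)), d[1], d[2]), smoothness)
      mag <- mean(sqrt(ux^2 + uy^2))
      ux <- ux * distortion_amplitude / mag
      uy <- uy * distortion_amplitude / mag
      # invertibility: Jacobian determinant of p + u(p) must stay positive
      jac_min <- function(sx, sy) {
        gx <- image_gradient(sx); gy <- image_gradient(sy)
        min((1 + gx[, , 1]) * (1 + gy[, , 2]) - gx[, , 2] * gy[, , 1])
      }
      jm <- jac_min(ux, uy)
      if (jm <= 0.1) {
        # shrink until the warp is safely invertible
        lo <- 0; hi <- 1
        for (i in 1:20) {
          mid <- (lo + hi) / 2
          if (jac_min(ux * mid, uy * mid) > 0.1) lo <- mid else hi <- mid
        }
        warning(sprintf(
          "distort_section: amplitude %.1f px would fold the warp (min Jacobian %.2f); rescaled by %.2f",
          distortion_amplitude, jm, lo))
        ux <- ux * lo
        uy <- uy * lo
      }
      field <- array(c(ux, uy), c(d, 2))
    }
    affine <- identity_affine()
    if (!is.null(affine_jitter)) {
      th <- stats::runif(1, -1, 1) * affine_jitter$max_rotation_deg * pi / 180
      tr <- stats::runif(2, -1, 1) * affine_jitter$max_translation_px
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      ctr <- (d + 1) / 2
      affine <- cbind(R, ctr - R %*% ctr + tr)
    }
    t <- transform2d(d, affine = affine, field = field)
    bg <- section$pixels[1, 1]
    warped <- apply_transform(section$pixels, t, background = bg)
    list(section = section_image(warped, section$pixel_size, section$stain,
                                 section$slice_index),
         transform = t)
  })
}

#' Build a complete phantom dataset
#'
#' Renders the undistorted blockface stack (its own sixth contrast, covering
#' every slice), renders and distorts each stained section according to the
#' sampling plan (damaged slices omitted from stains but kept in the
#' blockface), and records all ground truth: label/vessel volumes, the exact
#' per-section distortion transforms, and the undistorted renderings.
#'
#' @param spec `phantom_spec`.
#' @return object of class `phantom_dataset` with elements `spec`, `labels`,
#'   `vessels`, `blockface` (list of `section_image`, one per slice),
#'   `sections` (named list `s<slice>_<stain>` of
#'   `list(section, stain, slice, true_transform, undistorted)`).
#' @export
build_phantom_dataset <- function(spec) {
  gt <- generate_label_volume(spec)
  nz <- spec$grid_shape[3]
  stains <- names(spec$sampling_plan)
  blockface <- vector("list", nz)
  for (z in seq_len(nz)) {
    blockface[[z]] <- render_section(
      gt$labels[, , z], gt$vessels[, , z],
      spec$stain_profiles$blockface, stain = "blockface",
      slice_index = z - 1L, drift_rate = 0,
      noise_seed = sub_seed(spec$seed, z - 1L, 0L),
      pixel_size = spec$voxel_size)
  }
  sections <- list()
  for (k in seq_along(stains)) {
    st <- stains[k]
    for (s in sampled_slices(spec$sampling_plan[[st]], nz,
                             spec$damaged_slices)) {
      undist <- render_section(
        gt$labels[, , s + 1], gt$vessels[, , s + 1],
        spec$stain_profiles[[st]], stain = st, slice_index = s,
        drift_rate = spec$drift_rate,
        noise_seed = sub_seed(spec$seed, s, k),
        pixel_size = spec$voxel_size)
      dst <- distort_section(undist, spec$distortion_amplitude,
                             spec$affine_jitter,
                             seed = sub_seed(spec$seed, s, k + 100L),
                             smoothness = spec$distortion_smoothness)
      sections[[sprintf("s%03d_%s", s, st)]] <-
        list(section = dst$section, stain = st, slice = s,
             true_transform = dst$transform, undistorted = undist)
    }
  }
  structure(list(spec = spec, labels = gt$labels, vessels = gt$vessels,
                 blockface = blockface, sections = sections),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom_dataset: %s grid, %d blockface slices, %d stained sections\n",
              paste(x$spec$grid_shape, collapse = "x"),
              length(x$blockface), length(x$sections)))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Sections and blockface as float TIFFs with sidecars, ground-truth labels
#' and vessels as NIfTI, true displacement fields via [write_transform2d()],
#' and a YAML manifest recording the sampling plan and seed.
#'
#' @param dataset `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(dataset, dir) {
  dir.create(file.path(dir, "blockface"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sections"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (s in dataset$blockface)
    write_section(s, file.path(dir, "blockface",
                               sprintf("bf_%03d.tif", s$slice_index)))
  for (nm in names(dataset$sections)) {
    e <- dataset$sections[[nm]]
    write_section(e$section, file.path(dir, "sections", paste0(nm, ".tif")))
    write_transform2d(e$true_transform, file.path(dir, "truth", nm))
  }
  vs <- rep(dataset$spec$voxel_size, 3)
  write_volume(volume3d(dataset$labels + 0, vs),
               file.path(dir, "truth", "labels.nii.gz"))
  write_volume(volume3d(dataset$vessels + 0, vs),
               file.path(dir, "truth", "vessels.nii.gz"))
  yaml::write_yaml(list(seed = dataset$spec$seed,
                        grid_shape = dataset$spec$grid_shape,
                        voxel_size = dataset$spec$voxel_size,
                        sampling_plan = dataset$spec$sampling_plan,
                        damaged_slices = dataset$spec$damaged_slices),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
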