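# Pairwise 2D registration engine: multiresolution affine + Gaussian-
# regularized displacement-field alignment maximizing a weighted sum of
# mutual-information terms over multiple fixed targets.
#
# The deformable update is demons-style: at each iteration every target is
# remapped into the moving image's intensity space through the conditional
# mean of the current joint histogram (an MI-consistent, contrast-free
# representation), and the resulting intensity residuals drive a normalized
# gradient force, accumulated over targets with their weights, smoothed
# (fluid), integrated into the field, and smoothed again (diffusion).
# Mutual information itself is used to score iterates; the best-scoring
# field per level is kept.

#' Registration parameters
#'
#' @param n_scales number of dyadic resolution levels (default 6).
#' @param coarsest_downsampling downsampling factor at the coarsest level
#'   (default 64). Levels whose coarse image would drop below 8 pixels per
#'   axis are truncated; a full-resolution (factor 1) level is always run
#'   last.
#' @param mi_bins histogram bins for mutual information (default 32); at
#'   coarse levels the bin count is reduced to keep counts informative.
#' @param iterations_per_scale iterations per level, coarse to fine
#'   (recycled; default 25).
#' @param smoothing_sigma_fluid Gaussian sigma (pixels) applied to the force
#'   before integration.
#' @param smoothing_sigma_field Gaussian sigma (pixels) applied to the field
#'   after each update (the regularizer guaranteeing smooth warps).
#' @param step force step size (pixels of maximum per-iteration update).
#' @param convergence_tol relative metric change below which a level stops.
#' @param do_affine run the affine stage at the coarsest level.
#' @param boundary_force_gain force gain of boundary-band targets (their
#'   weight in the selection metric is unchanged).
#' @param boundary_sigma decay sigma of rebuilt boundary bands, in
#'   full-resolution pixels.
#' @param boundary_max_factor boundary targets are disabled at levels
#'   coarser than this downsampling factor (they are gauge-free until the
#'   residual fits inside the band).
#' @param mask_capture_sigma Gaussian softening of mask-channel targets
#'   (pixels); larger values widen the contrast-free capture range.
#' @param affine_max_rotation rejection bound (degrees) for the affine
#'   stage.
#' @param discrete_search run the discrete local-offset (block-matching)
#'   capture passes at coarse levels.
#' @param deadzone residual shrinkage in units of histogram bin width;
#'   residuals below it carry no alignment information.
#' @return object of class `registration_params`.
#' @export
registration_params <- function(n_scales = 6, coarsest_downsampling = 64,
                                mi_bins = 32, iterations_per_scale = 30,
                                smoothing_sigma_fluid = 2,
                                smoothing_sigma_field = 1.5,
                                step = 1.8, convergence_tol = 1e-4,
                                do_affine = TRUE, boundary_force_gain = 0.5,
                                boundary_sigma = 5, boundary_max_factor = 2.5,
                                mask_capture_sigma = 3,
                                affine_max_rotation = 20,
                                discrete_search = TRUE, deadzone = 0) {
  structure(list(n_scales = n_scales,
                 coarsest_downsampling = coarsest_downsampling,
                 mi_bins = mi_bins,
                 iterations_per_scale = iterations_per_scale,
                 smoothing_sigma_fluid = smoothing_sigma_fluid,
                 smoothing_sigma_field = smoothing_sigma_field,
                 step = step, convergence_tol = convergence_tol,
                 do_affine = do_affine,
                 boundary_force_gain = boundary_force_gain,
                 boundary_sigma = boundary_sigma,
                 boundary_max_factor = boundary_max_factor,
                 mask_capture_sigma = mask_capture_sigma,
                 affine_max_rotation = affine_max_rotation,
                 discrete_search = discrete_search, deadzone = deadzone),
            class = "registration_params")
}

#' A weighted registration target
#'
#' @param image raster on the fixed grid.
#' @param weight nonnegative scalar.
#' @param channel which moving channel this target is compared against:
#'   `"image"` (intensities), `"boundary"` (boundary feature map, rebuilt
#'   from the warped tissue mask), or `"mask"` (Gaussian-softened tissue
#'   mask: a contrast-free matching term with a wide capture range).
#' @param support_mask optional raster; zero excludes pixels from the metric
#'   and the force (used for ventricle-like unreliable regions).
#' @return object of class `weighted_target`.
#' @export
weighted_target <- function(image, weight = 1,
                            channel = c("image", "boundary", "mask"),
                            support_mask = NULL) {
  channel <- match.arg(channel)
  stopifnot(weight >= 0)
  structure(list(image = image, weight = weight, channel = channel,
                 support_mask = support_mask),
            class = "weighted_target")
}

# histogram bin indices over the observed range
bin_index <- function(v, bins) {
  r <- range(v)
  if (diff(r) == 0) return(rep(1L, length(v)))
  pmin.int(bins, 1L + as.integer(floor((v - r[1]) / diff(r) * bins)))
}

#' Mutual information between two rasters (bits)
#'
#' Joint-histogram MI with equal-width bins over each image's observed
#' range. A constant image within the support has zero entropy and yields 0.
#'
#' @param a,b numeric rasters (or vectors) of identical length.
#' @param bins number of bins per axis (default 32).
#' @param support_mask optional mask restricting the samples.
#' @return MI in bits (>= 0 up to numerical precision).
#' @export
mutual_information <- function(a, b, bins = 32, support_mask = NULL) {
  a <- as.vector(a); b <- as.vector(b)
  stopifnot(length(a) == length(b))
  if (!is.null(support_mask)) {
    keep <- as.vector(support_mask) > 0
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0 || diff(range(a)) == 0 || diff(range(b)) == 0)
    return(0)
  ia <- bin_index(a, bins); ib <- bin_index(b, bins)
  P <- matrix(tabulate(ia + bins * (ib - 1L), bins * bins), bins, bins)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  E <- outer(px, py)
  nz <- P > 0
  sum(P[nz] * log2(P[nz] / E[nz]))
}

# conditional mean of b within equal-width bins of a (target remapping)
cond_mean_remap <- function(a, b, bins) {
  ia <- bin_index(a, bins)
  cnt <- tabulate(ia, bins)
  rs <- rowsum(b, ia)
  cm <- numeric(bins)
  g <- as.integer(rownames(rs))
  cm[g] <- rs[, 1] / cnt[g]
  cm[ia]
}

# homogeneous scaling between the full grid and a level grid:
# level coords p_l = (p_f - 0.5)/f + 0.5
scale_homog <- function(f) rbind(c(1 / f, 0, 0.5 - 0.5 / f),
                                 c(0, 1 / f, 0.5 - 0.5 / f),
                                 c(0, 0, 1))

# reexpress a full-resolution affine on a level grid (factor f), and back
affine_to_level <- function(A, f) {
  S <- scale_homog(f)
  (S %*% rbind(A, c(0, 0, 1)) %*% solve(S))[1:2, , drop = FALSE]
}
affine_from_level <- function(Al, f) {
  S <- scale_homog(f)
  (solve(S) %*% rbind(Al, c(0, 0, 1)) %*% S)[1:2, , drop = FALSE]
}

# rotation(theta) about the grid center + translation, as a 2x3 affine
rigid_affine <- function(theta, tx, ty, d, log_s = 0) {
  s <- exp(log_s)
  R <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ctr <- (d + 1) / 2
  cbind(R, ctr - R %*% ctr + c(tx, ty))
}

# affine initialization: integer translation search at a coarse level,
# Nelder-Mead over (tx, ty, theta) at a finer level, then a full 6-dof
# Nelder-Mead refinement; scored on the weighted similarity (MI for
# intensity channels, boundary-band correlation for boundary targets, with
# the band rebuilt from the warped mask)
estimate_affine <- function(moving, targets, channels, bgs, d, params) {
  level_for <- function(minpix) max(1, 2^floor(log2(min(d) / minpix)))
  # boundary targets are dropped here: their band rebuild is costly per
  # evaluation and the mask term already carries the outline information
  # relevant at the affine stage
  targets <- Filter(function(tg) tg$channel != "boundary", targets)
  channels <- unique(vapply(targets, function(t) t$channel, character(1)))
  warp_set <- channels
  has_mask_ch <- "mask" %in% channels
  setup <- function(f) {
    dl <- as.integer(round(d / f))
    Ml <- lapply(moving, resize_bilinear, newdim = dl)
    Tl <- lapply(targets, function(tg) {
      tg$image <- resize_bilinear(tg$image, dl)
      if (tg$channel == "mask")
        tg$image <- smooth_gauss(tg$image, params$mask_capture_sigma)
      if (!is.null(tg$support_mask))
        tg$support_mask <- resize_bilinear(tg$support_mask + 0, dl) > 0.5
      tg
    })
    g <- grid_coords(dl)
    list(dl = dl, Ml = Ml, Tl = Tl, px = as.vector(g$x), py = as.vector(g$y),
         sigma_band = max(params$boundary_sigma / f, 1.2),
         bins = max(8L, min(params$mi_bins,
                            2L^as.integer(floor(log2(sqrt(prod(dl)) / 2))))))
  }
  score <- function(L, Alev) {
    mx <- Alev[1, 1] * L$px + Alev[1, 2] * L$py + Alev[1, 3]
    my <- Alev[2, 1] * L$px + Alev[2, 2] * L$py + Alev[2, 3]
    warped <- list()
    for (ch in warp_set)
      warped[[ch]] <- matrix(bilinear_sample(L$Ml[[ch]], mx, my, bgs[[ch]]),
                             L$dl[1], L$dl[2])
    if (has_mask_ch)
      warped$mask <- smooth_gauss(warped$mask, params$mask_capture_sigma)
    weighted_mi(warped, L$Tl, L$bins)
  }
  f1 <- level_for(16)
  L1 <- setup(f1)
  span <- max(2L, as.integer(round(min(L1$dl) / 3)))
  best <- c(0, 0); bestv <- -Inf
  for (tx in -span:span) for (ty in -span:span) {
    v <- score(L1, cbind(diag(2), c(tx, ty)))
    if (v > bestv) { bestv <- v; best <- c(tx, ty) }
  }
  f2 <- max(1, level_for(32))
  L2 <- setup(f2)
  start <- c(best * f1 / f2, 0)
  # mounted sections sit nearly upright on the blockface: large rotations
  # or shears are spurious optima of rotation-tolerant (round) masks
  th_max <- params$affine_max_rotation * pi / 180
  opt <- stats::optim(start,
                      function(p) {
                        if (abs(p[3]) > th_max) return(1e6)
                        -score(L2, rigid_affine(p[3], p[1], p[2], L2$dl))
                      },
                      method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-6))
  Ar <- rigid_affine(opt$par[3], opt$par[1], opt$par[2], L2$dl)
  # full-affine refinement about the rigid result, center-anchored
  ctr <- (L2$dl + 1) / 2
  full_affine <- function(p) {
    M <- matrix(p[1:4], 2, 2)
    cbind(M, ctr - M %*% ctr + p[5:6])
  }
  t0 <- as.vector(Ar %*% c(ctr, 1) - ctr)
  p0 <- c(as.vector(Ar[, 1:2]), t0)
  opt2 <- stats::optim(p0, function(p) {
                         M <- matrix(p[1:4], 2, 2)
                         ang <- atan2(M[2, 1] - M[1, 2], M[1, 1] + M[2, 2])
                         dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
                         if (abs(ang) > th_max || dt < 0.5 || dt > 2)
                           return(1e6)
                         -score(L2, full_affine(p))
                       },
                       method = "Nelder-Mead",
                       control = list(maxit = 250, reltol = 1e-6,
                                      parscale = c(rep(0.02, 4), 1, 1)))
  A2 <- full_affine(opt2$par)
  Al <- if (-opt2$value > -opt$value) A2 else Ar
  affine_from_level(Al, mean(d / L2$dl))
}

# Discrete local-offset search (block matching) on the remapped residual:
# for every pixel of the current warped moving image, try integer offsets
# within +/- span and keep the one minimizing the patch-averaged weighted
# residual against the targets. The chosen offsets, confidence-weighted and
# smoothed, are added to the field. This gives long-range capture that
# gradient-based updates lack when the misalignment exceeds the local
# gradient scale.
discrete_offset_update <- function(warped, Tl, bins, span, rbox, smooth_sigma) {
  d <- dim(warped[[1]])
  shift2 <- function(m, dx, dy) {
    i <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    j <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    m[i, j]
  }
  resid <- list()
  for (ti in seq_along(Tl)) {
    tg <- Tl[[ti]]
    if (tg$weight <= 0 || tg$channel == "boundary") next
    wv <- warped[[tg$channel]]
    virt <- if (tg$channel == "mask") tg$image
            else matrix(cond_mean_remap(as.vector(tg$image), as.vector(wv),
                                        bins), d[1], d[2])
    dyn <- diff(range(wv)) + 1e-12
    resid[[length(resid) + 1]] <-
      list(virt = virt / dyn, wv = wv / dyn, w = tg$weight)
  }
  if (length(resid) == 0) return(NULL)
  best_cost <- NULL; best_dx <- matrix(0L, d[1], d[2])
  best_dy <- matrix(0L, d[1], d[2]); cost0 <- NULL
  for (dx in -span:span) for (dy in -span:span) {
    cost <- 0
    for (r in resid)
      cost <- cost + r$w * box_mean((r$virt - shift2(r$wv, dx, dy))^2, rbox)
    if (is.null(best_cost)) {
      best_cost <- cost + Inf
    }
    upd <- cost < best_cost
    best_cost[upd] <- cost[upd]
    best_dx[upd] <- dx; best_dy[upd] <- dy
    if (dx == 0 && dy == 0) cost0 <- cost
  }
  conf <- pmax(cost0 - best_cost, 0)
  wsum <- smooth_gauss(conf, smooth_sigma) + 1e-12
  list(x = smooth_gauss(conf * best_dx, smooth_sigma) / wsum,
       y = smooth_gauss(conf * best_dy, smooth_sigma) / wsum)
}

# resolution schedule: dyadic factors from the coarsest, truncated so every
# level keeps >= 8 pixels per axis; a full-resolution level is always last
scale_schedule <- function(params, d) {
  fs <- params$coarsest_downsampling / 2^(seq_len(params$n_scales) - 1)
  fs <- fs[min(d) / fs >= 8]
  fs <- unique(c(fs, 1))
  if (length(fs) < params$n_scales)
    hs_log("scale schedule truncated to factors ", paste(fs, collapse = ", "),
           " for a ", d[1], "x", d[2], " grid")
  fs
}

hs_log <- function(...) {
  if (isTRUE(getOption("histostack.verbose", FALSE))) message(...)
  invisible(NULL)
}

# weighted similarity objective for a given warped channel set: MI for
# intensity channels; Pearson correlation for boundary/mask feature maps,
# which are already on a common calibrated scale and whose MI would reward
# degenerate overlap warps
weighted_mi <- function(warped, targets, bins) {
  s <- 0
  for (tg in targets) {
    if (tg$weight <= 0) next
    w <- warped[[tg$channel]]
    term <- if (tg$channel %in% c("boundary", "mask")) {
      a <- as.vector(tg$image); b <- as.vector(w)
      if (!is.null(tg$support_mask)) {
        keep <- as.vector(tg$support_mask) > 0
        a <- a[keep]; b <- b[keep]
      }
      if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) 0
      else stats::cor(a, b)
    } else {
      mutual_information(tg$image, w, bins, tg$support_mask)
    }
    s <- s + tg$weight * term
  }
  s
}

#' Register a moving section to a set of weighted fixed targets
#'
#' Coarse-to-fine optimization of `sum_i w_i MI(target_i, moving o T)` with
#' Gaussian field smoothing as regularization. An affine stage (translation
#' grid search + Nelder-Mead over rotation/translation/scale) precedes the
#' deformable stage at the coarsest level; the deformable stage is the
#' demons-style MI-force ascent described in the package vignette.
#'
#' @param moving raster, or named list of channels
#'   `list(image = ..., boundary = ...)`; all channels are warped by the one
#'   shared transform.
#' @param targets list of [weighted_target()]s on the fixed grid (same size
#'   as the moving raster).
#' @param params [registration_params()].
#' @param init optional `transform2d` used as the starting point (the affine
#'   stage is skipped when an init is supplied).
#' @return `transform2d` on the fixed grid, with attribute `trace` (a
#'   data.frame of level, iteration and weighted-MI score) and attribute
#'   `score` (final full-resolution weighted MI).
#' @export
register_pair <- function(moving, targets, params = registration_params(),
                          init = NULL) {
  if (!is.list(moving) || is.matrix(moving)) moving <- list(image = moving)
  stopifnot(length(targets) > 0)
  w <- vapply(targets, function(t) t$weight, numeric(1))
  if (!any(w > 0)) stop("register_pair: no target with positive weight")
  d <- dim(moving$image)
  for (tg in targets) stopifnot(all(dim(tg$image) == d))
  channels <- unique(vapply(targets, function(t) t$channel, character(1)))
  if (any(c("boundary", "mask") %in% channels) && is.null(moving$mask))
    stop("register_pair: boundary/mask targets require the moving channel ",
         "'mask' (binary tissue mask); the boundary band is rebuilt from ",
         "the warped mask so that distances stay consistent under ",
         "deformation")
  for (ch in setdiff(channels, "boundary")) if (is.null(moving[[ch]]))
    stop("register_pair: target requires moving channel '", ch, "'")
  if (!is.null(moving$mask)) moving$mask <- (moving$mask > 0) + 0
  fs <- scale_schedule(params, d)
  iters <- rep(params$iterations_per_scale, length.out = length(fs))
  A <- if (is.null(init)) identity_affine() else init$affine
  u <- NULL  # level-resolution displacement field (level pixels), list(x, y)
  prev_f <- NULL
  trace <- list()
  bgs <- lapply(moving, mean)
  bgs$mask <- 0
  warp_set <- setdiff(channels, "boundary")
  if ("boundary" %in% channels) warp_set <- union(warp_set, "mask")
  has_mask_ch <- "mask" %in% channels
  if (params$do_affine && is.null(init))
    A <- estimate_affine(moving, targets, channels, bgs, d, params)
  for (li in seq_along(fs)) {
    f <- fs[li]
    dl <- pmax(4L, as.integer(round(d / f)))
    fl <- d / dl  # effective (possibly slightly anisotropic) factor
    Ml <- lapply(moving, resize_bilinear, newdim = dl)
    Tl <- lapply(targets, function(tg) {
      tg$image <- resize_bilinear(tg$image, dl)
      if (tg$channel == "mask")
        tg$image <- smooth_gauss(tg$image, params$mask_capture_sigma)
      if (!is.null(tg$support_mask))
        tg$support_mask <- resize_bilinear(tg$support_mask + 0, dl) > 0.5
      tg
    })
    bins_l <- max(8L, min(params$mi_bins,
                          2L^as.integer(floor(log2(sqrt(prod(dl)) / 2)))))
    Al <- affine_to_level(A, mean(fl))
    g <- grid_coords(dl)
    px <- as.vector(g$x); py <- as.vector(g$y)
    if (is.null(u)) {
      if (!is.null(init) && !is.null(init$field)) {
        u <- list(x = resize_bilinear(init$field[, , 1], dl) / mean(fl),
                  y = resize_bilinear(init$field[, , 2], dl) / mean(fl))
      } else u <- list(x = matrix(0, dl[1], dl[2]), y = matrix(0, dl[1], dl[2]))
    } else {
      r <- prev_f / mean(fl)
      u <- list(x = resize_bilinear(u$x, dl) * r,
                y = resize_bilinear(u$y, dl) * r)
    }
    sigma_band <- max(params$boundary_sigma / mean(fl), 1.2)
    # boundary terms act only at fine levels: their capture range is the
    # band width, so they sharpen borders once the intensity channels have
    # brought the residual within it, and they are gauge-free (tangential
    # sliding) when engaged too early
    if (mean(fl) > params$boundary_max_factor)
      Tl <- lapply(Tl, function(tg) {
        if (tg$channel == "boundary") tg$weight <- 0
        tg
      })
    warp_channels <- function(Alev, ux, uy) {
      qx <- px + as.vector(ux); qy <- py + as.vector(uy)
      mx <- Alev[1, 1] * qx + Alev[1, 2] * qy + Alev[1, 3]
      my <- Alev[2, 1] * qx + Alev[2, 2] * qy + Alev[2, 3]
      out <- list()
      for (ch in warp_set)
        out[[ch]] <- matrix(bilinear_sample(Ml[[ch]], mx, my, bgs[[ch]]),
                            dl[1], dl[2])
      if ("boundary" %in% channels) {
        # rebuild the boundary band from the warped mask: distances must be
        # measured in the fixed grid, not pulled through the deformation
        wm <- out$mask > 0.5
        out$boundary <- if (any(wm) && !all(wm)) {
          ct <- mask_contour(wm)
          exp(-distance_to_set(ct)^2 / (2 * sigma_band^2))
        } else matrix(0, dl[1], dl[2])
      }
      if (has_mask_ch)
        out$mask <- smooth_gauss(out$mask, params$mask_capture_sigma)
      out
    }
    # ---- deformable stage ----
    warped <- warp_channels(Al, u$x, u$y)
    score <- weighted_mi(warped, Tl, bins_l)
    best_u <- u; best_score <- score; stall <- 0
    trace[[length(trace) + 1]] <-
      data.frame(level = li, factor = f, iter = 0L, score = score)
    if (params$discrete_search && mean(fl) >= 4) {
      # discrete long-range capture passes at coarse levels
      for (pass in 1:2) {
        upd <- discrete_offset_update(warped, Tl, bins_l,
                                      span = max(2L, as.integer(
                                        round(16 / mean(fl)))),
                                      rbox = 2, smooth_sigma = 2)
        if (is.null(upd)) break
        cand <- list(x = smooth_gauss(u$x + upd$x,
                                      params$smoothing_sigma_field),
                     y = smooth_gauss(u$y + upd$y,
                                      params$smoothing_sigma_field))
        warped_c <- warp_channels(Al, cand$x, cand$y)
        score_c <- weighted_mi(warped_c, Tl, bins_l)
        trace[[length(trace) + 1]] <-
          data.frame(level = li, factor = f, iter = 0L, score = score_c)
        if (score_c > score) {
          u <- cand; warped <- warped_c; score <- score_c
          if (score > best_score) { best_score <- score; best_u <- u }
        } else break
      }
    }
    for (it in seq_len(iters[li])) {
      grads <- lapply(warped, image_gradient)
      fx <- matrix(0, dl[1], dl[2]); fy <- matrix(0, dl[1], dl[2])
      for (tg in Tl) {
        if (tg$weight <= 0) next
        wv <- warped[[tg$channel]]
        # boundary maps are already on a common [0, 1] scale by
        # construction, so their residual is used directly; intensity
        # channels are first remapped through the conditional mean of the
        # joint histogram (contrast-free, MI-consistent)
        virt <- if (tg$channel %in% c("boundary", "mask")) tg$image
                else matrix(cond_mean_remap(as.vector(tg$image),
                                            as.vector(wv), bins_l),
                            dl[1], dl[2])
        dyn <- diff(range(wv)) + 1e-12
        nd <- (virt - wv) / dyn
        if (!tg$channel %in% c("boundary", "mask")) {
          # residuals below the within-bin quantization scale carry no
          # alignment information; shrinking them keeps a perfectly aligned
          # pair stationary
          dz <- params$deadzone / bins_l
          nd <- sign(nd) * pmax(abs(nd) - dz, 0)
        }
        gch <- grads[[tg$channel]]
        ngx <- gch[, , 1] / dyn; ngy <- gch[, , 2] / dyn
        # the mean-gradient-energy floor keeps weak-signal regions (noise,
        # feature-map halos) from generating spurious unit-scale forces
        den <- ngx^2 + ngy^2 + nd^2 + 0.5 * mean(ngx^2 + ngy^2) + 1e-12
        sup <- if (is.null(tg$support_mask)) 1 else (tg$support_mask > 0) * 1
        # boundary bands reproject with slightly different widths under
        # deformation, which makes their raw residual force unstable at
        # full strength; they enter the force at reduced gain while keeping
        # their full weight in the selection metric
        gain <- if (tg$channel == "boundary") params$boundary_force_gain else 1
        fx <- fx + gain * tg$weight * sup * nd * ngx / den
        fy <- fy + gain * tg$weight * sup * nd * ngy / den
      }
      wsum <- sum(vapply(Tl, function(t) t$weight, numeric(1)))
      fx <- smooth_gauss(fx / wsum, params$smoothing_sigma_fluid)
      fy <- smooth_gauss(fy / wsum, params$smoothing_sigma_fluid)
      mmax <- max(sqrt(fx^2 + fy^2), 1e-12)
      stepk <- params$step * min(1, 2 / (params$step * mmax))
      u$x <- smooth_gauss(u$x + stepk * fx, params$smoothing_sigma_field)
      u$y <- smooth_gauss(u$y + stepk * fy, params$smoothing_sigma_field)
      warped <- warp_channels(Al, u$x, u$y)
      score <- weighted_mi(warped, Tl, bins_l)
      trace[[length(trace) + 1]] <-
        data.frame(level = li, factor = f, iter = it, score = score)
      if (score > best_score + params$convergence_tol * abs(best_score)) {
        best_score <- score; best_u <- u; stall <- 0
      } else stall <- stall + 1
      if (stall >= 5) break
    }
    u <- best_u
    prev_f <- mean(fl)
  }
  field <- array(c(u$x * prev_f, u$y * prev_f), c(d, 2))
  if (prev_f != 1) {
    field <- array(c(resize_bilinear(u$x, d) * prev_f,
                     resize_bilinear(u$y, d) * prev_f), c(d, 2))
  }
  out <- transform2d(d, affine = A, field = field)
  tr <- do.call(rbind, trace)
  # final full-resolution score
  g <- grid_coords(d)
  m <- tf_map(out, as.vector(g$x), as.vector(g$y))
  warped_full <- list()
  for (ch in warp_set)
    warped_full[[ch]] <- matrix(bilinear_sample(moving[[ch]], m$x, m$y,
                                                bgs[[ch]]), d[1], d[2])
  if ("boundary" %in% channels) {
    wm <- warped_full$mask > 0.5
    warped_full$boundary <- if (any(wm) && !all(wm)) {
      exp(-distance_to_set(mask_contour(wm))^2 /
            (2 * params$boundary_sigma^2))
    } else matrix(0, d[1], d[2])
  }
  if (has_mask_ch) {
    warped_full$mask <- smooth_gauss(warped_full$mask,
                                     params$mask_capture_sigma)
    targets <- lapply(targets, function(tg) {
      if (tg$channel == "mask")
        tg$image <- smooth_gauss(tg$image, params$mask_capture_sigma)
      tg
    })
  }
  attr(out, "score") <- weighted_mi(warped_full, targets, params$mi_bins)
  attr(out, "trace") <- tr
  out
}
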