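# Forward-backward, multi-stain, blockface-anchored reconstruction of the
# whole stack. Every stained section is registered to a weighted target set:
# the blockface image of its slice (the anchor, weight 1), the nearest
# previously-coregistered section of the same stain plus its boundary map
# (weight 1/2 each), and the two nearest previously-coregistered sections of
# any stain plus their boundary maps (weight 1/4 each). Sweeps run rostral
# -> caudal then caudal -> rostral; the chain is Markov-like because each
# registered section immediately refreshes the targets of the next. The
# forward-backward cycle is repeated (default three times), each time
# restarting from the per-slice best result in terms of mutual information
# against the blockface.

#' Initialize the alignment state
#'
#' @param dataset a `phantom_dataset`, or any list with `blockface` (list of
#'   blockface `section_image`s covering every slice) and `sections` (named
#'   list of `list(section, stain, slice)`).
#' @param feature_radius_range vessel radius filter passed to feature
#'   extraction (pixels).
#' @param boundary_sigma boundary-map decay in micrometers.
#' @return object of class `alignment_state`.
#' @export
init_alignment <- function(dataset, feature_radius_range = c(1.5, 6),
                           boundary_sigma = 1000) {
  bf <- dataset$blockface
  stopifnot(length(bf) > 0, length(dataset$sections) > 0)
  bf_slices <- vapply(bf, function(s) s$slice_index, integer(1))
  names(bf) <- as.character(bf_slices)
  pixel_size <- bf[[1]]$pixel_size
  d <- dim(bf[[1]]$pixels)
  # blockface masks + ventricle-scale exclusion support
  bf_support <- list()
  bf_boundary <- list()
  bf_mask <- list()
  for (nm in names(bf)) {
    m <- try(mask_background(bf[[nm]]), silent = TRUE)
    sup <- matrix(1, d[1], d[2])
    if (!inherits(m, "try-error")) {
      bf_mask[[nm]] <- m$mask + 0
      if (any(m$holes)) {
        lab <- ebi_mat(EBImage::bwlabel(EBImage::Image(m$holes * 1)))
        for (k in seq_len(max(lab))) {
          idx <- which(lab == k)
          if (sqrt(length(idx) / pi) > feature_radius_range[2] * 2)
            sup[idx] <- 0  # ventricle-scale hole: exclude from the metric
        }
      }
      bf_boundary[[nm]] <- boundary_map(m, boundary_sigma, pixel_size)
    }
    bf_support[[nm]] <- sup
  }
  sections <- list()
  for (nm in names(dataset$sections)) {
    e <- dataset$sections[[nm]]
    px <- e$section$pixels
    stopifnot(all(dim(px) == d))
    feats <- section_features(e$section, feature_radius_range,
                              boundary_sigma, pixel_size)
    if (is.null(feats))
      feats <- list(mask = NULL, boundary = matrix(0, d[1], d[2]),
                    vessel_mask = array(FALSE, d), centroids = NULL)
    mov_mask <- if (!is.null(feats$mask)) feats$mask$mask + 0
                else (abs(px - px[1, 1]) > 1e-9) + 0
    sections[[nm]] <- list(
      key = nm, stain = e$stain, slice = as.integer(e$slice),
      original = e$section,
      orig_boundary = feats$boundary,
      moving = list(image = px, mask = mov_mask),
      transform = transform2d(d),
      resampled = px,
      features = feats,
      score = -Inf, registered_once = FALSE,
      best = list(score = -Inf, transform = transform2d(d)))
  }
  structure(list(blockface = bf, bf_support = bf_support,
                 bf_boundary = bf_boundary, bf_mask = bf_mask,
                 sections = sections, dim = d, pixel_size = pixel_size,
                 feature_radius_range = feature_radius_range,
                 boundary_sigma = boundary_sigma,
                 sweep_log = data.frame(), iteration = 0L,
                 failures = character(0)),
            class = "alignment_state")
}

#' @export
print.alignment_state <- function(x, ...) {
  cat(sprintf("alignment_state: %d blockface slices, %d sections, %d sweeps run\n",
              length(x$blockface), length(x$sections), nrow(x$sweep_log)))
  invisible(x)
}

# keys of sections registered so far in the current sweep, by slice
sweep_registered <- function(state) {
  keys <- names(state$sections)
  keys[vapply(state$sections, function(s) isTRUE(s$fresh), logical(1))]
}

#' Build the weighted target set for one section
#'
#' Targets: the blockface image of the slice (weight 1, with the
#' ventricle-exclusion support mask); the nearest previously-coregistered
#' same-stain section and its boundary map (weight 1/2 each); the two
#' nearest previously-coregistered sections of any stain and their boundary
#' maps (weight 1/4 each). "Previously coregistered" means registered
#' earlier in the current sweep (so it respects the sweep direction) and
#' within a sliding window of `window` slices. Distance ties are resolved in
#' favor of the most recently refreshed section.
#'
#' @param state `alignment_state`.
#' @param slice_index slice of the section being registered.
#' @param stain its stain.
#' @param direction `"forward"` or `"backward"` (used only for
#'   documentation of intent; eligibility is tracked by the per-sweep
#'   freshness flags).
#' @param window sliding-window half-width in slices (default 3).
#' @param anchor_features also include the blockface tissue mask (channel
#'   `"mask"`, weight 1/2) and boundary band (channel `"boundary"`, weight
#'   1/2) as targets. The mask term gives contrast-free capture for
#'   sections whose stain relates non-monotonically to the blockface; set
#'   to `FALSE` for the strict image-plus-neighbor target set.
#' @param blockface_weight weight of the blockface anchor (0 drops it).
#' @return list of [weighted_target()]s.
#' @export
build_target_set <- function(state, slice_index, stain,
                             direction = c("forward", "backward"),
                             window = 3, anchor_features = TRUE,
                             blockface_weight = 1) {
  direction <- match.arg(direction)
  nm <- as.character(slice_index)
  if (is.null(state$blockface[[nm]]))
    stop("build_target_set: no blockface image for slice ", slice_index,
         " - the anchor is mandatory")
  targets <- if (blockface_weight > 0)
    list(weighted_target(state$blockface[[nm]]$pixels,
                         weight = blockface_weight, channel = "image",
                         support_mask = state$bf_support[[nm]]))
  else list()
  if (anchor_features && blockface_weight > 0) {
    if (!is.null(state$bf_mask[[nm]]))
      targets[[length(targets) + 1]] <-
        weighted_target(state$bf_mask[[nm]], weight = 0.5, channel = "mask")
    if (!is.null(state$bf_boundary[[nm]]))
      targets[[length(targets) + 1]] <-
        weighted_target(state$bf_boundary[[nm]], weight = 0.5,
                        channel = "boundary")
  }
  cand_keys <- sweep_registered(state)
  if (length(cand_keys) == 0) return(targets)
  cand <- state$sections[cand_keys]
  dist <- vapply(cand, function(s) abs(s$slice - slice_index), numeric(1))
  recency <- vapply(cand, function(s) s$fresh_rank, numeric(1))
  ok <- dist > 0 & dist <= window
  cand <- cand[ok]; dist <- dist[ok]; recency <- recency[ok]
  if (length(cand) == 0) return(targets)
  ord <- order(dist, -recency)
  add_pair <- function(targets, s, w) {
    targets[[length(targets) + 1]] <-
      weighted_target(s$resampled, weight = w, channel = "image")
    targets[[length(targets) + 1]] <-
      weighted_target(s$features$boundary, weight = w, channel = "boundary")
    targets
  }
  same <- ord[vapply(cand[ord], function(s) s$stain == stain, logical(1))]
  used <- character(0)
  if (length(same) > 0) {
    s <- cand[[same[1]]]
    targets <- add_pair(targets, s, 0.5)
    used <- s$key
  }
  any_ord <- ord[!vapply(cand[ord], function(s) s$key %in% used, logical(1))]
  for (j in utils::head(any_ord, 2)) {
    targets <- add_pair(targets, cand[[j]], 0.25)
  }
  targets
}

# refresh a section's resampled image, features, and archive score.
# The archive score is the blockface MI plus a boundary-agreement term
# (correlation of the blockface boundary band with the section's): MI alone
# can reward degenerate warps that collapse a stain's classes, and the
# boundary term vetoes those without changing the MI-based ranking among
# honest candidates.
refresh_section <- function(state, key, mi_bins = 32) {
  s <- state$sections[[key]]
  bg <- s$original$pixels[1, 1]
  s$resampled <- apply_transform(s$original$pixels, s$transform,
                                 background = bg)
  feats <- section_features(section_image(s$resampled, state$pixel_size,
                                          s$stain, s$slice),
                            state$feature_radius_range, state$boundary_sigma,
                            state$pixel_size)
  if (!is.null(feats)) s$features <- feats
  # the moving image/mask channels stay in the section's native geometry
  # (computed once at init); only target-side features are refreshed here
  nm <- as.character(s$slice)
  s$score <- mutual_information(state$blockface[[nm]]$pixels, s$resampled,
                                mi_bins, state$bf_support[[nm]])
  bfb <- state$bf_boundary[[nm]]
  if (!is.null(bfb) && !is.null(feats) &&
      stats::sd(feats$boundary) > 1e-12) {
    s$score <- s$score +
      0.5 * stats::cor(as.vector(bfb), as.vector(feats$boundary))
  }
  if (s$score > s$best$score)
    s$best <- list(score = s$score, transform = s$transform)
  state$sections[[key]] <- s
  state
}

#' Run one forward or backward sweep over the stack
#'
#' Slices are visited in direction order; each section is registered against
#' [build_target_set()] output and the state is updated in place, so later
#' slices immediately see refreshed neighbors. Registration failures are
#' recorded and the sweep continues (damaged-slice tolerance).
#'
#' @param state `alignment_state`.
#' @param direction `"forward"` (rostral -> caudal) or `"backward"`.
#' @param params [registration_params()].
#' @param window sliding-window half-width (slices).
#' @param anchor_features include the blockface mask/boundary targets (see
#'   [build_target_set()]).
#' @param rescue_params optional [registration_params()] used for sections
#'   flagged for a fresh restart (`rescue`).
#' @param blockface_weight weight of the blockface anchor target; 0 gives
#'   the neighbors-only ablation that exhibits the banana effect.
#' @return updated `alignment_state`.
#' @export
sweep_stack <- function(state, direction = c("forward", "backward"),
                        params = registration_params(), window = 3,
                        anchor_features = TRUE, rescue_params = NULL,
                        blockface_weight = 1) {
  direction <- match.arg(direction)
  for (k in names(state$sections)) {
    state$sections[[k]]$fresh <- FALSE
    state$sections[[k]]$fresh_rank <- 0
  }
  slices <- sort(unique(vapply(state$sections, function(s) s$slice,
                               integer(1))),
                 decreasing = (direction == "backward"))
  rank <- 0
  t0 <- proc.time()[3]
  for (sl in slices) {
    keys <- names(state$sections)[vapply(state$sections,
                                         function(s) s$slice == sl,
                                         logical(1))]
    for (k in keys) {
      s <- state$sections[[k]]
      targets <- build_target_set(state, sl, s$stain, direction, window,
                                  anchor_features, blockface_weight)
      rescuing <- isTRUE(s$rescue) && !is.null(rescue_params)
      if (rescuing && !is.null(state$bf_mask[[as.character(sl)]])) {
        # extra rescue attempt in the reverse direction: for strongly
        # compressive section distortions the blockface side keeps intact
        # gradients, so registering blockface -> section and inverting can
        # reach basins the forward direction cannot; the best-score
        # archive keeps whichever attempt wins
        nm_sl <- as.character(sl)
        mv_rev <- list(image = state$blockface[[nm_sl]]$pixels,
                       mask = state$bf_mask[[nm_sl]])
        tg_rev <- list(weighted_target(s$moving$image, 1),
                       weighted_target(s$moving$mask, 0.5,
                                       channel = "mask"),
                       weighted_target(s$orig_boundary, 0.5,
                                       channel = "boundary"))
        rb <- tryCatch(register_pair(mv_rev, tg_rev, rescue_params),
                       error = function(e) NULL)
        if (!is.null(rb)) {
          state$sections[[k]]$transform <- invert_transform(rb)
          state$sections[[k]]$registered_once <- TRUE
          state <- refresh_section(state, k, params$mi_bins)
          s <- state$sections[[k]]
        }
        # a fresh forward restart under the exploratory schedule
        rh <- tryCatch(register_pair(s$moving, targets, rescue_params),
                       error = function(e) NULL)
        if (!is.null(rh)) {
          state$sections[[k]]$transform <- rh
          state$sections[[k]]$registered_once <- TRUE
          state <- refresh_section(state, k, params$mi_bins)
          s <- state$sections[[k]]
        }
      }
      res <- tryCatch(
        register_pair(s$moving, targets, params,
                      init = if (s$registered_once) s$transform else NULL),
        error = function(e) e)
      state$sections[[k]]$rescue <- FALSE
      if (inherits(res, "error")) {
        state$failures <- c(state$failures,
                            sprintf("%s (%s sweep): %s", k, direction,
                                    conditionMessage(res)))
      } else {
        state$sections[[k]]$transform <- res
        state$sections[[k]]$registered_once <- TRUE
      }
      rank <- rank + 1
      state$sections[[k]]$fresh <- TRUE
      state$sections[[k]]$fresh_rank <- rank
      state <- refresh_section(state, k, params$mi_bins)
    }
  }
  state$sweep_log <- rbind(state$sweep_log,
                           data.frame(iteration = state$iteration,
                                      direction = direction,
                                      mean_score = mean(vapply(
                                        state$sections,
                                        function(s) s$score, numeric(1))),
                                      seconds = proc.time()[3] - t0))
  state
}

# revert every section to its archived best-MI transform
revert_to_best <- function(state, mi_bins = 32) {
  for (k in names(state$sections)) {
    b <- state$sections[[k]]$best
    if (is.finite(b$score)) {
      state$sections[[k]]$transform <- b$transform
      state <- refresh_section(state, k, mi_bins)
    }
  }
  state
}

#' Run the full iterated forward-backward reconstruction
#'
#' Executes `n_iterations` forward-backward cycles (two sweeps each). After
#' each sweep, every section reverts to its archived best result in terms of
#' mutual information against the blockface before seeding the next sweep,
#' so the per-slice best score never decreases.
#'
#' @param dataset input accepted by [init_alignment()], or an existing
#'   `alignment_state` to continue from.
#' @param params [registration_params()]; the default uses a tapering
#'   iteration schedule suited to repeated sweeps.
#' @param n_iterations number of forward-backward cycles (default 3).
#' @param window sliding-window half-width (slices).
#' @param refine_iterations iteration schedule used from the second sweep
#'   on, when every section starts from an already-good transform.
#' @param anchor_features include the blockface mask/boundary feature
#'   targets (see [build_target_set()]).
#' @param rescue_params more exploratory [registration_params()] used to
#'   restart trailing sections from scratch in later iterations.
#' @param rescue_fraction quantile of the archived best scores below which
#'   a section is restarted (0 disables rescues).
#' @param polish run a final anchor-only refinement pass (accepted per
#'   section only when it improves the anchor score).
#' @return final `alignment_state`; `$sweep_log` has one row per sweep
#'   (`2 * n_iterations` rows), `$failures` lists sections whose
#'   registration failed.
#' @export
run_reconstruction <- function(dataset,
                               params = registration_params(
                                 iterations_per_scale = c(30, 20, 15, 10, 6)),
                               n_iterations = 3, window = 3,
                               refine_iterations = c(15, 12, 10, 8, 6),
                               anchor_features = TRUE,
                               rescue_params = registration_params(
                                 iterations_per_scale = c(30, 40, 60, 30, 10),
                                 step = 2.2, smoothing_sigma_field = 1,
                                 smoothing_sigma_fluid = 2.5,
                                 mask_capture_sigma = 4, deadzone = 0.75),
                               rescue_fraction = 0.3, polish = TRUE) {
  state <- if (inherits(dataset, "alignment_state")) dataset
           else init_alignment(dataset)
  refine <- params
  refine$iterations_per_scale <- refine_iterations
  for (it in seq_len(n_iterations)) {
    state$iteration <- it
    if (it > 1 && rescue_fraction > 0) {
      # sections whose archived best score trails the field restart from a
      # fresh affine stage under a more exploratory schedule, now with
      # well-registered neighbors as targets; the best-MI archive keeps
      # whichever result wins
      scores <- vapply(state$sections, function(s) s$best$score, numeric(1))
      low <- scores <= stats::quantile(scores, rescue_fraction)
      for (k in names(state$sections)[low])
        state$sections[[k]]$rescue <- TRUE
    }
    state <- sweep_stack(state, "forward",
                         if (it == 1) params else refine, window,
                         anchor_features, rescue_params = rescue_params)
    state <- revert_to_best(state, params$mi_bins)
    state <- sweep_stack(state, "backward", refine, window, anchor_features,
                         rescue_params = rescue_params)
    state <- revert_to_best(state, params$mi_bins)
  }
  if (polish) {
    # final anchor-only refinement: neighbor targets guide the search but
    # carry their own residual errors, so the last word goes to the
    # blockface reference; the best-score archive only accepts
    # improvements in anchor agreement
    for (k in names(state$sections)) {
      state$sections[[k]]$fresh <- FALSE
      state$sections[[k]]$fresh_rank <- 0
    }
    pol <- params
    pol$iterations_per_scale <- c(2, 3, 6, 10, 16)
    for (k in names(state$sections)) {
      s <- state$sections[[k]]
      targets <- build_target_set(state, s$slice, s$stain, "forward",
                                  window, anchor_features)
      res <- tryCatch(register_pair(s$moving, targets, pol,
                                    init = s$transform),
                      error = function(e) NULL)
      if (!is.null(res)) {
        # a polish is a local refinement: large excursions are basin
        # changes that must not bypass the neighbor-constrained search
        g <- grid_coords(state$dim)
        m_new <- tf_map(res, as.vector(g$x), as.vector(g$y))
        m_old <- tf_map(s$transform, as.vector(g$x), as.vector(g$y))
        drift <- mean(sqrt((m_new$x - m_old$x)^2 + (m_new$y - m_old$y)^2))
        if (drift < 2.5) {
          state$sections[[k]]$transform <- res
          state <- refresh_section(state, k, params$mi_bins)
        }
      }
    }
    state <- revert_to_best(state, params$mi_bins)
  }
  scores <- vapply(state$sections, function(s) s$best$score, numeric(1))
  state$low_score_sections <-
    names(scores)[scores < stats::quantile(scores, 0.05)]
  state
}

#' Inject a sinusoidal bending into the current transforms
#'
#' Replaces every section's transform by a pure translation following a
#' sine along the slice axis — the smooth global curvature ("banana
#' effect") that sequential slice-to-slice registration can introduce when
#' no 3D reference anchors the stack. Used to probe whether the blockface
#' anchor removes such bending.
#'
#' @param state `alignment_state`.
#' @param amplitude peak translation in pixels.
#' @param axis 1 (x) or 2 (y).
#' @return state with bent transforms (marked as already registered, so
#'   sweeps refine rather than restart).
#' @export
inject_bending <- function(state, amplitude = 6, axis = 1) {
  nz <- length(state$blockface)
  for (k in names(state$sections)) {
    s <- state$sections[[k]]
    shift <- c(0, 0)
    shift[axis] <- amplitude * sin(2 * pi * s$slice / nz)
    state$sections[[k]]$transform <-
      transform2d(state$dim, affine = cbind(diag(2), shift))
    state$sections[[k]]$registered_once <- TRUE
    state$sections[[k]]$best <- list(score = -Inf,
                                     transform = state$sections[[k]]$transform)
    state <- refresh_section(state, k)
  }
  state
}

#' RMS deviation of the reconstruction's centroid curve from the blockface
#'
#' Per slice, compares the tissue centroid of each registered section with
#' the centroid of the blockface tissue mask; global smooth deviations of
#' this curve are the signature of the banana effect.
#'
#' @param state `alignment_state`.
#' @return RMS deviation in in-plane voxels, with attribute `per_section`.
#' @export
centroid_deviation <- function(state) {
  devs <- c()
  for (k in names(state$sections)) {
    s <- state$sections[[k]]
    nm <- as.character(s$slice)
    bfm <- state$bf_mask[[nm]]
    if (is.null(bfm)) next
    m <- s$features$mask
    if (is.null(m) || !any(m$mask)) next
    ij <- which(m$mask, arr.ind = TRUE)
    cb <- which(bfm > 0, arr.ind = TRUE)
    devs[k] <- sqrt(sum((colMeans(ij) - colMeans(cb))^2))
  }
  out <- sqrt(mean(devs^2))
  attr(out, "per_section") <- devs
  out
}
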