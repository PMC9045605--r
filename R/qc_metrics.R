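# Reconstruction quality control: interslice boundary and vessel distances,
# within and across markers, with per-marker means and outlier flagging.

#' Symmetric mean contour distance between two masks
#'
#' Average over the points of each contour of the Euclidean distance to the
#' nearest point of the other contour, averaged over both directions and
#' scaled to micrometers. The directed Hausdorff maximum is returned as an
#' attribute.
#'
#' @param a,b binary masks (or `tissue_mask`) on the same grid.
#' @param pixel_size micrometers per pixel.
#' @return distance in micrometers, with attribute `hausdorff`.
#' @export
boundary_distance <- function(a, b, pixel_size = 200) {
  if (inherits(a, "tissue_mask")) a <- a$mask
  if (inherits(b, "tissue_mask")) b <- b$mask
  ca <- mask_contour(a); cb <- mask_contour(b)
  if (!any(ca) || !any(cb))
    stop("boundary_distance: empty contour")
  da <- distance_to_set(cb)[ca]  # distances from contour-A points to B
  db <- distance_to_set(ca)[cb]
  out <- (mean(da) + mean(db)) / 2 * pixel_size
  attr(out, "hausdorff") <- max(max(da), max(db)) * pixel_size
  out
}

#' Mean matched vessel-centroid distance between two sections
#'
#' Greedy mutual-nearest matching under a distance ceiling; the mean is
#' taken over matched pairs only.
#'
#' @param centroids_a,centroids_b data.frames with columns `x`, `y` (pixels).
#' @param max_match maximum match distance in micrometers.
#' @param pixel_size micrometers per pixel.
#' @return `list(distance, n_matches)`; distance is `NA` when nothing
#'   matches.
#' @export
vessel_distance <- function(centroids_a, centroids_b, max_match = 1000,
                            pixel_size = 200) {
  na <- nrow(centroids_a); nb <- nrow(centroids_b)
  if (is.null(na) || is.null(nb) || na == 0 || nb == 0)
    return(list(distance = NA_real_, n_matches = 0L))
  D <- outer(centroids_a$x, centroids_b$x, `-`)^2 +
       outer(centroids_a$y, centroids_b$y, `-`)^2
  D <- sqrt(D) * pixel_size
  D[D > max_match] <- Inf
  matches <- numeric(0)
  while (any(is.finite(D))) {
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    matches <- c(matches, D[ij[1], ij[2]])
    D[ij[1], ] <- Inf
    D[, ij[2]] <- Inf
  }
  if (length(matches) == 0) return(list(distance = NA_real_, n_matches = 0L))
  list(distance = mean(matches), n_matches = length(matches))
}

#' Interslice QC profile of a reconstructed stack
#'
#' For consecutive measured slice pairs, within each marker and across
#' markers (each section against the nearest following section of a
#' different stain), computes the symmetric mean boundary distance and the
#' matched vessel-centroid distance. Blockface features are excluded from
#' QC. Records whose boundary distance exceeds `flag_threshold` are flagged
#' (missing-structure outliers).
#'
#' @param state completed `alignment_state`.
#' @param max_match vessel match ceiling (micrometers).
#' @param flag_threshold boundary-distance flag level in micrometers
#'   (default 2000 um = 2 mm).
#' @return `list(records, summary, flagged)`: `records` is a data.frame
#'   (slice_index, stain_a, stain_b, kind, boundary_distance_um,
#'   hausdorff_um, vessel_distance_um, n_vessel_matches), `summary` the
#'   per-marker mean within-marker distances, `flagged` the outlier rows.
#' @export
qc_profile <- function(state, max_match = 1000, flag_threshold = 2000) {
  ps <- state$pixel_size
  secs <- state$sections
  info <- data.frame(key = names(secs),
                     stain = vapply(secs, function(s) s$stain, character(1)),
                     slice = vapply(secs, function(s) s$slice, integer(1)),
                     stringsAsFactors = FALSE)
  has_mask <- vapply(secs, function(s)
    !is.null(s$features$mask) && any(s$features$mask$mask), logical(1))
  info <- info[has_mask[info$key], ]
  rec <- list()
  pair_record <- function(ka, kb, kind) {
    sa <- secs[[ka]]; sb <- secs[[kb]]
    bd <- tryCatch(boundary_distance(sa$features$mask, sb$features$mask, ps),
                   error = function(e) NULL)
    if (is.null(bd)) return(NULL)
    vd <- vessel_distance(sa$features$centroids, sb$features$centroids,
                          max_match, ps)
    data.frame(slice_index = sa$slice, stain_a = sa$stain, stain_b = sb$stain,
               kind = kind, boundary_distance_um = as.numeric(bd),
               hausdorff_um = attr(bd, "hausdorff"),
               vessel_distance_um = vd$distance,
               n_vessel_matches = vd$n_matches)
  }
  for (st in unique(info$stain)) {
    sub <- info[info$stain == st, ]
    sub <- sub[order(sub$slice), ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1))
      rec[[length(rec) + 1]] <- pair_record(sub$key[i], sub$key[i + 1],
                                            "within")
  }
  ord <- info[order(info$slice), ]
  for (i in seq_len(nrow(ord))) {
    later <- ord[ord$slice > ord$slice[i] & ord$stain != ord$stain[i], ]
    if (nrow(later) == 0) next
    j <- which.min(later$slice)
    rec[[length(rec) + 1]] <- pair_record(ord$key[i], later$key[j], "across")
  }
  records <- do.call(rbind, rec)
  summary <- do.call(rbind, lapply(split(records[records$kind == "within", ],
                                         records$stain_a[records$kind == "within"]),
                                   function(g)
    data.frame(stain = g$stain_a[1], n_pairs = nrow(g),
               mean_boundary_um = mean(g$boundary_distance_um),
               mean_vessel_um = mean(g$vessel_distance_um, na.rm = TRUE))))
  rownames(summary) <- NULL
  list(records = records, summary = summary,
       flagged = records[records$boundary_distance_um > flag_threshold, ])
}

#' Plot the interslice distance profile per marker
#'
#' Distance versus slice index, one panel line per marker, with horizontal
#' per-marker mean lines and the flag threshold.
#'
#' @param qc result of [qc_profile()].
#' @param flag_threshold threshold line (micrometers).
#' @param file optional PDF path; plotted to the active device otherwise.
#' @export
qc_plot <- function(qc, flag_threshold = 2000, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 5)
    on.exit(grDevices::dev.off())
  }
  w <- qc$records[qc$records$kind == "within", ]
  stains <- unique(w$stain_a)
  cols <- grDevices::hcl.colors(max(3, length(stains)), "Dark 3")
  graphics::plot(NA, xlim = range(w$slice_index),
                 ylim = c(0, max(w$boundary_distance_um, flag_threshold) * 1.05),
                 xlab = "slice index", ylab = "boundary distance (um)",
                 main = "Interslice distance per marker")
  for (i in seq_along(stains)) {
    g <- w[w$stain_a == stains[i], ]
    graphics::lines(g$slice_index, g$boundary_distance_um, col = cols[i])
    graphics::abline(h = mean(g$boundary_distance_um), col = cols[i],
                     lty = 3)
  }
  graphics::abline(h = flag_threshold, col = "grey40", lty = 2)
  graphics::legend("topleft", legend = stains, col = cols[seq_along(stains)],
                   lty = 1, bty = "n", cex = 0.8)
  invisible(qc)
}
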