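#' A labeled voxel mask
#'
#' Integer labels over a voxel grid (0 = background), same shape and spacing
#' as the volume it was derived from. Labels are contiguous positive
#' integers ordered by first occurrence in array scan order, which makes
#' segmentations deterministic.
#'
#' @param labels Integer 3D array.
#' @param spacing um per axis.
#' @return Object of class `labeled_mask`.
#' @export
labeled_mask <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3D integer array.")
  }
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(labels = labels, spacing = check_spacing(spacing),
                 label_ids = as.integer(ids)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_mask> %d x %d x %d voxels, %d object(s), spacing %s um\n",
              d[1], d[2], d[3], length(x$label_ids),
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

# Otsu's threshold on a 256-bin histogram (maximizes between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    as.integer((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins),
    nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 26-connectivity components of a logical 3D array via an igraph over the
# foreground voxel adjacency; returns an integer label array with labels
# ordered by each component's first voxel in scan order.
label_components_26 <- function(fg) {
  dims <- dim(fg)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- which(fg)
  labels <- array(0L, dims)
  if (!length(idx)) return(labels)
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  ai <- arrayInd(idx, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[order(offsets[, 1] + offsets[, 2] * 3 + offsets[, 3] * 9), ]
  offsets <- offsets[offsets[, 3] > 0 |
                     (offsets[, 3] == 0 & (offsets[, 2] > 0 |
                      (offsets[, 2] == 0 & offsets[, 1] > 0))), , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    ok <- ai[, 1] + o[1] >= 1L & ai[, 1] + o[1] <= nx &
          ai[, 2] + o[2] >= 1L & ai[, 2] + o[2] <= ny &
          ai[, 3] + o[3] >= 1L & ai[, 3] + o[3] <= nz
    if (!any(ok)) next
    from <- idx[ok]
    to <- from + o[1] + o[2] * nx + o[3] * nx * ny
    hit <- fg[to]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- cbind(rank[from[hit]], rank[to[hit]])
  }
  n <- length(idx)
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(n)
  }
  # relabel by first occurrence in scan order (idx is already sorted)
  first_seen <- match(memb, unique(memb))
  labels[idx] <- first_seen
  labels
}

#' Segment foreground objects from a fluorescence volume
#'
#' Thresholds the volume (Otsu's method on a 256-bin histogram, or a fixed
#' threshold), labels connected components with 26-connectivity, and removes
#' objects smaller than a minimum physical volume to suppress noise specks.
#'
#' @param volume A [voxel_volume()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Intensity threshold, required when `method = "fixed"`.
#' @param min_volume Minimum object volume retained, um^3. The default
#'   (65 um^3, about a 2.5 um-radius sphere) is well below a cell body.
#' @return A [labeled_mask()]; empty (all zero) with a warning when nothing
#'   exceeds the threshold.
#' @export
segment_foreground <- function(volume, method = c("otsu", "fixed"),
                               threshold = NULL, min_volume = 65) {
  stopifnot(inherits(volume, "voxel_volume"))
  method <- match.arg(method)
  if (method == "fixed" && is.null(threshold)) {
    abort("`threshold` must be supplied when method = 'fixed'.")
  }
  thr <- if (method == "otsu") otsu_threshold(volume$intensities) else threshold
  fg <- volume$intensities > thr
  if (!any(fg)) {
    warn("segmentation found no foreground voxels; returning an empty mask.")
    return(labeled_mask(array(0L, dim(volume$intensities)), volume$spacing))
  }
  labels <- label_components_26(fg)
  voxvol <- prod(volume$spacing)
  counts <- tabulate(labels[labels > 0L])
  keep <- which(counts * voxvol >= min_volume)
  if (!length(keep)) {
    warn("all segmented objects fell below `min_volume`; returning an empty mask.")
    return(labeled_mask(array(0L, dim(volume$intensities)), volume$spacing))
  }
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  pos <- labels > 0L
  out[pos] <- relab[labels[pos]]
  labeled_mask(out, volume$spacing)
}

# voxel counts per label id
label_sizes <- function(mask) {
  tabulate(mask$labels[mask$labels > 0L], nbins = max(mask$label_ids, 0L))
}

#' Crop a mask at the widest point of the spheroid
#'
#' Single-photon imaging cannot resolve tissue past the widest point of a
#' dense spheroid, so analysis is restricted to the slab between the imaging
#' face (z = 0) and the z-slice where the spheroid's cross-sectional area is
#' maximal (ties broken toward the imaging face). The spheroid is taken as
#' the largest-volume component.
#'
#' @param mask A [labeled_mask()].
#' @return List with `mask` (the cropped [labeled_mask()]) and `z_depth`,
#'   the physical distance (um) between the imaging face and the widest
#'   plane.
#' @export
crop_at_widest <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (!length(mask$label_ids)) abort("`mask` is empty; nothing to crop.")
  sizes <- label_sizes(mask)
  sph <- spheroid_label(mask, sizes)
  sl <- mask$labels == sph
  per_slice <- apply(sl, 3, sum)
  k <- which.max(per_slice) # which.max takes the first maximum: face-ward tie
  cropped <- mask$labels[, , seq_len(k), drop = FALSE]
  list(mask = labeled_mask(cropped, mask$spacing),
       z_depth = (k - 1) * mask$spacing[3])
}

spheroid_label <- function(mask, sizes = label_sizes(mask)) {
  mx <- max(sizes)
  cand <- which(sizes == mx)
  if (length(cand) > 1L) {
    warn(sprintf("two or more components tie for largest volume; using label %d.",
                 cand[1]))
  }
  cand[1]
}

#' Split a mask into the spheroid mass and candidate escaped cells
#'
#' The largest-volume component is the spheroid (lowest label wins a tie,
#' with a warning); every remaining component is a candidate escaped or
#' escaping cell, relabeled contiguously.
#'
#' @param mask A [labeled_mask()].
#' @return List with `spheroid` (a [labeled_mask()] holding a single label)
#'   and `cells` (a [labeled_mask()] of the remaining components).
#' @export
split_spheroid_and_cells <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (!length(mask$label_ids)) abort("`mask` is empty; nothing to split.")
  sph <- spheroid_label(mask)
  sph_arr <- array(0L, dim(mask$labels))
  sph_arr[mask$labels == sph] <- 1L
  cells <- mask$labels
  cells[cells == sph] <- 0L
  old <- sort(unique(cells[cells > 0L]))
  if (length(old)) {
    remap <- integer(max(old))
    remap[old] <- seq_along(old)
    pos <- cells > 0L
    cells[pos] <- remap[cells[pos]]
  }
  list(spheroid = labeled_mask(sph_arr, mask$spacing),
       cells = labeled_mask(cells, mask$spacing))
}

#' Build a smoothed reference surface around the spheroid
#'
#' Invasion distances should reflect how far a cell has travelled from the
#' bulk spheroid core, not from elongated invasive cells still attached to
#' the periphery. The reference is therefore the spheroid mask with
#' protrusions thinner than `smoothing_scale` removed (morphological opening
#' with a ball of that radius) and concavities of the same scale filled
#' (closing), both spacing-aware.
#'
#' @param spheroid_mask A [labeled_mask()] holding the spheroid component.
#' @param smoothing_scale Ball radius in um; 0 returns the raw surface.
#' @return Object of class `reference_surface`: the smoothed mask, its
#'   surface voxels and the spacing.
#' @export
smoothed_reference_surface <- function(spheroid_mask, smoothing_scale = 10) {
  stopifnot(inherits(spheroid_mask, "labeled_mask"))
  if (smoothing_scale < 0) abort("`smoothing_scale` must be >= 0.")
  m <- spheroid_mask$labels > 0L
  if (!any(m)) abort("spheroid mask is empty.")
  sp <- spheroid_mask$spacing
  if (smoothing_scale > 0) {
    m <- close_ball(open_ball(m, sp, smoothing_scale), sp, smoothing_scale)
  }
  structure(list(mask = m, spacing = sp, surface = surface_voxels(m)),
            class = "reference_surface")
}

#' @export
print.reference_surface <- function(x, ...) {
  cat(sprintf("<reference_surface> %d surface voxel(s), spacing %s um\n",
              sum(x$surface), paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Mean fluorescence intensity over a labeled object
#'
#' Arithmetic mean of a channel's intensities over the voxels of one label;
#' the per-surface statistic used to quantify protein expression in
#' immunofluorescence stacks.
#'
#' @param label_id Label to measure.
#' @param mask A [labeled_mask()].
#' @param channel A [voxel_volume()] of the same shape.
#' @return Mean intensity (scalar).
#' @export
mean_intensity <- function(label_id, mask, channel) {
  stopifnot(inherits(mask, "labeled_mask"), inherits(channel, "voxel_volume"))
  if (!identical(dim(mask$labels), dim(channel$intensities))) {
    abort("`channel` must have the same voxel grid as `mask`.")
  }
  sel <- mask$labels == label_id
  if (!any(sel)) abort(sprintf("label %s not present in mask.", label_id))
  mean(channel$intensities[sel])
}
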