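#' Wadell sphericity
#'
#' \deqn{\Psi = \pi^{1/3} (6 V_p)^{2/3} / A_p}
#'
#' Dimensionless in (0, 1]: the ratio of the surface area of a sphere with
#' the object's volume to the object's actual surface area. Exactly 1 for a
#' sphere; strictly below 1 for everything else (isoperimetric inequality).
#'
#' @param V_p Object volume, um^3 (> 0).
#' @param A_p Object surface area, um^2 (> 0).
#' @return Sphericity (vectorized over inputs).
#' @export
sphericity <- function(V_p, A_p) {
  if (any(V_p <= 0) || any(A_p <= 0)) {
    abort("`V_p` and `A_p` must be positive.")
  }
  pi^(1 / 3) * (6 * V_p)^(2 / 3) / A_p
}

#' Estimated spheroid volume from the mean radius
#'
#' The periphery ellipse radii at the widest (`a`) and narrowest (`b`)
#' points and the imaging depth `z` are averaged into a mean radius
#' \eqn{r = (a + b + z)/3}, and the spheroid volume is estimated as the
#' volume of the sphere with that radius, \eqn{V = \frac{4}{3}\pi r^3}.
#'
#' @param a,b Ellipse radii, um (a at the widest point).
#' @param z Imaging depth (face to widest plane), um.
#' @return A list with `r` (um) and `V` (um^3).
#' @export
estimate_spheroid_volume <- function(a, b, z) {
  if (any(c(a, b, z) <= 0)) abort("`a`, `b` and `z` must be positive.")
  r <- (a + b + z) / 3
  list(r = r, V = 4 / 3 * pi * r^3)
}

#' Spherical-cap surface area of the imaged hemispheroid
#'
#' \deqn{SA = \pi (e^2 + z^2)}
#'
#' The lateral area of a spherical cap with base radius `e` (the mean
#' ellipsoid axis, \eqn{(a+b)/2}) and height `z` (the imaging depth). With
#' `z = e` this reduces to the hemisphere area \eqn{2\pi e^2}. Used to
#' normalize escaped-cell counts to the imaged spheroid surface.
#'
#' @param e Mean ellipsoid axis, um.
#' @param z Imaging depth, um.
#' @return Surface area, um^2 (vectorized).
#' @export
cap_surface_area <- function(e, z) {
  if (any(e < 0) || any(z < 0)) abort("`e` and `z` must be >= 0.")
  if (any(e + z == 0)) abort("`e` and `z` must not both be 0.")
  pi * (e^2 + z^2)
}

#' Fit an ellipse to the spheroid periphery at one z-slice
#'
#' Direct least-squares conic (ellipse-specific Fitzgibbon) fit to the
#' boundary pixels of the slice mask, returning the semi-axes in physical
#' units: `a` is the radius at the widest point, `b` at the narrowest.
#'
#' @param slice Logical or 0/1 2D matrix (the spheroid at the widest slice).
#' @param spacing um per axis for x and y (length 2).
#' @return List with `a`, `b` (um, a >= b) and `center` (um).
#' @export
fit_periphery_ellipse <- function(slice, spacing) {
  if (length(spacing) != 2L || any(spacing <= 0)) {
    abort("`spacing` must be two positive values (x, y um).")
  }
  m <- slice > 0
  if (!any(m)) abort("slice is empty; cannot fit an ellipse.")
  # boundary pixels: foreground with a 4-neighbor background or on the edge
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  core <- pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] &
    pad[1:nrow(m), 2:(ncol(m) + 1L)] & pad[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)] &
    pad[2:(nrow(m) + 1L), 1:ncol(m)] & pad[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)]
  bnd <- which(m & !core, arr.ind = TRUE)
  if (nrow(bnd) < 5L) abort("fewer than 5 boundary points; cannot fit an ellipse.")
  x <- (bnd[, 1] - 1) * spacing[1]
  y <- (bnd[, 2] - 1) * spacing[2]
  fit <- fit_ellipse_direct(x, y)
  if (is.null(fit) || any(!is.finite(c(fit$a, fit$b)))) {
    abort("degenerate boundary; ellipse fit failed.")
  }
  # boundary pixel centers lie inside the continuous contour by about half
  # a pixel along the normal; debias the semi-axes accordingly
  half_px <- mean(spacing) / 2
  fit$a <- fit$a + half_px
  fit$b <- fit$b + half_px
  fit
}

# Fitzgibbon, Pilu & Fisher direct least-squares ellipse fit.
fit_ellipse_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sx <- max(stats::sd(x), 1e-9); sy <- max(stats::sd(y), 1e-9)
  xs <- (x - mx) / sx; ys <- (y - my) / sy
  D <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  S <- crossprod(D)
  C <- matrix(0, 6, 6)
  C[1, 3] <- 2; C[3, 1] <- 2; C[2, 2] <- -1
  Si <- tryCatch(solve(S, C), error = function(e) NULL)
  if (is.null(Si)) return(NULL)
  eg <- eigen(Si)
  ev <- Re(eg$values)
  vecs <- Re(eg$vectors)
  # the ellipse solution has 4ac - b^2 > 0
  ok <- which(apply(vecs, 2, function(v) 4 * v[1] * v[3] - v[2]^2) > 0 &
                is.finite(ev))
  if (!length(ok)) return(NULL)
  v <- vecs[, ok[which.max(ev[ok])]]
  # un-normalize conic coefficients
  A <- v[1] / sx^2; B <- v[2] / (sx * sy); Cc <- v[3] / sy^2
  Dd <- v[4] / sx - 2 * v[1] * mx / sx^2 - v[2] * my / (sx * sy)
  Ee <- v[5] / sy - 2 * v[3] * my / sy^2 - v[2] * mx / (sx * sy)
  Ff <- v[6] + v[1] * mx^2 / sx^2 + v[3] * my^2 / sy^2 +
    v[2] * mx * my / (sx * sy) - v[4] * mx / sx - v[5] * my / sy
  conic_to_axes(A, B, Cc, Dd, Ee, Ff)
}

conic_to_axes <- function(A, B, C, D, E, F) {
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  t1 <- num / (den * (s - (A + C)))
  t2 <- num / (den * (-s - (A + C)))
  ax <- sqrt(c(t1, t2))
  list(a = max(ax), b = min(ax), center = c(x0, y0))
}

#' Assemble spheroid geometry at one timepoint
#'
#' Combines the periphery-ellipse radii and the imaging depth into the
#' derived quantities used throughout the invasion analysis: mean radius
#' `r = (a+b+z)/3`, mean ellipsoid axis `e = (a+b)/2`, estimated volume
#' `V = 4/3 pi r^3` and spherical-cap surface area `SA = pi (e^2 + z^2)`.
#'
#' @param a,b Ellipse radii, um (`a >= b`; swapped with a warning if not).
#' @param z Imaging depth, um.
#' @return One-row tibble of class `spheroid_geometry`.
#' @export
spheroid_geometry <- function(a, b, z) {
  if (any(c(a, b, z) <= 0)) abort("`a`, `b` and `z` must be positive.")
  if (b > a) {
    warn("`b` > `a`; swapping so that `a` is the widest radius.")
    tmp <- a; a <- b; b <- tmp
  }
  est <- estimate_spheroid_volume(a, b, z)
  e <- (a + b) / 2
  out <- tibble(a = a, b = b, z = z, e = e, r = est$r, V = est$V,
                SA = cap_surface_area(e, z))
  class(out) <- c("spheroid_geometry", class(out))
  out
}

# Bounding-box indices of a label, padded, clamped to the volume.
label_bbox <- function(arr, label_id, pad) {
  w <- which(arr == label_id)
  if (!length(w)) return(NULL)
  ai <- arrayInd(w, dim(arr))
  lapply(1:3, function(ax) {
    lo <- max(1L, min(ai[, ax]) - pad)
    hi <- min(dim(arr)[ax], max(ai[, ax]) + pad)
    lo:hi
  })
}

#' Measure volume and surface area of one labeled object
#'
#' Volume is voxel count times physical voxel volume. Surface area comes
#' from a spacing-aware marching-tetrahedra mesh of the object's indicator
#' field, Gaussian-smoothed by about one voxel per axis so the mesh tracks
#' the underlying smooth surface rather than the voxel staircase; the iso
#' level is chosen per object so the enclosed voxel count matches the
#' object's (volume-matched), cancelling the shrinkage smoothing would
#' otherwise cause on small cells. Objects touching the volume border are
#' measured with a warning (the mesh is closed at the border).
#'
#' @param label_id Label to measure.
#' @param mask A [labeled_mask()].
#' @param smooth_sigma Per-axis Gaussian sigma in um used before meshing;
#'   default one voxel per axis.
#' @return List with `V_p` (um^3) and `A_p` (um^2).
#' @export
measure_object <- function(label_id, mask, smooth_sigma = NULL) {
  stopifnot(inherits(mask, "labeled_mask"))
  sp <- mask$spacing
  if (is.null(smooth_sigma)) smooth_sigma <- sp
  smooth_sigma <- rep_len(smooth_sigma, 3L)
  sel_n <- sum(mask$labels == label_id)
  if (sel_n == 0L) abort(sprintf("label %s not present in mask.", label_id))
  V_p <- sel_n * prod(sp)
  pad <- as.integer(pmax(2, ceiling(3 * smooth_sigma / sp) + 1))
  dims <- dim(mask$labels)
  w <- which(mask$labels == label_id)
  ai <- arrayInd(w, dims)
  touches <- any(ai == 1L) ||
    any(vapply(1:3, function(ax) any(ai[, ax] == dims[ax]), logical(1)))
  if (touches) {
    warn(sprintf("label %s touches the volume border; its surface is closed at the border.",
                 label_id))
  }
  rng <- lapply(1:3, function(ax) {
    lo <- as.integer(min(ai[, ax]) - pad[ax])
    hi <- as.integer(max(ai[, ax]) + pad[ax])
    list(lo = lo, hi = hi, src = max(1L, lo):min(dims[ax], hi))
  })
  # sub-volume with zero padding beyond the volume border
  sub_dims <- vapply(rng, function(r) r$hi - r$lo + 1L, integer(1))
  sub <- array(0, sub_dims)
  src <- lapply(rng, `[[`, "src")
  dst <- lapply(1:3, function(ax) src[[ax]] - rng[[ax]]$lo + 1L)
  sub[dst[[1]], dst[[2]], dst[[3]]] <-
    (mask$labels[src[[1]], src[[2]], src[[3]]] == label_id) * 1
  f <- gaussian_smooth(sub, sp, smooth_sigma)
  # volume-matched iso level: choose the level whose enclosed voxel count
  # equals the object's, which cancels the surface shrinkage Gaussian
  # smoothing would otherwise introduce for small or coarsely sampled cells
  lev <- sort(as.vector(f), decreasing = TRUE)[sel_n]
  lev <- min(max(lev, 1e-6), 1 - 1e-6)
  A_p <- mesh_isosurface(f, sp, level = lev)$area
  list(V_p = V_p, A_p = A_p)
}

#' Nearest distance from a cell to the reference surface
#'
#' Minimum spacing-aware Euclidean distance (um) from the cell's surface
#' voxels to the smoothed spheroid reference surface; 0 when the cell
#' overlaps or touches the reference. `method = "centroid"` measures from
#' the cell centroid instead (exposed because commercial "distance to
#' surface" statistics differ; nearest-surface is the default and matches
#' the travelled-distance semantics).
#'
#' @param label_id Cell label.
#' @param cells A [labeled_mask()] of candidate cells.
#' @param reference A [smoothed_reference_surface()] result.
#' @param method `"surface"` (default) or `"centroid"`.
#' @return Distance in um (0 for overlapping/touching cells).
#' @export
distance_to_reference <- function(label_id, cells, reference,
                                  method = c("surface", "centroid")) {
  stopifnot(inherits(cells, "labeled_mask"),
            inherits(reference, "reference_surface"))
  method <- match.arg(method)
  d2 <- reference_distance_field(reference)
  sel <- cells$labels == label_id
  if (!any(sel)) abort(sprintf("label %s not present in mask.", label_id))
  if (method == "centroid") {
    ai <- arrayInd(which(sel), dim(cells$labels))
    ctr <- round(colMeans(ai))
    return(sqrt(d2[ctr[1], ctr[2], ctr[3]]))
  }
  if (any(sel & reference$mask)) return(0)
  surf <- sel & surface_voxels(sel)
  sqrt(min(d2[surf]))
}

# cache the squared distance field on the reference object (environment
# trick: recompute lazily and store)
reference_distance_field <- function(reference) {
  if (!is.null(attr(reference, "d2"))) return(attr(reference, "d2"))
  edt_squared(reference$mask, reference$spacing)
}

#' Measure all candidate cells against a reference surface
#'
#' The tidy per-cell workhorse: volume, surface area, sphericity, nearest
#' distance to the reference, attachment (distance zero) and optionally the
#' mean intensity of one or more channels.
#'
#' @param cells A [labeled_mask()] of candidate cells.
#' @param reference A [smoothed_reference_surface()] result.
#' @param channels Optional named list of [voxel_volume()] objects.
#' @param smooth_sigma Passed to [measure_object()].
#' @return A tibble of class `cell_metrics`: one row per cell with
#'   `cell_id`, `V_p`, `A_p`, `psi`, `d`, `attached` and one
#'   `mean_<channel>` column per supplied channel.
#' @export
measure_cells <- function(cells, reference, channels = NULL,
                          smooth_sigma = NULL) {
  stopifnot(inherits(cells, "labeled_mask"))
  ids <- cells$label_ids
  d2 <- reference_distance_field(reference)
  attr(reference, "d2") <- d2
  rows <- purrr::map(ids, function(id) {
    m <- measure_object(id, cells, smooth_sigma = smooth_sigma)
    d <- distance_to_reference(id, cells, reference)
    row <- tibble(cell_id = id, V_p = m$V_p, A_p = m$A_p,
                  psi = sphericity(m$V_p, m$A_p), d = d, attached = d <= 0)
    if (!is.null(channels)) {
      for (nm in names(channels)) {
        row[[paste0("mean_", nm)]] <- mean_intensity(id, cells, channels[[nm]])
      }
    }
    row
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(cell_id = integer(), V_p = numeric(), A_p = numeric(),
                  psi = numeric(), d = numeric(), attached = logical())
  }
  class(out) <- c("cell_metrics", class(out))
  out
}
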