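# Exact squared Euclidean distance transforms and ball morphology on
# anisotropic voxel grids. No installed R package offers an N-D EDT
# (EBImage::distmap is 2D-only), so the separable transform is implemented
# here: per axis, the 1-D transform d(i) = min_j f(j) + ((i-j) s)^2 is
# evaluated by shifted-parabola minimisation, which is exact (not a chamfer
# approximation) as long as the shift range covers the requested distance.

# Move `axis` to the front of a 3D array.
axis_first <- function(a, axis) {
  if (axis == 1L) a else aperm(a, switch(axis, NULL, c(2, 1, 3), c(3, 1, 2)))
}
axis_restore <- function(a, axis) {
  if (axis == 1L) a else aperm(a, switch(axis, NULL, c(2, 1, 3), c(2, 3, 1)))
}

# One separable pass: f holds squared distances; returns
# g(i) = min_j f(j) + ((i-j)*s)^2 along `axis`.
edt_pass <- function(f, axis, s, max_k) {
  dims <- dim(f)
  n <- dims[axis]
  g <- axis_first(f, axis)
  dim(g) <- c(n, length(g) / n)
  f0 <- g
  kmax <- min(n - 1L, max_k)
  for (k in seq_len(kmax)) {
    c2 <- (k * s)^2
    lo <- seq_len(n - k)
    hi <- lo + k
    g[hi, ] <- pmin(g[hi, ], f0[lo, ] + c2)
    g[lo, ] <- pmin(g[lo, ], f0[hi, ] + c2)
  }
  dim(g) <- axis_first_dims(dims, axis)
  axis_restore(g, axis)
}

axis_first_dims <- function(dims, axis) {
  switch(axis, dims, dims[c(2, 1, 3)], dims[c(3, 1, 2)])
}

#' Squared Euclidean distance transform of a voxel mask
#'
#' For every voxel, the squared distance (um^2) from its center to the center
#' of the nearest `TRUE` voxel, honoring anisotropic spacing. Distances above
#' `max_dist` are not guaranteed exact (they are reported as lower-bounded
#' values or `Inf`); pass `max_dist = Inf` for the full exact transform.
#'
#' @param mask Logical 3D array.
#' @param spacing um per axis (length 3).
#' @param max_dist Largest distance (um) that must be exact; smaller values
#'   make the transform cheaper (used by the ball morphology).
#' @return Numeric 3D array of squared distances; `Inf` where no `TRUE`
#'   voxel is in range.
#' @export
edt_squared <- function(mask, spacing, max_dist = Inf) {
  spacing <- check_spacing(spacing)
  if (!any(mask)) return(array(Inf, dim(mask)))
  f <- array(ifelse(mask, 0, Inf), dim(mask))
  for (ax in 1:3) {
    max_k <- if (is.infinite(max_dist)) Inf else ceiling(max_dist / spacing[ax]) + 1L
    f <- edt_pass(f, ax, spacing[ax], max_k)
  }
  f
}

# Ball dilation/erosion/opening/closing with a physical radius in um.
# Erosion is defined by duality with dilation so that closing is extensive
# and opening anti-extensive on the voxel grid.
dilate_ball <- function(mask, spacing, radius) {
  if (radius <= 0) return(mask)
  d2 <- edt_squared(mask, spacing, max_dist = radius + max(spacing))
  d2 <= radius^2 + 1e-9
}

erode_ball <- function(mask, spacing, radius) {
  if (radius <= 0) return(mask)
  !dilate_ball(!mask, spacing, radius)
}

close_ball <- function(mask, spacing, radius) {
  erode_ball(dilate_ball(mask, spacing, radius), spacing, radius)
}

open_ball <- function(mask, spacing, radius) {
  dilate_ball(erode_ball(mask, spacing, radius), spacing, radius)
}

# Surface voxels of a mask: foreground voxels with at least one 6-neighbor
# outside the mask (volume border counts as outside).
surface_voxels <- function(mask) {
  dims <- dim(mask)
  interior <- array(TRUE, dims)
  shift_and <- function(m, axis, k) {
    n <- dim(m)[axis]
    out <- array(FALSE, dim(m))
    idx_to <- if (k > 0) (1 + k):n else 1:(n + k)
    idx_from <- if (k > 0) 1:(n - k) else (1 - k):n
    ix <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    to <- from <- ix
    to[[axis]] <- idx_to; from[[axis]] <- idx_from
    out[to[[1]], to[[2]], to[[3]]] <- m[from[[1]], from[[2]], from[[3]]]
    out
  }
  for (ax in 1:3) {
    interior <- interior & shift_and(mask, ax, 1L) & shift_and(mask, ax, -1L)
  }
  mask & !interior
}
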