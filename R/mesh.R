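# Spacing-aware isosurface extraction by marching tetrahedra.
#
# Each grid cube is split into six tetrahedra around the (0,0,0)-(1,1,1)
# diagonal; within a tetrahedron the iso-level crossing is a triangle or a
# quad (split into two triangles), with vertices linearly interpolated along
# the cut edges. On a binary mask the staircase would bias areas, so callers
# smooth the indicator field (Gaussian, ~1 voxel) before meshing; surface
# area then converges to the true area as resolution increases.

# corner id 0..7 encodes (dx, dy, dz) bits; order matters for tet table
.mc_corners <- cbind(
  dx = c(0, 1, 0, 1, 0, 1, 0, 1),
  dy = c(0, 0, 1, 1, 0, 0, 1, 1),
  dz = c(0, 0, 0, 0, 1, 1, 1, 1)
)

# six tetrahedra sharing the 0-7 diagonal (corner ids, 0-based)
.mc_tets <- list(
  c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
  c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L)
)

# per-case triangle list; each triangle is three edges, each edge a pair of
# local tet vertices (1..4). Cases indexed by inside-bitmask 1..14.
.mt_cases <- local({
  quad <- function(e) list(e[1:3], e[c(1, 3, 4)])
  tri <- function(a, b, c, d) list(list(c(a, b), c(a, c), c(a, d)))
  q <- function(p1, p2, p3, p4) quad(list(p1, p2, p3, p4))
  cases <- vector("list", 14L)
  cases[[1L]] <- tri(1, 2, 3, 4)                                  # {1}
  cases[[2L]] <- tri(2, 1, 3, 4)                                  # {2}
  cases[[3L]] <- q(c(1, 3), c(2, 3), c(2, 4), c(1, 4))            # {1,2}
  cases[[4L]] <- tri(3, 1, 2, 4)                                  # {3}
  cases[[5L]] <- q(c(1, 2), c(3, 2), c(3, 4), c(1, 4))            # {1,3}
  cases[[6L]] <- q(c(1, 2), c(1, 3), c(4, 3), c(4, 2))            # {2,3}
  cases[[7L]] <- tri(4, 1, 2, 3)                                  # {1,2,3}
  cases[[8L]] <- tri(4, 1, 2, 3)                                  # {4}
  cases[[9L]] <- q(c(1, 2), c(1, 3), c(4, 3), c(4, 2))            # {1,4}
  cases[[10L]] <- q(c(1, 2), c(3, 2), c(3, 4), c(1, 4))           # {2,4}
  cases[[11L]] <- tri(3, 1, 2, 4)                                 # {1,2,4}
  cases[[12L]] <- q(c(1, 3), c(2, 3), c(2, 4), c(1, 4))           # {3,4}
  cases[[13L]] <- tri(2, 1, 3, 4)                                 # {1,3,4}
  cases[[14L]] <- tri(1, 2, 3, 4)                                 # {2,3,4}
  cases
})

#' Extract an isosurface mesh from a scalar volume
#'
#' Marching tetrahedra over an anisotropic grid: vertex positions are voxel
#' centers at physical coordinates `(i - 1) * spacing`. Intended for smoothed
#' indicator fields at `level = 0.5`.
#'
#' @param vol Numeric 3D array.
#' @param spacing um per axis.
#' @param level Iso level.
#' @return List with `area` (um^2) and `triangles` (n x 9 matrix: the three
#'   vertices of each triangle, xyz in um).
#' @export
mesh_isosurface <- function(vol, spacing, level = 0.5) {
  spacing <- check_spacing(spacing)
  dims <- dim(vol)
  if (length(dims) != 3L || any(dims < 2L)) {
    abort("`vol` must be a 3D array with at least 2 voxels per axis.")
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- nx - 1L; cy <- ny - 1L; cz <- nz - 1L
  I <- rep(seq_len(cx), times = cy * cz)
  J <- rep(rep(seq_len(cy), each = cx), times = cz)
  K <- rep(seq_len(cz), each = cx * cy)
  base <- I + (J - 1L) * nx + (K - 1L) * nx * ny
  off <- .mc_corners[, 1] + .mc_corners[, 2] * nx + .mc_corners[, 3] * nx * ny
  vals <- lapply(1:8, function(c) vol[base + off[c]])
  inside <- lapply(vals, function(v) v >= level)
  n_in <- Reduce(`+`, inside)
  active <- n_in > 0L & n_in < 8L
  if (!any(active)) {
    return(list(area = 0, triangles = matrix(numeric(0), 0, 9)))
  }
  I <- I[active]; J <- J[active]; K <- K[active]
  vals <- lapply(vals, function(v) v[active])
  tri_chunks <- list()
  for (tet in .mc_tets) {
    v <- lapply(tet, function(c) vals[[c + 1L]])
    p <- lapply(tet, function(c) {
      cbind((I - 1L + .mc_corners[c + 1L, 1]) * spacing[1],
            (J - 1L + .mc_corners[c + 1L, 2]) * spacing[2],
            (K - 1L + .mc_corners[c + 1L, 3]) * spacing[3])
    })
    s <- lapply(v, function(x) x >= level)
    caseid <- s[[1]] + 2L * s[[2]] + 4L * s[[3]] + 8L * s[[4]]
    for (cs in 1:14) {
      sel <- which(caseid == cs)
      if (!length(sel)) next
      for (trg in .mt_cases[[cs]]) {
        pts <- lapply(trg, function(edge) {
          a <- edge[1]; b <- edge[2]
          va <- v[[a]][sel]; vb <- v[[b]][sel]
          t <- (level - va) / (vb - va)
          p[[a]][sel, , drop = FALSE] +
            t * (p[[b]][sel, , drop = FALSE] - p[[a]][sel, , drop = FALSE])
        })
        tri_chunks[[length(tri_chunks) + 1L]] <-
          cbind(pts[[1]], pts[[2]], pts[[3]])
      }
    }
  }
  tri <- do.call(rbind, tri_chunks)
  list(area = sum(triangle_areas(tri)), triangles = tri)
}

triangle_areas <- function(tri) {
  u <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  v <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Separable Gaussian smoothing with per-axis physical sigma (um); zero
# padding outside the volume (background).
gaussian_smooth <- function(vol, spacing, sigma) {
  spacing <- check_spacing(spacing)
  sigma <- rep_len(sigma, 3L)
  out <- vol
  for (ax in 1:3) {
    sv <- sigma[ax] / spacing[ax] # sigma in voxels along this axis
    if (sv <= 0) next
    rad <- max(1L, ceiling(3 * sv))
    w <- exp(-0.5 * ((-rad:rad) / sv)^2)
    w <- w / sum(w)
    dims <- dim(out)
    n <- dims[ax]
    m <- axis_first(out, ax)
    dim(m) <- c(n, length(m) / n)
    acc <- matrix(0, n, ncol(m))
    for (k in -rad:rad) {
      lo_to <- max(1L, 1L - k); hi_to <- min(n, n - k)
      if (lo_to > hi_to) next
      acc[lo_to:hi_to, ] <- acc[lo_to:hi_to, ] +
        w[k + rad + 1L] * m[(lo_to + k):(hi_to + k), ]
    }
    dim(acc) <- axis_first_dims(dims, ax)
    out <- axis_restore(acc, ax)
  }
  out
}
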