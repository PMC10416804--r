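#' Specify a synthetic cell shape
#'
#' A `cell_spec` describes one synthetic cell placed in an imaging scenario:
#' a sphere, an axis-aligned (or arbitrarily oriented) ellipsoid, or a
#' spherocylinder ("capsule", the standard model of an elongated migrating
#' cell). All dimensions are physical micrometres, so rasterization is
#' spacing-aware. Volume and surface area of every shape are available in
#' closed form, which is what makes generated scenes usable as ground truth
#' for the morphometry pipeline.
#'
#' For `shape = "capsule"`, `semi_axes[1]` is the half-length of the capsule
#' including its hemispherical caps and `semi_axes[2] == semi_axes[3]` is the
#' cap/cylinder radius; `semi_axes[1] >= semi_axes[2]` is required.
#'
#' @param shape One of `"sphere"`, `"ellipsoid"`, `"capsule"`.
#' @param semi_axes Numeric length 3, semi-axes in um (for a sphere all three
#'   equal; only the first is consulted and recycled).
#' @param center Numeric length 3, center in um.
#' @param axis Orientation of the long axis (unit-normalized internally);
#'   default along x.
#' @param attached Logical; whether the cell is placed in contact with the
#'   spheroid (used as ground-truth attachment).
#' @param phenotype True phenotype label: `"epithelial"`, `"escaping"` or
#'   `"amoeboid"`.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(shape = c("sphere", "ellipsoid", "capsule"),
                      semi_axes, center, axis = c(1, 0, 0),
                      attached = FALSE,
                      phenotype = c("amoeboid", "escaping", "epithelial")) {
  shape <- match.arg(shape)
  phenotype <- match.arg(phenotype)
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    abort("`semi_axes` must be positive and finite.")
  }
  if (shape == "sphere") semi_axes <- rep(semi_axes[1], 3L)
  if (shape == "capsule") {
    if (abs(semi_axes[2] - semi_axes[3]) > 1e-9) {
      abort("capsule requires semi_axes[2] == semi_axes[3] (circular cross-section).")
    }
    if (semi_axes[1] < semi_axes[2]) {
      abort("capsule half-length (semi_axes[1]) must be >= its radius.")
    }
  }
  if (length(center) != 3L || any(!is.finite(center))) {
    abort("`center` must be three finite coordinates (um).")
  }
  if (vec_norm(axis) == 0) abort("`axis` must be a nonzero direction.")
  structure(
    list(shape = shape, semi_axes = semi_axes, center = as.numeric(center),
         axis = as.numeric(axis) / vec_norm(axis),
         attached = isTRUE(attached), phenotype = phenotype),
    class = "cell_spec"
  )
}

#' Closed-form volume of a cell shape
#'
#' Sphere and ellipsoid use \eqn{\frac{4}{3}\pi a b c}; the capsule is a
#' cylinder of radius r and length L plus a full sphere of radius r:
#' \eqn{\pi r^2 L + \frac{4}{3}\pi r^3}.
#'
#' @param spec A [cell_spec()].
#' @return Volume in um^3.
#' @export
shape_volume <- function(spec) {
  s <- spec$semi_axes
  switch(spec$shape,
    sphere    = 4 / 3 * pi * s[1]^3,
    ellipsoid = 4 / 3 * pi * prod(s),
    capsule   = {
      r <- s[2]; L <- 2 * (s[1] - r)
      pi * r^2 * L + 4 / 3 * pi * r^3
    }
  )
}

#' Closed-form surface area of a cell shape
#'
#' Spheres use \eqn{4\pi r^2}. Spheroids of revolution (two equal semi-axes)
#' use the exact prolate/oblate elementary forms. Fully triaxial ellipsoids
#' use the Knud Thomsen approximation with p = 1.6075, whose relative error
#' is bounded by about 1.1%. Capsules are exact:
#' \eqn{2\pi r L + 4 \pi r^2}.
#'
#' @inheritParams shape_volume
#' @return Surface area in um^2.
#' @export
shape_area <- function(spec) {
  s <- sort(spec$semi_axes, decreasing = TRUE) # a >= b >= c
  switch(spec$shape,
    sphere = 4 * pi * s[1]^2,
    capsule = {
      r <- spec$semi_axes[2]; L <- 2 * (spec$semi_axes[1] - r)
      2 * pi * r * L + 4 * pi * r^2
    },
    ellipsoid = ellipsoid_area(s[1], s[2], s[3])
  )
}

# Exact for spheres of revolution, Knud Thomsen (p = 1.6075) otherwise.
ellipsoid_area <- function(a, b, c) {
  tol <- 1e-12
  if (abs(a - b) < tol && abs(b - c) < tol) return(4 * pi * a^2)
  if (abs(b - c) < tol) { # prolate: a > b == c
    e <- sqrt(1 - (b / a)^2)
    return(2 * pi * b^2 * (1 + a / (b * e) * asin(e)))
  }
  if (abs(a - b) < tol) { # oblate: a == b > c
    e <- sqrt(1 - (c / a)^2)
    return(2 * pi * a^2 + pi * c^2 / e * log((1 + e) / (1 - e)))
  }
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' Ground-truth sphericity of a cell shape
#'
#' Wadell sphericity computed from the closed-form volume and surface area;
#' exactly 1 for spheres, strictly below 1 for any other shape.
#'
#' @inheritParams shape_volume
#' @return Sphericity in (0, 1].
#' @export
shape_sphericity <- function(spec) {
  if (spec$shape == "sphere") return(1)
  sphericity(shape_volume(spec), shape_area(spec))
}

# Signed tests for "is this physical point inside the shape".  `pts` is an
# n x 3 matrix of um coordinates. Used both by the rasterizer and by the
# ground-truth distance sampler.
points_in_shape <- function(pts, spec) {
  d <- sweep(pts, 2, spec$center)
  switch(spec$shape,
    sphere = rowSums(d^2) <= spec$semi_axes[1]^2,
    ellipsoid = {
      dl <- local_frame(d, spec$axis)
      rowSums(sweep(dl, 2, spec$semi_axes, "/")^2) <= 1
    },
    capsule = {
      dl <- local_frame(d, spec$axis)
      r <- spec$semi_axes[2]; h <- spec$semi_axes[1] - r
      ax <- pmin(pmax(dl[, 1], -h), h) # nearest point on the core segment
      (dl[, 1] - ax)^2 + dl[, 2]^2 + dl[, 3]^2 <= r^2
    }
  )
}

# Rotate displacement vectors into the shape's local frame whose first axis
# is `axis` (any orthonormal completion works for axisymmetric shapes; for
# triaxial ellipsoids the completion fixes the orientation of axes 2 and 3).
local_frame <- function(d, axis) {
  u1 <- axis / vec_norm(axis)
  helper <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- helper - sum(helper * u1) * u1
  u2 <- u2 / vec_norm(u2)
  u3 <- c(
    u1[2] * u2[3] - u1[3] * u2[2],
    u1[3] * u2[1] - u1[1] * u2[3],
    u1[1] * u2[2] - u1[2] * u2[1]
  )
  d %*% cbind(u1, u2, u3)
}

# Quasi-uniform sample of points on the shape surface (Fibonacci sphere for
# the sphere/ellipsoid map; capsule split between caps and cylinder).  Used
# for numerical ground-truth distances of non-spherical cells.
sample_shape_surface <- function(spec, n = 2000L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  unit <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  pts_local <- switch(spec$shape,
    sphere = unit * spec$semi_axes[1],
    ellipsoid = sweep(unit, 2, spec$semi_axes, "*"),
    capsule = {
      r <- spec$semi_axes[2]; h <- spec$semi_axes[1] - r
      p <- unit * r
      p[, 1] <- p[, 1] + ifelse(p[, 1] >= 0, h, -h) # push caps apart
      ncyl <- max(8L, n %/% 3L)
      t_ang <- runif_free(ncyl) # deterministic grid, see below
      cyl <- cbind(seq(-h, h, length.out = ncyl),
                   r * cos(2 * pi * t_ang), r * sin(2 * pi * t_ang))
      rbind(p, cyl)
    }
  )
  # rotate local -> world: rows were expressed in the local frame (u1,u2,u3)
  u <- frame_basis(spec$axis) # rows are the basis vectors
  sweep(pts_local %*% u, 2, spec$center, "+")
}

runif_free <- function(n) ((seq_len(n) - 1) * (sqrt(5) - 1) / 2) %% 1

frame_basis <- function(axis) {
  u1 <- axis / vec_norm(axis)
  helper <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- helper - sum(helper * u1) * u1
  u2 <- u2 / vec_norm(u2)
  u3 <- c(
    u1[2] * u2[3] - u1[3] * u2[2],
    u1[3] * u2[1] - u1[1] * u2[3],
    u1[1] * u2[2] - u1[2] * u2[1]
  )
  rbind(u1, u2, u3)
}

# True nearest distance (um) from the cell surface to the spheroid sphere
# surface; negative values are clamped to 0 (overlap/touch).
true_distance_to_sphere <- function(spec, sphere_center, sphere_radius) {
  if (spec$shape == "sphere") {
    d <- vec_norm(spec$center - sphere_center) - sphere_radius - spec$semi_axes[1]
    return(max(0, d))
  }
  pts <- sample_shape_surface(spec, 4000L)
  d <- sqrt(rowSums(sweep(pts, 2, sphere_center)^2)) - sphere_radius
  max(0, min(d))
}
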