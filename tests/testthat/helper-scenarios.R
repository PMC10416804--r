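# Shared fixture builders: everything is generated in code at test time.

# Logical mask of a rasterized sphere (voxel-center rule).
make_sphere_mask <- function(dims, spacing, center, radius) {
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
        (zs - center[3])^2, "+") <= radius^2
}

mask_to_labeled <- function(mask, spacing) {
  labeled_mask(array(as.integer(mask), dim(mask)), spacing)
}

# Quadrature oracle for the surface area of an axis-aligned ellipsoid
# (a, b, c): numerical integral of |r_theta x r_phi| over the standard
# spherical parametrization. Independent of the closed forms under test.
ellipsoid_area_quadrature <- function(a, b, c) {
  integrand <- function(theta, phi) {
    st <- sin(theta); ct <- cos(theta)
    sp <- sin(phi); cp <- cos(phi)
    # cross product of the parametrization derivatives
    x <- b * c * st^2 * cp
    y <- a * c * st^2 * sp
    z <- a * b * st * ct
    sqrt(x^2 + y^2 + z^2)
  }
  pracma::integral2(integrand, 0, pi, 0, 2 * pi, reltol = 1e-10)$Q
}

# Exhaustive Ward oracle: at each step merge the pair of clusters whose
# union minimizes the within-cluster sum-of-squares increase. Heights use
# the convention in which two singletons merge at their Euclidean distance
# (sqrt(2 * delta SS)).
ward_oracle <- function(X) {
  ss <- function(idx) {
    if (length(idx) == 1L) return(0)
    M <- X[idx, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_delta <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        delta <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best <- c(i, j)
        }
      }
    }
    members <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = members,
                                          height = sqrt(2 * best_delta))
    clusters[[best[1]]] <- members
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Member sets of every internal node of an hclust, in merge order.
hclust_member_sets <- function(hc) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    grab <- function(k) if (k < 0) -k else sets[[k]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}

# A small invasion scene: spheroid + detached spheres + attached capsules,
# all inside an (extent_x, extent_y, extent_z) um volume at `spacing`.
make_invasion_scenario <- function(spacing = c(2, 2, 3), noise_sigma = 3,
                                   seed = 42L) {
  cells <- list(
    cell_spec("sphere", 6, c(14, 80, 40), phenotype = "amoeboid"),
    cell_spec("sphere", 5, c(80, 18, 30), phenotype = "amoeboid"),
    cell_spec("capsule", c(16, 5, 5), c(130, 80, 40), axis = c(1, 0, 0),
              attached = TRUE, phenotype = "escaping")
  )
  imaging_scenario(dims = c(81, 81, 31), spacing = spacing,
                   spheroid_radius = 40, spheroid_center = c(80, 80, 40),
                   cells = cells, noise_sigma = noise_sigma, seed = seed)
}
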