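#' Describe a synthetic spheroid-imaging scenario
#'
#' An `imaging_scenario` stands in for the microscope: a dense central
#' spheroid (sphere) plus peripheral cells of controlled shape, rasterized
#' into an intensity z-stack with additive Gaussian noise. Every quantity a
#' downstream measurement should recover (cell volume, surface area,
#' sphericity, distance to the spheroid) is known in closed form, which is
#' what makes these scenes usable as ground truth.
#'
#' Defaults emulate a day ~6 collagen-embedded melanoma spheroid imaged on a
#' confocal stack: a 120 um-diameter spheroid, anisotropic voxels
#' (1 x 1 x 3 um, z coarser than xy as in real stacks), and the spheroid
#' placed tangent to the imaging face so the widest point sits one radius
#' deep (single-photon imaging cannot see past it).
#'
#' @param dims Grid size in voxels (x, y, z).
#' @param spacing Voxel spacing in um (x, y, z).
#' @param spheroid_radius Spheroid radius, um.
#' @param spheroid_center Spheroid center, um; default centers it in x/y and
#'   places its top at the imaging face (z = radius).
#' @param cells List of [cell_spec()] objects.
#' @param background_intensity,foreground_intensity Intensity units.
#' @param noise_sigma SD of additive Gaussian noise (clipped at zero).
#' @param seed Integer seed; fixed seed gives byte-identical volumes.
#' @return An object of class `imaging_scenario`.
#' @export
imaging_scenario <- function(dims = c(160, 160, 36),
                             spacing = c(1, 1, 3),
                             spheroid_radius = 60,
                             spheroid_center = NULL,
                             cells = list(),
                             background_intensity = 10,
                             foreground_intensity = 120,
                             noise_sigma = 4,
                             seed = 1L) {
  spacing <- check_spacing(spacing)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 2L)) {
    abort("`dims` must be three voxel counts >= 2.")
  }
  extent <- (dims - 1L) * spacing
  if (is.null(spheroid_center)) {
    spheroid_center <- c(extent[1] / 2, extent[2] / 2, spheroid_radius)
  }
  if (spheroid_radius <= 0) abort("`spheroid_radius` must be positive.")
  lo <- spheroid_center - spheroid_radius
  hi <- spheroid_center + spheroid_radius
  # x/y: the whole spheroid must fit; z: the stack must reach at least the
  # widest plane (a hemispheroid acquisition ends at/near the equator, so the
  # deep half may extend beyond the last slice, as in real confocal stacks)
  if (any(lo[1:2] < -1e-9) || any(hi[1:2] > extent[1:2] + 1e-9) ||
      lo[3] < -1e-9 || spheroid_center[3] > extent[3] + 1e-9) {
    abort("spheroid does not fit inside the volume bounds.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    if (!inherits(cl, "cell_spec")) abort("`cells` must be a list of cell_spec objects.")
    r <- max(cl$semi_axes)
    if (any(cl$center - r < -1e-9) || any(cl$center + r > extent + 1e-9)) {
      abort(sprintf("cell %d (%s, %s) lies outside the volume bounds.",
                    i, cl$shape, cl$phenotype))
    }
  }
  structure(
    list(dims = dims, spacing = spacing, spheroid_radius = spheroid_radius,
         spheroid_center = as.numeric(spheroid_center), cells = cells,
         background_intensity = background_intensity,
         foreground_intensity = foreground_intensity,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "imaging_scenario"
  )
}

#' A fluorescence voxel volume
#'
#' Container for a 3D intensity grid with physical voxel spacing. Voxel
#' `[i, j, k]` has its center at physical coordinate `(i-1, j-1, k-1) *
#' spacing`; z grows away from the imaging face.
#'
#' @param intensities Numeric 3D array.
#' @param spacing um per axis.
#' @param channel_name Channel label.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing, channel_name = "dendra2_green") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array.")
  }
  structure(list(intensities = intensities, spacing = check_spacing(spacing),
                 channel_name = channel_name),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s um, channel '%s'\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              x$channel_name))
  invisible(x)
}

#' Rasterize an imaging scenario into a volume with ground truth
#'
#' A voxel is foreground iff its center lies inside the spheroid sphere or
#' inside any cell (the same rule the measurement side assumes). Intensities
#' are `background_intensity` outside and `foreground_intensity` inside,
#' plus Gaussian noise clipped at zero.
#'
#' @param scenario An [imaging_scenario()].
#' @return A list with `volume` (a [voxel_volume()]) and `truth`, a tibble
#'   with one row for the spheroid and one per cell: closed-form volume
#'   `V_p` (um^3), surface area `A_p` (um^2), sphericity `psi`, nearest
#'   surface-to-surface distance to the spheroid sphere `d` (um), geometric
#'   attachment (`d == 0`) and the planted phenotype.
#' @export
generate_volume <- function(scenario) {
  stopifnot(inherits(scenario, "imaging_scenario"))
  dims <- scenario$dims; spacing <- scenario$spacing
  xs <- axis_coords(dims[1], spacing[1])
  ys <- axis_coords(dims[2], spacing[2])
  zs <- axis_coords(dims[3], spacing[3])
  inside <- array(FALSE, dims)
  # spheroid: vectorized sphere test without materializing the full grid
  dx2 <- (xs - scenario$spheroid_center[1])^2
  dy2 <- (ys - scenario$spheroid_center[2])^2
  dz2 <- (zs - scenario$spheroid_center[3])^2
  r2 <- scenario$spheroid_radius^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
  for (cl in scenario$cells) {
    bb_lo <- cl$center - max(cl$semi_axes) - spacing
    bb_hi <- cl$center + max(cl$semi_axes) + spacing
    ix <- which(xs >= bb_lo[1] & xs <= bb_hi[1])
    iy <- which(ys >= bb_lo[2] & ys <= bb_hi[2])
    iz <- which(zs >= bb_lo[3] & zs <= bb_hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
    hit <- points_in_shape(pts, cl)
    sub <- array(inside[ix, iy, iz], c(length(ix), length(iy), length(iz)))
    inside[ix, iy, iz] <- sub | array(hit, dim(sub))
  }
  vol <- with_seed(scenario$seed, {
    v <- array(ifelse(inside, scenario$foreground_intensity,
                      scenario$background_intensity), dims)
    if (scenario$noise_sigma > 0) {
      v <- v + array(rnorm(length(v), 0, scenario$noise_sigma), dims)
    }
    pmax(v, 0)
  })
  truth <- ground_truth_table(scenario)
  list(volume = voxel_volume(vol, spacing), truth = truth)
}

ground_truth_table <- function(scenario) {
  sph <- tibble(
    object = "spheroid", cell_id = NA_integer_, shape = "sphere",
    V_p = 4 / 3 * pi * scenario$spheroid_radius^3,
    A_p = 4 * pi * scenario$spheroid_radius^2,
    psi = 1, d = 0, attached = TRUE, phenotype = NA_character_
  )
  if (!length(scenario$cells)) return(sph)
  cells <- purrr::imap(scenario$cells, function(cl, i) {
    d <- true_distance_to_sphere(cl, scenario$spheroid_center,
                                 scenario$spheroid_radius)
    tibble(
      object = "cell", cell_id = as.integer(i), shape = cl$shape,
      V_p = shape_volume(cl), A_p = shape_area(cl),
      psi = shape_sphericity(cl), d = d, attached = d <= 0,
      phenotype = cl$phenotype
    )
  })
  bind_rows(sph, bind_rows(cells))
}

#' Generate a time series of imaging volumes
#'
#' The spheroid radius grows by a constant per-day factor; escaped cells
#' accumulate according to a per-day schedule and each cohort drifts outward
#' at a fixed speed, emulating invasion. The escape schedule and speed are
#' free parameters of the emulation, not estimates of any cell line's
#' biology.
#'
#' @param scenario Base [imaging_scenario()] (day-0 spheroid; its `cells`
#'   are ignored).
#' @param days Strictly increasing integer vector of imaging days.
#' @param growth_rate Per-day radius multiplication factor.
#' @param escape_schedule Number of newly escaping cells per day (recycled
#'   to `length(days)`).
#' @param escape_gap Initial surface-to-surface gap of a fresh escaper, um.
#' @param invasion_speed Outward drift of escaped cohorts, um/day.
#' @param cell_radius Radius of escaped (spherical, amoeboid-like) cells, um.
#' @return A list with one element per day: `day`, `volume`, `truth`.
#' @export
generate_timeseries <- function(scenario, days, growth_rate = 1.1,
                                escape_schedule = 0, escape_gap = 12,
                                invasion_speed = 12, cell_radius = 7) {
  stopifnot(inherits(scenario, "imaging_scenario"))
  days <- as.numeric(days)
  if (length(days) < 1L || any(diff(days) <= 0)) {
    abort("`days` must be strictly increasing.")
  }
  schedule <- rep_len(as.integer(escape_schedule), length(days))
  extent <- (scenario$dims - 1L) * scenario$spacing
  # deterministic escape directions (outward in the imaged hemisphere)
  cohorts <- list() # each: day_added, direction
  out <- vector("list", length(days))
  golden <- (sqrt(5) - 1) / 2
  n_prev <- 0L
  for (di in seq_along(days)) {
    day <- days[di]
    radius_day <- scenario$spheroid_radius * growth_rate^(day - days[1])
    center_day <- c(extent[1] / 2, extent[2] / 2, radius_day)
    if (schedule[di] > 0) {
      for (j in seq_len(schedule[di])) {
        idx <- n_prev + j
        theta <- 2 * pi * ((idx * golden) %% 1)
        cohorts[[idx]] <- list(day_added = day, theta = theta)
      }
      n_prev <- n_prev + schedule[di]
    }
    cells <- purrr::imap(cohorts, function(ch, i) {
      gap <- escape_gap + invasion_speed * (day - ch$day_added)
      rho <- radius_day + gap + cell_radius
      # keep escapers in the imaged hemisphere, slightly below the face
      zc <- min(max(cell_radius, radius_day * 0.55), extent[3] - cell_radius)
      rho_xy <- sqrt(max(rho^2 - (zc - center_day[3])^2, (cell_radius * 1.5)^2))
      ctr <- c(center_day[1] + rho_xy * cos(ch$theta),
               center_day[2] + rho_xy * sin(ch$theta), zc)
      ctr <- pmin(pmax(ctr, cell_radius), extent - cell_radius)
      cell_spec("sphere", cell_radius, ctr, phenotype = "amoeboid")
    })
    sc_day <- imaging_scenario(
      dims = scenario$dims, spacing = scenario$spacing,
      spheroid_radius = radius_day, spheroid_center = center_day,
      cells = cells,
      background_intensity = scenario$background_intensity,
      foreground_intensity = scenario$foreground_intensity,
      noise_sigma = scenario$noise_sigma,
      seed = scenario$seed + di - 1L
    )
    gv <- generate_volume(sc_day)
    out[[di]] <- list(day = day, volume = gv$volume, truth = gv$truth)
  }
  out
}
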