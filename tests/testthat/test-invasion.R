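test_that("phenotype classification follows attachment and sphericity", {
  metrics <- tibble::tibble(
    cell_id = 1:3,
    psi = c(0.98, 0.60, 0.92),
    attached = c(FALSE, TRUE, TRUE),
    d = c(30, 0, 0)
  )
  out <- classify_phenotype(metrics, sphericity_threshold = 0.8)
  expect_equal(out$phenotype, c("amoeboid", "escaping", "epithelial"))
  # an attached capsule below the threshold by its closed-form sphericity
  caps <- cell_spec("capsule", c(20, 3.5, 3.5), c(0, 0, 0))
  expect_lt(shape_sphericity(caps), 0.8)
  m2 <- tibble::tibble(psi = shape_sphericity(caps), attached = TRUE, d = 0)
  expect_equal(classify_phenotype(m2)$phenotype, "escaping")
  expect_error(classify_phenotype(tibble::tibble(psi = 1)), "attached")
})

test_that("classification recovers planted labels on separated scenarios", {
  # ground-truth metrics for many cells with psi separation >= 0.15 around
  # the 0.8 threshold: epithelial/amoeboid spheres (psi 1), escaping
  # capsules (psi <= 0.65)
  set.seed(31)
  specs <- c(
    lapply(1:40, function(i) cell_spec("sphere", runif(1, 4, 8),
                                       c(0, 0, 0), phenotype = "amoeboid")),
    lapply(1:40, function(i) cell_spec("capsule",
                                       c(runif(1, 22, 30), 3.5, 3.5),
                                       c(0, 0, 0), attached = TRUE,
                                       phenotype = "escaping")),
    lapply(1:40, function(i) cell_spec("sphere", runif(1, 5, 9),
                                       c(0, 0, 0), attached = TRUE,
                                       phenotype = "epithelial"))
  )
  truth <- vapply(specs, function(s) s$phenotype, character(1))
  psi <- vapply(specs, shape_sphericity, numeric(1))
  expect_true(all(psi[truth == "escaping"] <= 0.70))
  metrics <- tibble::tibble(
    psi = psi,
    attached = vapply(specs, function(s) s$attached, logical(1)),
    d = ifelse(truth == "amoeboid", 25, 0)
  )
  out <- classify_phenotype(metrics)
  expect_gte(mean(out$phenotype == truth), 0.95)
})

test_that("invasion density is count over cap area", {
  expect_equal(invasion_density(0, 1e5), 0)
  expect_equal(invasion_density(10, 1e5), 1e-4)
  expect_error(invasion_density(1, 0), "positive")
})

test_that("the time series fills volumes, densities and speeds", {
  geo <- dplyr::bind_rows(lapply(c(0, 1, 3, 5), function(day) {
    dplyr::bind_cols(tibble::tibble(day = day), spheroid_geometry(90, 90, 90))
  }))
  # constant geometry, no cells
  ts0 <- build_timeseries(geo)
  expect_true(all(ts0$relative_volume == 1))
  expect_true(all(ts0$invasion_density == 0))
  expect_true(all(ts0$cumulative_escaped == 0))
  # growing radius: x1.26/day doubles the volume by day 1
  geo2 <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(day = 0), spheroid_geometry(90, 90, 90)),
    dplyr::bind_cols(tibble::tibble(day = 1),
                     spheroid_geometry(90 * 1.26, 90 * 1.26, 90 * 1.26))
  )
  ts2 <- build_timeseries(geo2)
  expect_equal(ts2$relative_volume[2], 1.26^3, tolerance = 1e-12)
  expect_equal(ts2$relative_volume[2], 2, tolerance = 0.01)
  # escaped-cell metrics: mean distance 50 at day 3, 80 at day 5
  cells <- dplyr::bind_rows(
    tibble::tibble(day = 3, d = c(40, 60), psi = 0.9, attached = FALSE),
    tibble::tibble(day = 5, d = c(70, 90), psi = 0.85, attached = FALSE)
  )
  ts3 <- build_timeseries(geo, cells)
  expect_equal(ts3$mean_escaped_d[ts3$day == 3], 50)
  expect_equal(ts3$mean_escaped_d[ts3$day == 5], 80)
  expect_equal(ts3$invasion_speed[ts3$day == 5], 15)
  expect_true(all(diff(ts3$cumulative_escaped) >= 0))
  expect_equal(ts3$invasion_density, ts3$cumulative_escaped / ts3$SA)
})

test_that("a missing day 0 is flagged and leaves relative volume undefined", {
  geo <- dplyr::bind_rows(lapply(c(1, 2), function(day) {
    dplyr::bind_cols(tibble::tibble(day = day), spheroid_geometry(50, 50, 50))
  }))
  expect_warning(ts <- build_timeseries(geo), "day 0")
  expect_true(all(is.na(ts$relative_volume)))
})

test_that("per-day escaped counts accumulate like the generator schedule", {
  geo <- dplyr::bind_rows(lapply(1:2, function(day) {
    dplyr::bind_cols(tibble::tibble(day = day), spheroid_geometry(50, 50, 50))
  }))
  cells <- dplyr::bind_rows(
    tibble::tibble(day = 1, d = rep(20, 3), psi = 0.9, attached = FALSE),
    tibble::tibble(day = 2, d = rep(25, 5), psi = 0.9, attached = FALSE)
  )
  suppressWarnings(ts <- build_timeseries(geo, cells))
  expect_equal(ts$cumulative_escaped, c(3, 5))
  expect_equal(ts$invasion_density[2] / ts$invasion_density[1], 5 / 3)
})

test_that("density is invariant to voxel spacing", {
  # same physical scene sampled at two resolutions
  mk <- function(sp) {
    cells <- list(
      cell_spec("sphere", 6, c(14, 80, 40), phenotype = "amoeboid"),
      cell_spec("sphere", 6, c(80, 16, 40), phenotype = "amoeboid")
    )
    sc <- imaging_scenario(dims = c(160 / sp[1], 160 / sp[2], 90 / sp[3]) + 1,
                           spacing = sp, spheroid_radius = 40,
                           spheroid_center = c(80, 80, 40),
                           cells = cells, noise_sigma = 0, seed = 1)
    gv <- generate_volume(sc)
    m <- segment_foreground(gv$volume, method = "otsu")
    cr <- crop_at_widest(m)
    parts <- split_spheroid_and_cells(cr$mask)
    nz <- dim(parts$spheroid$labels)[3]
    ell <- fit_periphery_ellipse(parts$spheroid$labels[, , nz] > 0, sp[1:2])
    geo <- spheroid_geometry(ell$a, ell$b, cr$z_depth)
    invasion_density(length(parts$cells$label_ids), geo$SA)
  }
  d1 <- mk(c(2, 2, 3))
  d2 <- mk(c(1, 1, 1.5))
  expect_equal(d1, d2, tolerance = 0.05)
})
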