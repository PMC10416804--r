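test_that("the sphericity formula is exact on analytic inputs", {
  # sphere with V = 4pi/3, A = 4pi
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-14)
  # unit cube
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-14)
  expect_equal(sphericity(1, 6), 0.80599, tolerance = 1e-4)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -1), "positive")
})

test_that("measured volumes track the analytic values", {
  # rasterized sphere radius 10 um at 1 um spacing: V within 2% of 4/3 pi 10^3
  msk <- make_sphere_mask(c(25, 25, 25), c(1, 1, 1), c(12, 12, 12), 10)
  m <- measure_object(1, mask_to_labeled(msk, c(1, 1, 1)))
  expect_equal(m$V_p, 4 / 3 * pi * 1000, tolerance = 0.02)
  expect_equal(sphericity(m$V_p, m$A_p), 1, tolerance = 0.04)
  # single voxel at unit spacing
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  expect_equal(measure_object(1, labeled_mask(one, c(1, 1, 1)))$V_p, 1)
  # anisotropic vs isotropic sampling of the same physical sphere
  aniso <- make_sphere_mask(c(41, 41, 15), c(1, 1, 3), c(20, 20, 21), 12)
  iso <- make_sphere_mask(c(41, 41, 43), c(1, 1, 1), c(20, 20, 21), 12)
  va <- measure_object(1, mask_to_labeled(aniso, c(1, 1, 3)))$V_p
  vi <- measure_object(1, mask_to_labeled(iso, c(1, 1, 1)))$V_p
  expect_equal(va / vi, 1, tolerance = 0.05)
})

test_that("an object touching the border is measured with a warning", {
  msk <- make_sphere_mask(c(12, 20, 20), c(1, 1, 1), c(0, 10, 10), 6)
  expect_warning(m <- measure_object(1, mask_to_labeled(msk, c(1, 1, 1))),
                 "border")
  expect_gt(m$A_p, 0)
})

test_that("mesh surface area converges toward the analytic value", {
  errs <- vapply(c(1.6, 0.8), function(s) {
    n <- ceiling(24 / s) + 1
    msk <- make_sphere_mask(rep(n, 3), rep(s, 3), rep(12, 3), 8)
    m <- measure_object(1, mask_to_labeled(msk, rep(s, 3)))
    abs(m$A_p - 4 * pi * 64) / (4 * pi * 64)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.01)
  expect_lt(errs[2], 0.03)
})

test_that("ellipse fitting recovers rasterized discs and ellipses", {
  sp <- c(2, 2)
  grid_xy <- function(n) (seq_len(n) - 1) * 2
  xs <- grid_xy(71); ys <- grid_xy(71)
  circle <- outer((xs - 70)^2, (ys - 70)^2, "+") <= 50^2
  f <- fit_periphery_ellipse(circle, sp)
  expect_equal(f$a, 50, tolerance = 1 / 50)   # within half a voxel
  expect_equal(f$b, 50, tolerance = 1 / 50)
  ell <- outer(((xs - 70) / 60)^2, ((ys - 70) / 40)^2, "+") <= 1
  f2 <- fit_periphery_ellipse(ell, sp)
  expect_equal(f2$a, 60, tolerance = 0.02)
  expect_equal(f2$b, 40, tolerance = 0.02)
  # degenerate one-voxel-wide line
  line <- matrix(FALSE, 30, 30); line[5:25, 10] <- TRUE
  expect_error(fit_periphery_ellipse(line, sp), "ellipse|boundary")
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_error(fit_periphery_ellipse(tiny, sp), "boundary")
})

test_that("estimated spheroid volume follows the mean-radius sphere formula", {
  est <- estimate_spheroid_volume(90, 90, 90)
  expect_equal(est$r, 90)
  expect_equal(est$V, 4 / 3 * pi * 90^3)
  expect_equal(est$V, 3.0536e6, tolerance = 1e-4)
  # symmetric in (a, b, z): only the mean matters
  est2 <- estimate_spheroid_volume(100, 80, 90)
  expect_equal(est2$r, 90)
  expect_equal(est2$V, est$V)
  expect_equal(estimate_spheroid_volume(80, 90, 100)$V, est2$V)
  expect_error(estimate_spheroid_volume(0, 1, 1), "positive")
})

test_that("cap surface area has the hemisphere identity and is monotone", {
  e <- 100
  expect_identical(cap_surface_area(e, e), 2 * pi * e^2)
  expect_equal(cap_surface_area(100, 50), pi * 12500)
  grid <- seq(10, 200, by = 10)
  sa_e <- cap_surface_area(grid, 50)
  sa_z <- cap_surface_area(50, grid)
  expect_true(all(diff(sa_e) > 0))
  expect_true(all(diff(sa_z) > 0))
  expect_error(cap_surface_area(-1, 5), ">= 0")
  expect_error(cap_surface_area(0, 0), "both")
})

test_that("spheroid_geometry derives e, r, V and SA consistently", {
  g <- spheroid_geometry(100, 80, 90)
  expect_equal(g$e, 90)
  expect_equal(g$r, 90)
  expect_equal(g$SA, pi * (90^2 + 90^2))
  expect_warning(g2 <- spheroid_geometry(80, 100, 90), "swap")
  expect_equal(g2$a, 100)
})

test_that("distance to the reference matches a brute-force oracle on 20^3 grids", {
  sp <- c(1, 1.5, 2)
  for (seed in 1:3) {
    set.seed(seed)
    dims <- c(20, 20, 20)
    ref_mask <- make_sphere_mask(dims, sp, c(6, 9, 12), 5 + seed)
    cell <- array(0L, dims)
    ctr <- c(sample(14:18, 1), sample(14:18, 1), sample(12:16, 1))
    cell[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <- 1L
    ref <- structure(list(mask = ref_mask, spacing = sp,
                          surface = spheroquant:::surface_voxels(ref_mask)),
                     class = "reference_surface")
    d_impl <- distance_to_reference(1, labeled_mask(cell, sp), ref)
    # oracle: min over all (cell-surface voxel, reference voxel) pairs
    cs <- which(spheroquant:::surface_voxels(cell == 1L), arr.ind = TRUE)
    rs <- which(ref_mask, arr.ind = TRUE)
    cs_um <- sweep(cs - 1, 2, sp, "*")
    rs_um <- sweep(rs - 1, 2, sp, "*")
    d_bf <- min(apply(cs_um, 1, function(p) {
      sqrt(min(colSums((t(rs_um) - p)^2)))
    }))
    if (any(cell == 1L & ref_mask)) d_bf <- 0
    expect_equal(d_impl, d_bf, tolerance = 1e-10)
  }
})

test_that("distances are zero on contact and near-analytic for point cells", {
  sp <- c(2, 2, 2)
  dims <- c(71, 61, 61)
  ref_mask <- make_sphere_mask(dims, sp, c(60, 60, 60), 50)
  ref <- structure(list(mask = ref_mask, spacing = sp,
                        surface = spheroquant:::surface_voxels(ref_mask)),
                   class = "reference_surface")
  # point cell at center distance 74: expected gap 24 within a voxel diagonal
  cell <- array(0L, dims)
  cell[134 / 2 + 1, 31, 31] <- 1L
  d <- distance_to_reference(1, labeled_mask(cell, sp), ref)
  expect_lte(abs(d - 24), sqrt(sum(sp^2)))
  # a voxel on the reference surface has distance zero
  touch <- array(0L, dims)
  touch[which(ref_mask)[1]] <- 1L
  expect_identical(distance_to_reference(1, labeled_mask(touch, sp), ref), 0)
  # centroid mode measures from the cell center instead
  d_c <- distance_to_reference(1, labeled_mask(cell, sp), ref,
                               method = "centroid")
  expect_gte(d_c, d)
})

test_that("measured sphericity of generated ellipsoids matches ground truth", {
  # spacing <= axis/10 throughout
  shapes <- list(c(12, 8, 8), c(10, 10, 6))
  for (ax in shapes) {
    sp <- rep(min(ax) / 10, 3)
    cl <- cell_spec("ellipsoid", ax, c(24, 20, 20))
    sc <- imaging_scenario(dims = ceiling(c(48, 40, 40) / sp) + 1L,
                           spacing = sp, spheroid_radius = 2,
                           spheroid_center = c(3, 3, 2.5),
                           cells = list(cl), noise_sigma = 0)
    gv <- generate_volume(sc)
    m <- segment_foreground(gv$volume, method = "otsu", min_volume = 0)
    big <- which.max(tabulate(m$labels[m$labels > 0L]))
    mm <- measure_object(big, m)
    psi_meas <- sphericity(mm$V_p, mm$A_p)
    psi_true <- gv$truth$psi[gv$truth$object == "cell"]
    expect_equal(psi_meas, psi_true, tolerance = 0.03)
  }
})
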