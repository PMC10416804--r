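test_that("a uniform volume segments to an empty mask with a warning", {
  vol <- voxel_volume(array(0, c(10, 10, 5)), c(1, 1, 1))
  expect_warning(m <- segment_foreground(vol, method = "fixed", threshold = 1),
                 "no foreground")
  expect_length(m$label_ids, 0)
})

test_that("noise-free spheres segment to exactly the rasterized truth", {
  s1 <- cell_spec("sphere", 6, c(14, 20, 20))
  s2 <- cell_spec("sphere", 8, c(50, 20, 20))
  sc <- imaging_scenario(dims = c(41, 26, 26), spacing = c(1.6, 1.6, 1.6),
                         spheroid_radius = 4, spheroid_center = c(34, 34, 4),
                         cells = list(s1, s2), noise_sigma = 0)
  gv <- generate_volume(sc)
  m <- segment_foreground(gv$volume, method = "otsu", min_volume = 0)
  expect_length(m$label_ids, 3)
  truth_fg <- gv$volume$intensities > 60
  expect_identical(m$labels > 0L, truth_fg)
  # per-object voxel counts match the per-shape rasterization
  sizes <- sort(tabulate(m$labels[m$labels > 0L]))
  count_shape <- function(spec) {
    xs <- (seq_len(41) - 1) * 1.6; ys <- (seq_len(26) - 1) * 1.6
    zs <- ys
    pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    sum(spheroquant:::points_in_shape(pts, spec))
  }
  expected <- sort(c(count_shape(s1), count_shape(s2),
                     count_shape(cell_spec("sphere", 4, c(34, 34, 4)))))
  expect_identical(sizes, expected)
})

test_that("Otsu recovers nearly all foreground under modest noise", {
  sc <- make_invasion_scenario(noise_sigma = 6, seed = 21L)
  gv <- generate_volume(sc)
  truth_sc <- make_invasion_scenario(noise_sigma = 0, seed = 21L)
  truth <- generate_volume(truth_sc)$volume$intensities > 60
  m <- segment_foreground(gv$volume, method = "otsu")
  recovered <- sum((m$labels > 0L) & truth) / sum(truth)
  expect_gte(recovered, 0.99)
})

test_that("small specks below the minimum object volume are removed", {
  arr <- array(0, c(20, 20, 10))
  arr[3:10, 3:10, 3:6] <- 100   # big object
  arr[15, 15, 8] <- 100         # single-voxel speck (8 um^3)
  vol <- voxel_volume(arr, c(2, 2, 2))
  m <- segment_foreground(vol, method = "fixed", threshold = 50,
                          min_volume = 65)
  expect_length(m$label_ids, 1)
  m2 <- segment_foreground(vol, method = "fixed", threshold = 50,
                           min_volume = 0)
  expect_length(m2$label_ids, 2)
})

test_that("cropping stops at the widest spheroid plane, ties toward the face", {
  # full sphere radius 30 um, z spacing 3 um, center at z = 33
  msk <- make_sphere_mask(c(45, 45, 23), c(1.5, 1.5, 3), c(33, 33, 33), 30)
  lm <- mask_to_labeled(msk, c(1.5, 1.5, 3))
  cr <- crop_at_widest(lm)
  expect_equal(cr$z_depth, 33) # equatorial slice (z = 33 falls on a slice)
  expect_equal(dim(cr$mask$labels)[3], 12)
  # hemispheroid with its pole at the imaging face: z_depth ~ radius
  hemi <- make_sphere_mask(c(45, 45, 11), c(1.5, 1.5, 3), c(33, 33, 30), 30)
  cr2 <- crop_at_widest(mask_to_labeled(hemi, c(1.5, 1.5, 3)))
  expect_lte(abs(cr2$z_depth - 30), 3)
  # single-slice mask: crop is identity with zero depth
  one <- array(0L, c(10, 10, 1)); one[4:6, 4:6, 1] <- 1L
  cr3 <- crop_at_widest(labeled_mask(one, c(1, 1, 1)))
  expect_equal(cr3$z_depth, 0)
  expect_identical(cr3$mask$labels, one)
  expect_error(crop_at_widest(labeled_mask(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("splitting keeps the largest component as the spheroid", {
  sc <- make_invasion_scenario(noise_sigma = 0, seed = 2L)
  gv <- generate_volume(sc)
  m <- segment_foreground(gv$volume, method = "otsu")
  parts <- split_spheroid_and_cells(m)
  expect_length(parts$spheroid$label_ids, 1)
  # capsule overlaps the spheroid (attached), so detached spheres remain
  expect_length(parts$cells$label_ids, 2)
  # one component only: no candidate cells
  solo <- mask_to_labeled(make_sphere_mask(c(20, 20, 20), c(1, 1, 1),
                                           c(9, 9, 9), 6), c(1, 1, 1))
  expect_length(split_spheroid_and_cells(solo)$cells$label_ids, 0)
})

test_that("equal-volume largest components tie to the lowest label", {
  arr <- array(0L, c(20, 10, 6))
  arr[2:4, 2:4, 2:4] <- 1L
  arr[12:14, 2:4, 2:4] <- 2L
  lm <- labeled_mask(arr, c(1, 1, 1))
  expect_warning(parts <- split_spheroid_and_cells(lm), "tie")
  expect_equal(unique(parts$spheroid$labels[arr == 1L]), 1L)
})

test_that("label voxel counts are conserved across cropping", {
  sc <- make_invasion_scenario(noise_sigma = 0, seed = 3L)
  gv <- generate_volume(sc)
  m <- segment_foreground(gv$volume, method = "otsu")
  cr <- crop_at_widest(m)
  full <- tabulate(m$labels[m$labels > 0L])
  crop <- tabulate(cr$mask$labels[cr$mask$labels > 0L], nbins = length(full))
  # cells wholly inside the crop keep their counts
  zmax <- dim(cr$mask$labels)[3]
  for (id in m$label_ids) {
    zs <- arrayInd(which(m$labels == id), dim(m$labels))[, 3]
    if (max(zs) <= zmax) expect_equal(crop[id], full[id])
  }
})

test_that("the smoothed reference removes thin spikes but keeps the bulk", {
  sp <- c(2, 2, 2)
  ball <- make_sphere_mask(c(61, 41, 41), sp, c(40, 40, 40), 30)
  # thin 20 um spike along +x from the ball surface (x = 70) out to x = 90,
  # ~4 um thick
  spike <- ball
  spike[36:46, 20:21, 20:21] <- TRUE
  lm <- mask_to_labeled(spike, sp)
  ref <- smoothed_reference_surface(lm, smoothing_scale = 10)
  # spike tip voxels are not part of the reference
  expect_false(any(ref$mask[42:46, 20:21, 20:21]))
  # the reference still encloses the opened bulk core
  core <- spheroquant:::open_ball(spike, sp, 10)
  expect_true(all(ref$mask[core]))
  # a perfect sphere is essentially unchanged (Hausdorff <= voxel diagonal)
  lm_ball <- mask_to_labeled(ball, sp)
  ref_ball <- smoothed_reference_surface(lm_ball, smoothing_scale = 10)
  diff_vox <- xor(ref_ball$mask, ball)
  if (any(diff_vox)) {
    d2 <- spheroquant:::edt_squared(ball & !diff_vox, sp)
    expect_lte(sqrt(max(d2[diff_vox])), sqrt(sum(sp^2)) + 1e-9)
  } else {
    succeed()
  }
  # zero smoothing returns the raw surface
  ref0 <- smoothed_reference_surface(lm, smoothing_scale = 0)
  expect_identical(ref0$mask, spike)
  expect_error(smoothed_reference_surface(lm, smoothing_scale = -1), ">= 0")
})

test_that("mean intensity equals the direct voxel average", {
  arr <- array(0L, c(10, 10, 4))
  arr[2:5, 2:5, 2:3] <- 1L
  lm <- labeled_mask(arr, c(1, 1, 1))
  ch <- array(7, c(10, 10, 4))
  expect_equal(mean_intensity(1, lm, voxel_volume(ch, c(1, 1, 1))), 7)
  ch2 <- ch
  sel <- which(arr == 1L)
  ch2[sel[seq_len(16)]] <- 10; ch2[sel[17:32]] <- 20
  expect_equal(mean_intensity(1, lm, voxel_volume(ch2, c(1, 1, 1))), 15)
  grad <- array(seq_len(400), c(10, 10, 4))
  expect_equal(mean_intensity(1, lm, voxel_volume(grad, c(1, 1, 1))),
               mean(grad[arr == 1L]))
  expect_error(mean_intensity(9, lm, voxel_volume(ch, c(1, 1, 1))),
               "not present")
})

test_that("the Otsu threshold agrees with the EBImage reference", {
  set.seed(12)
  # overlapping bimodal mixture: a unique between-class-variance optimum
  x <- pmin(pmax(c(rnorm(5000, 0.3, 0.08), rnorm(3000, 0.62, 0.08)), 0), 1)
  mine <- spheroquant:::otsu_threshold(x)
  ref <- EBImage::otsu(matrix(x, 80, 100), range = c(0, 1), levels = 256)
  expect_lt(abs(mine - ref), 2 / 256) # within two histogram bins
  expect_gt(mean((x > mine) == (x > ref)), 0.99)
  # well-separated modes: any threshold in the gap yields the same
  # partition even though tie-breaking on the plateau may differ
  y <- pmin(pmax(c(rnorm(4000, 0.1, 0.03), rnorm(2000, 0.8, 0.05)), 0), 1)
  mine2 <- spheroquant:::otsu_threshold(y)
  ref2 <- EBImage::otsu(matrix(y, 60, 100), range = c(0, 1), levels = 256)
  expect_identical(y > mine2, y > ref2)
})
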