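test_that("uniform soft-tissue volume raises an empty-segmentation error", {
  expect_error(segment_lungs(uniform_volume(40)),
               class = "ctild_empty_segmentation_error")
  expect_error(segment_lungs(uniform_volume(40)), "-1024")
})

test_that("noise-free phantom is segmented exactly, trachea removed", {
  # default 96-grid: the trachea column is large enough to pass the size
  # filter, so removal must happen through the top-central rule
  ph <- generate_phantom(phantom_spec(target_fibrotic_fraction = 0.25,
                                      noise_sd = 0, seed = 1))
  m <- segment_lungs(ph$volume)
  expect_identical(m$mask, ph$truth_mask$mask)
  expect_gte(m$provenance$trachea_components_removed, 1L)
})

test_that("noisy phantoms are recovered with Dice >= 0.98 across seeds", {
  for (s in 1:6) {
    ph <- generate_phantom(small_phantom_spec(fraction = 0.3, seed = s))
    m <- segment_lungs(ph$volume)
    expect_gte(dice(m, ph$truth_mask), 0.98)
  }
})

test_that("the mask is a subset of the thresholded voxel set", {
  params <- segmentation_params()
  for (s in 1:3) {
    ph <- generate_phantom(small_phantom_spec(fraction = 0.5, seed = 10 + s))
    m <- segment_lungs(ph$volume, params)
    inband <- ph$volume$voxels >= params$lung_band[1] &
      ph$volume$voxels <= params$lung_band[2]
    expect_true(all(inband[m$mask]))
  }
})

test_that("segmentation is idempotent", {
  ph <- generate_phantom(small_phantom_spec(seed = 21))
  expect_identical(segment_lungs(ph$volume)$mask,
                   segment_lungs(ph$volume)$mask)
})

test_that("enlarging the band's upper bound never shrinks the candidate mask", {
  # interior blob spanning several attenuation levels, away from borders
  dims <- c(24L, 24L, 3L)
  vox <- array(40, dims)
  set.seed(99)
  vox[8:16, 8:16, ] <- sample(seq(-900, -150, by = 50), 9 * 9 * 3, TRUE)
  v <- ct_volume(vox)
  masks <- lapply(c(-400, -300, -200, -150), function(up)
    segment_lungs(v, segmentation_params(lung_band = c(-1024, up),
                                         min_component_voxels = 1L,
                                         trachea_policy = "none"))$mask)
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i + 1]][masks[[i]]]))
})

test_that("3-D connectivity mode also recovers the phantom", {
  ph <- generate_phantom(small_phantom_spec(seed = 31))
  m <- segment_lungs(ph$volume, segmentation_params(connectivity = "3d"))
  expect_gte(dice(m, ph$truth_mask), 0.98)
})

test_that("manual exclusions remove exactly the outlined voxels", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  m <- segment_lungs(ph$volume)

  expect_identical(apply_manual_exclusions(m, list()), m)

  # rectangle strictly containing a known set of voxel centres on slice 4
  rect <- list(slice = 4L, poly = cbind(c(19.5, 30.5, 30.5, 19.5),
                                        c(9.5, 9.5, 20.5, 20.5)))
  k <- sum(m$mask[20:30, 10:20, 4])  # brute-force point-in-rectangle count
  expect_gt(k, 0)
  m2 <- apply_manual_exclusions(m, list(rect))
  expect_equal(m$n_voxels - m2$n_voxels, k)
  expect_false(any(m2$mask[20:30, 10:20, 4]))

  # a polygon covering the whole grid empties the mask
  d <- dim(m$mask)
  all_poly <- list(slice = 4L,
                   poly = cbind(c(0.5, d[1] + 0.5, d[1] + 0.5, 0.5),
                                c(0.5, 0.5, d[2] + 0.5, d[2] + 0.5)))
  m3 <- apply_manual_exclusions(m, list(all_poly))
  expect_equal(sum(m3$mask[, , 4]), 0)
  expect_lte(m3$n_voxels, m$n_voxels)

  expect_error(apply_manual_exclusions(m, list(list(slice = 99L,
                                                    poly = rect$poly))),
               class = "ctild_bounds_error")
})

test_that("closing fills small holes when requested", {
  dims <- c(20L, 20L, 1L)
  vox <- array(40, dims)
  vox[5:15, 5:15, 1] <- -850
  vox[10, 10, 1] <- 40  # one-voxel vessel hole
  v <- ct_volume(vox)
  p_open <- segmentation_params(min_component_voxels = 1L,
                                trachea_policy = "none")
  p_closed <- segmentation_params(min_component_voxels = 1L,
                                  trachea_policy = "none",
                                  closing_radius_vox = 1.5)
  expect_false(segment_lungs(v, p_open)$mask[10, 10, 1])
  expect_true(segment_lungs(v, p_closed)$mask[10, 10, 1])
})
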