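make_vol <- function(hu, phases = 2) {
  ct_volume_4d(array(rep(hu, phases), dim = c(dim(hu), phases)),
               spacing = c(1, 1, 1), origin = c(0, 0, 0))
}

test_that("threshold bounds are inclusive on both ends", {
  hu <- array(40, dim = c(4, 4, 4))
  hu[1, 1, 1] <- 159; hu[2, 1, 1] <- 160; hu[3, 1, 1] <- 500
  hu[4, 1, 1] <- 890; hu[1, 2, 1] <- 891
  m <- threshold_lumen(make_vol(hu))
  expect_false(m$mask[1, 1, 1, 1])
  expect_true(m$mask[2, 1, 1, 1])
  expect_true(m$mask[3, 1, 1, 1])
  expect_true(m$mask[4, 1, 1, 1])
  expect_false(m$mask[1, 2, 1, 1])
  expect_error(threshold_lumen(make_vol(hu), low = 800, high = 100),
               class = "p4d_invalid_argument")
})

test_that("pure-background volume yields an empty mask with a warning", {
  hu <- array(40, dim = c(4, 4, 4))
  expect_warning(m <- threshold_lumen(make_vol(hu)),
                 class = "p4d_empty_segmentation")
  expect_false(any(m$mask))
})

test_that("thresholding is deterministic and monotone in the lower bound", {
  set.seed(42)
  hu <- array(runif(6^3, 0, 1000), dim = c(6, 6, 6))
  vol <- make_vol(hu)
  m1 <- threshold_lumen(vol, 160, 890)
  expect_identical(m1$mask, threshold_lumen(vol, 160, 890)$mask)
  for (low in c(200, 400, 600)) {
    m2 <- threshold_lumen(vol, low, 890)
    expect_true(all(m1$mask | !m2$mask))   # raising `low` never adds voxels
  }
})

test_that("VOI crop clears outside voxels and validates bounds", {
  hu <- array(500, dim = c(10, 10, 10))
  vol <- make_vol(hu)
  m <- threshold_lumen(vol)
  full <- crop_voi(m, c(0, 10, 0, 10, 0, 10))
  expect_identical(full$mask, m$mask)
  half <- crop_voi(m, c(0, 5, 0, 10, 0, 10))
  expect_equal(sum(half$mask[, , , 1]), 5 * 10 * 10)
  expect_error(crop_voi(m, c(0, 11, 0, 10, 0, 10)),
               class = "p4d_invalid_argument")
  expect_error(crop_voi(m, c(3, 3, 0, 10, 0, 10)),
               class = "p4d_invalid_argument")
  # a VOI missing the structure empties the mask with a warning
  hu2 <- array(40, dim = c(10, 10, 10)); hu2[1:2, 1:2, 1:2] <- 500
  m2 <- threshold_lumen(make_vol(hu2))
  expect_warning(crop_voi(m2, c(5, 10, 5, 10, 5, 10)),
                 class = "p4d_empty_segmentation")
})

test_that("component filtering keeps only the seeded 26-component", {
  hu <- array(40, dim = c(12, 12, 12))
  hu[2:4, 2:4, 2:4] <- 500       # cube A
  hu[8:11, 8:11, 8:11] <- 500    # cube B, disjoint
  m <- threshold_lumen(make_vol(hu))
  kA <- keep_component(m, c(2, 2, 2))
  expect_equal(sum(kA$mask[, , , 1]), 27)
  expect_true(all(which(kA$mask[, , , 1], arr.ind = TRUE) <= 4))
  kB <- keep_component(m, c(9, 9, 9))
  expect_equal(sum(kB$mask[, , , 1]), 64)
  single <- keep_component(kA, c(2, 2, 2))
  expect_identical(single$mask, kA$mask)
  expect_error(keep_component(m, c(6, 6, 6)), class = "p4d_seed_error")
  expect_error(keep_component(m, c(40, 0, 0)), class = "p4d_seed_error")
})

test_that("seed transfers to the nearest masked voxel on later phases", {
  hu1 <- array(40, dim = c(8, 8, 8)); hu1[3:5, 3:5, 3:5] <- 500
  hu2 <- array(40, dim = c(8, 8, 8)); hu2[4:6, 4:6, 4:6] <- 500  # shifted
  vox <- array(c(hu1, hu2), dim = c(8, 8, 8, 2))
  m <- threshold_lumen(ct_volume_4d(vox, c(1, 1, 1), c(0, 0, 0)))
  k <- keep_component(m, c(2, 2, 2))   # in mask at phase 0 only
  expect_equal(sum(k$mask[, , , 1]), 27)
  expect_equal(sum(k$mask[, , , 2]), 27)
})

test_that("masked volume at half-maximum matches the analytic lumen volume", {
  r <- default_digital()
  spec <- r$truth$spec
  m <- threshold_lumen(r$volume, low = 220, high = 890)
  vox_vol <- sum(m$mask[, , , 1]) * prod(spec$spacing)
  # analytic lumen inside the grid: tube (pi rv^2 Lz) + sphere \ cylinder
  Lz <- spec$grid_shape[3] * spec$spacing[3]
  v_tube <- pi * spec$vessel_radius^2 * Lz
  analytic <- v_tube + mc_sphere_minus_cyl(r$truth)
  expect_equal(vox_vol, analytic, tolerance = 0.03)
})
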