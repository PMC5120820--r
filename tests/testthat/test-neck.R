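test_that("cut surface over 3 points is their triangle", {
  pts <- neck_points(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)))
  cut <- build_cut_surface(pts)
  expect_equal(nrow(cut$faces), 3L)  # centroid fan over a triangle
  expect_equal(cut$area, 3, tolerance = 1e-12)  # = triangle area
  expect_equal(abs(cut$normal), c(0, 0, 1), tolerance = 1e-12)
})

test_that("octagon fan area matches the closed form and point order is canonical", {
  r <- 3
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(r * cos(th), r * sin(th), 0)
  cut <- build_cut_surface(neck_points(pts))
  expect_equal(cut$area, 2 * sqrt(2) * r^2, tolerance = 1e-12)
  expect_lt(abs(cut$area - pi * r^2) / (pi * r^2), 0.14)
  for (s in 1:5) {
    shuf <- pts[sample(8), ]
    cut2 <- build_cut_surface(neck_points(shuf))
    expect_equal(cut2$points, cut$points)
    expect_equal(cut2$apex, cut$apex)
  }
})

test_that("collinear neck points are rejected", {
  expect_error(neck_points(cbind(1:5, 2 * (1:5), 0 * (1:5))),
               class = "p4d_invalid_geometry")
  pts3 <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0))
  expect_error(neck_points(pts3), class = "p4d_invalid_geometry")
})

test_that("neck transfer is exact on a constant phantom", {
  r <- default_flat()
  pts <- transfer_neck_points(r$points0, r$mesh_seq)
  for (p in 2:length(r$mesh_seq))
    expect_equal(unclass(pts[[p]]), unclass(pts[[1]]), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("neck transfer follows a pure per-phase translation", {
  shift <- outer(seq(0, 0.2, length.out = 10), c(1, 0, 0))
  spec <- phantom_spec(pulsation_amplitude = 1, noise_fraction = 0,
                       rigid_motion = list(translations = shift))
  r <- measure_phantom(spec)
  pts <- transfer_neck_points(r$points0, r$mesh_seq)
  base <- unclass(pts[[1]])
  for (p in c(5, 10)) {
    moved <- unclass(pts[[p]])
    delta <- sweep(moved, 2, shift[p, ]) - base
    # snapped to a 0.39/0.5 mm lattice surface: allow half a voxel
    expect_lt(sqrt(max(rowSums(delta^2))), 0.3)
  }
})

test_that("transferred points stay on the true ostium while pulsating", {
  r <- default_noisefree()
  pts <- transfer_neck_points(r$points0, r$mesh_seq)
  diag_mm <- sqrt(sum(r$truth$spec$spacing^2))
  for (p in seq_along(pts)) {
    dj <- dense_junction(r$truth, phase = p)
    d <- vapply(seq_len(nrow(pts[[p]])), function(i)
      sqrt(min(colSums((t(dj) - pts[[p]][i, ])^2))), numeric(1))
    expect_lt(max(d), diag_mm)
  }
})

test_that("partition recovers the analytic dome volume with the true neck", {
  r <- default_digital()
  seg <- partition_mesh(r$mesh_seq$meshes[[1]],
                        build_cut_surface(transfer_neck_points(r$points0, r$mesh_seq)[[1]]),
                        r$truth$dome_seed)
  oracle <- mc_membrane_volume(r$truth)
  expect_equal(seg$volume, oracle, tolerance = 0.02)
})

test_that("aneurysm and vessel volumes add up to the whole lumen", {
  r <- default_noisefree()
  cut <- build_cut_surface(transfer_neck_points(r$points0, r$mesh_seq)[[1]])
  seg <- partition_mesh(r$mesh_seq$meshes[[1]], cut, r$truth$dome_seed)
  expect_equal(seg$volume + seg$vessel_volume, seg$total_volume,
               tolerance = 1e-3)
  expect_true(seg$watertight || is_watertight(seg$mesh) ||
                pulse4d:::is_closed_surface(seg$mesh$faces))
})

test_that("reordering neck points leaves the measured volume unchanged", {
  r <- default_noisefree()
  pts <- transfer_neck_points(r$points0, r$mesh_seq)[[1]]
  seg1 <- partition_mesh(r$mesh_seq$meshes[[1]], build_cut_surface(pts),
                         r$truth$dome_seed)
  set.seed(1)
  pts2 <- neck_points(unclass(pts)[sample(nrow(pts)), ])
  seg2 <- partition_mesh(r$mesh_seq$meshes[[1]], build_cut_surface(pts2),
                         r$truth$dome_seed)
  expect_equal(seg2$volume, seg1$volume, tolerance = 1e-12)
})

test_that("a dome seed on the parent vessel is detected", {
  r <- default_noisefree()
  cut <- build_cut_surface(transfer_neck_points(r$points0, r$mesh_seq)[[1]])
  spec <- r$truth$spec
  vessel_seed <- spec$vessel_point + c(0, 0, 5)
  res <- tryCatch(partition_mesh(r$mesh_seq$meshes[[1]], cut, vessel_seed),
                  error = function(e) e)
  good <- partition_mesh(r$mesh_seq$meshes[[1]], cut, r$truth$dome_seed)
  if (inherits(res, "error")) {
    expect_s3_class(res, "p4d_leak_error")
  } else {
    # the complementary (vessel) side was selected
    expect_equal(res$volume, good$vessel_volume, tolerance = 0.02)
    expect_gt(abs(res$volume - good$volume) / good$volume, 0.1)
  }
})

test_that("a cut surface missing the mesh raises a leak error", {
  r <- default_noisefree()
  far <- neck_points(rbind(c(30, 30, 30), c(32, 30, 30), c(30, 33, 31)))
  expect_error(partition_mesh(r$mesh_seq$meshes[[1]], build_cut_surface(far),
                              r$truth$dome_seed),
               class = "p4d_leak_error")
})

test_that("volume curve of a constant phantom is constant", {
  r <- default_flat()
  expect_lt(diff(range(r$curve$values)) / mean(r$curve$values), 0.005)
  expect_true(all(r$curve$diagnostics$watertight))
})

test_that("volume curve recovers a 1.06 amplitude on noise-free input", {
  r <- default_noisefree()
  amp <- pulsation_amplitude(r$curve)
  expect_gte(amp, 1.05)
  expect_lte(amp, 1.07)
})

test_that("sub-voxel translation of every phase cancels in the volumes", {
  # supersample 5: the rasterizer's own quantization under sub-voxel shifts
  # (0.7% at the default 3) must stay below the 1% effect bound being tested
  shift <- outer(seq(0, 0.2, length.out = 10), c(1, 0, 0))
  spec <- phantom_spec(pulsation_amplitude = 1, noise_fraction = 0,
                       supersample = 5L,
                       rigid_motion = list(translations = shift))
  r <- measure_phantom(spec, npts = 24)
  expect_lt(max(abs(r$curve$values - r$curve$values[1])) / r$curve$values[1],
            0.01)
})

test_that("noisy pulsatile curve beats the random-null 97.5th percentile", {
  res <- measure_phantom(phantom_spec(pulsation_amplitude = 1.06,
                                      noise_fraction = 0.18, seed = 7),
                         smooth = 0.4)
  pw <- generate_pulse_template(10)
  d <- hausdorff_distance(normalize_minmax(res$curve), pw)
  null <- generate_random_null(n_curves = 200, seed = 123, pulse = pw,
                               renorm = TRUE)
  expect_lt(d, quantile(null$distances, 0.975))
})
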