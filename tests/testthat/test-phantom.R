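test_that("ground-truth volume curve is the pulse template, amplitude exact", {
  spec <- phantom_spec(pulsation_amplitude = 1.06, noise_fraction = 0)
  ph <- generate_phantom_4d(spec)
  v <- ph$truth$volumes
  expect_equal(max(v) / min(v), 1.06, tolerance = 1e-12)
  mm <- (v - min(v)) / diff(range(v))
  expect_equal(mm, spec$pulse_template, tolerance = 1e-9)
})

test_that("non-pulsating noise-free phantom has identical phases", {
  spec <- phantom_spec(pulsation_amplitude = 1, noise_fraction = 0)
  ph <- generate_phantom_4d(spec)
  expect_equal(length(unique(ph$truth$volumes)), 1L)
  for (p in 2:spec$n_phases)
    expect_identical(ph$volume$voxels[, , , p], ph$volume$voxels[, , , 1])
})

test_that("same spec and seed give bit-identical volumes", {
  spec <- phantom_spec(noise_fraction = 0.18, seed = 5)
  a <- generate_phantom_4d(spec)
  b <- generate_phantom_4d(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  spec2 <- phantom_spec(noise_fraction = 0.18, seed = 6)
  expect_false(identical(generate_phantom_4d(spec2)$volume$voxels,
                         a$volume$voxels))
})

test_that("intraluminal noise SD matches the requested fraction", {
  spec <- phantom_spec(pulsation_amplitude = 1, noise_fraction = 0.18, seed = 3)
  ph <- generate_phantom_4d(spec)
  # homogeneous ROI: voxels deep inside the aneurysm (1.5 mm from the wall)
  g <- spec$grid_shape
  idx <- as.matrix(expand.grid(1:g[1], 1:g[2], 1:g[3]))
  w <- voxel_to_world(idx - 1, spec$spacing, spec$origin)
  roi <- rowSums(sweep(w, 2, spec$aneurysm_center)^2) <= (spec$aneurysm_base_radius - 1.5)^2
  vals <- ph$volume$voxels[, , , 1][roi]
  expect_gt(length(vals), 50)
  expect_equal(sd(vals), 0.18 * 400, tolerance = 0.10)
})

test_that("doubling supersampling barely changes the rasterized volume", {
  lum_vol <- function(S) {
    spec <- phantom_spec(pulsation_amplitude = 1, noise_fraction = 0,
                         psf_sigma = 0, supersample = S, n_phases = 2)
    ph <- generate_phantom_4d(spec)
    sum((ph$volume$voxels[, , , 1] - 40) / 360) * prod(spec$spacing)
  }
  v3 <- lum_vol(3L); v6 <- lum_vol(6L)
  expect_lt(abs(v6 - v3) / v3, 0.005)
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_spec(aneurysm_center = c(20, 0, 0)),
               class = "p4d_invalid_geometry")  # sphere detached from vessel
  expect_error(phantom_spec(aneurysm_center = c(0.5, 0, 0)),
               class = "p4d_invalid_geometry")  # centre inside the vessel
  expect_error(phantom_spec(pulsation_amplitude = 0.9),
               class = "p4d_invalid_argument")
  expect_error(phantom_spec(n_phases = 1), class = "p4d_invalid_argument")
  expect_error(phantom_spec(spacing = c(0.39, -1, 0.5)),
               class = "p4d_invalid_argument")
  expect_error(phantom_spec(pulse_template = generate_pulse_template(5)),
               class = "p4d_invalid_argument")
})

test_that("ground-truth neck ring lies on the lumen surface", {
  r <- default_digital()
  ring <- r$truth$neck_rings[[1]]
  spec <- r$truth$spec
  # each ring point satisfies both surface equations within tolerance
  on_sph <- abs(sqrt(rowSums(sweep(ring, 2, spec$aneurysm_center)^2)) -
                  r$truth$radii[1])
  ax <- sweep(ring, 2, spec$vessel_point)
  tpar <- ax %*% spec$vessel_axis
  on_tub <- abs(sqrt(rowSums((ax - tpar %*% t(spec$vessel_axis))^2)) -
                  spec$vessel_radius)
  expect_lt(max(pmin(on_sph, on_tub)), 1e-9)
  expect_lt(max(pmax(on_sph, on_tub)), 0.35)  # near the junction curve
})

test_that("rigid motion resampling is identity for the null transform", {
  spec <- phantom_spec(pulsation_amplitude = 1, noise_fraction = 0)
  ph <- generate_phantom_4d(spec)
  v0 <- ph$volume$voxels[, , , 1]
  v1 <- apply_rigid_motion(v0, c(0, 0, 0), 0, spec$spacing, spec$origin)
  expect_equal(v1, v0, tolerance = 1e-12)
  expect_error(apply_rigid_motion(v0, c(50, 0, 0), 0, spec$spacing, spec$origin),
               class = "p4d_out_of_bounds")
})
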