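test_that("isosurface volume of a 5 mm digital sphere is within 1% of analytic", {
  vol <- digital_sphere_volume(h = 0.25)
  mask <- threshold_lumen(vol)
  mesh <- extract_isosurface(vol, mask, phase = 0, iso = 220)  # half-maximum
  v <- mesh_enclosed_volume(mesh)
  analytic <- 4 / 3 * pi * 2.5^3
  expect_equal(as.numeric(v), analytic, tolerance = 0.01)
  expect_true(is_watertight(mesh))
  expect_gt(attr(v, "area"), 4 * pi * 2.5^2 * 0.95)
})

test_that("refining the grid reduces the sphere volume error", {
  analytic <- 4 / 3 * pi * 2.5^3
  err <- function(h) {
    vol <- digital_sphere_volume(h = h)
    mesh <- extract_isosurface(vol, threshold_lumen(vol), 0, iso = 220)
    abs(as.numeric(mesh_enclosed_volume(mesh, check = FALSE)) - analytic)
  }
  expect_lt(err(0.2), err(0.4))
})

test_that("empty masks cannot be isosurfaced", {
  hu <- array(40, dim = c(5, 5, 5, 2))
  vol <- ct_volume_4d(hu, c(1, 1, 1), c(0, 0, 0))
  suppressWarnings(mask <- threshold_lumen(vol))
  expect_error(extract_isosurface(vol, mask, 0), class = "p4d_empty_mesh")
})

test_that("unit cube volume is exactly 1, inward orientation is corrected", {
  cube <- unit_cube_mesh()
  expect_equal(as.numeric(mesh_enclosed_volume(cube)), 1)
  expect_equal(as.numeric(attr(mesh_enclosed_volume(cube), "area")), 6)
  flipped <- cube
  flipped$faces <- cube$faces[, c(1, 3, 2)]
  expect_warning(v <- mesh_enclosed_volume(flipped),
                 class = "p4d_orientation_corrected")
  expect_equal(as.numeric(v), 1)
})

test_that("open meshes are rejected with a boundary-edge count", {
  cube <- unit_cube_mesh()
  cube$faces <- cube$faces[-1, ]
  err <- tryCatch(mesh_enclosed_volume(cube), error = function(e) e)
  expect_s3_class(err, "p4d_open_mesh")
  expect_match(conditionMessage(err), "3 boundary")
})

test_that("subdivided icosahedra converge to the sphere volume from below", {
  analytic <- 4 / 3 * pi
  v0 <- as.numeric(mesh_enclosed_volume(icosphere_mesh(0)))
  v1 <- as.numeric(mesh_enclosed_volume(icosphere_mesh(1)))
  v2 <- as.numeric(mesh_enclosed_volume(icosphere_mesh(2)))
  expect_lt(v0, v1); expect_lt(v1, v2); expect_lt(v2, analytic)
  expect_equal(v2, analytic, tolerance = 0.05)
})

test_that("enclosed volume is rigid-motion invariant", {
  m <- icosphere_mesh(2)
  v0 <- as.numeric(mesh_enclosed_volume(m))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2$vertices <- sweep(m$vertices %*% t(R), 2, c(13.2, -4.1, 7.7), "+")
  expect_equal(as.numeric(mesh_enclosed_volume(m2)), v0, tolerance = 1e-9)
})

test_that("whole-lumen mesh volumes track the true volumes in rank", {
  r <- default_noisefree()
  mesh_vols <- vapply(r$mesh_seq$meshes, function(m)
    as.numeric(mesh_enclosed_volume(m, check = FALSE)), numeric(1))
  expect_equal(cor(mesh_vols, r$truth$volumes, method = "spearman"), 1)
})

test_that("upper-threshold clamping removes bright structures", {
  hu <- array(40, dim = c(12, 12, 12))
  hu[3:6, 3:6, 3:6] <- 500     # lumen
  hu[9:11, 9:11, 9:11] <- 1500 # bone/calcification
  vol <- ct_volume_4d(array(rep(hu, 2), dim = c(12, 12, 12, 2)),
                      c(1, 1, 1), c(0, 0, 0))
  mask <- threshold_lumen(vol)
  mesh <- extract_isosurface(vol, mask, 0, iso = 270)
  # all vertices belong to the lumen cube, none to the bright block
  expect_lt(max(mesh$vertices), 7.5)
})
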