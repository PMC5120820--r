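#' Specification of a synthetic pulsating-aneurysm 4D-CTA phantom
#'
#' Describes a contrast-enhanced vascular lumen (a straight parent vessel of
#' radius `vessel_radius` plus a spherical aneurysm) on a soft-tissue
#' background, sampled on the acquisition grid of a cerebral 4D-CTA protocol
#' (0.39 x 0.39 mm in-plane, 0.5 mm slices, 10 cardiac phases). The aneurysm
#' dome volume is driven linearly by an arterial pulse-wave template:
#' V(p) = Vmin * (1 + (A - 1) * w(p)) with amplitude A = Vmax/Vmin, and the
#' per-phase sphere radius is recovered from the target dome volume, so the
#' ground-truth amplitude is exact by construction. Intraluminal image noise
#' is i.i.d. Gaussian with SD `noise_fraction * lumen_hu` (18% emulates the
#' noise measured in a homogeneous aneurysm ROI of the reference protocol).
#'
#' @param grid_shape integer voxels per axis (x, y, z).
#' @param spacing mm per axis; default c(0.39, 0.39, 0.5).
#' @param n_phases cardiac phases per cycle (default 10).
#' @param vessel_radius parent-vessel radius, mm.
#' @param vessel_axis unit direction of the vessel (default z).
#' @param vessel_point a point on the vessel axis, mm.
#' @param aneurysm_center sphere centre at the reference phase, mm.
#' @param aneurysm_base_radius sphere radius at minimal volume, mm.
#' @param lumen_hu,background_hu attenuation of lumen and background (HU).
#' @param noise_fraction noise SD as a fraction of `lumen_hu` (default 0.18).
#' @param pulsation_amplitude target Vmax/Vmin >= 1 (default 1.06).
#' @param pulse_template a [generate_pulse_template()] wave; defaults to the
#'   built-in MCA-like shape at `n_phases`.
#' @param rigid_motion optional list with `translations` (n_phases x 3 mm
#'   matrix) and/or `rotations_deg` (length n_phases, about the vessel axis
#'   through `aneurysm_center`), applied analytically to the geometry.
#' @param psf_sigma Gaussian partial-volume blur, mm (default 0.4).
#' @param supersample occupancy supersampling factor per axis (default 3).
#' @param seed RNG seed for the noise field.
#' @param origin world position (mm) of voxel (0,0,0) centre; default centres
#'   the grid between vessel axis and aneurysm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(34L, 26L, 26L),
                         spacing = c(0.39, 0.39, 0.5),
                         n_phases = 10L,
                         vessel_radius = 1.5,
                         vessel_axis = c(0, 0, 1),
                         vessel_point = c(0, 0, 0),
                         aneurysm_center = c(3.5, 0, 0),
                         aneurysm_base_radius = 3,
                         lumen_hu = 400, background_hu = 40,
                         noise_fraction = 0.18,
                         pulsation_amplitude = 1.06,
                         pulse_template = NULL,
                         rigid_motion = NULL,
                         psf_sigma = 0.4,
                         supersample = 3L,
                         seed = 1L,
                         origin = NULL) {
  if (any(spacing <= 0)) p4d_stop("spacing must be > 0", "p4d_invalid_argument")
  n_phases <- as.integer(n_phases)
  if (n_phases < 2L) p4d_stop("n_phases must be >= 2", "p4d_invalid_argument")
  if (pulsation_amplitude < 1)
    p4d_stop("pulsation_amplitude must be >= 1", "p4d_invalid_argument")
  if (is.null(pulse_template)) pulse_template <- generate_pulse_template(n_phases)
  if (length(pulse_template) != n_phases)
    p4d_stop("pulse_template length must equal n_phases", "p4d_invalid_argument")
  vessel_axis <- vessel_axis / sqrt(sum(vessel_axis^2))
  if (is.null(origin)) {
    ctr <- (vessel_point + aneurysm_center) / 2
    origin <- ctr - (grid_shape - 1) * spacing / 2
  }
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = spacing, n_phases = n_phases,
    vessel_radius = vessel_radius, vessel_axis = vessel_axis,
    vessel_point = vessel_point, aneurysm_center = aneurysm_center,
    aneurysm_base_radius = aneurysm_base_radius,
    lumen_hu = lumen_hu, background_hu = background_hu,
    noise_fraction = noise_fraction,
    pulsation_amplitude = pulsation_amplitude,
    pulse_template = as.numeric(pulse_template),
    rigid_motion = rigid_motion, psf_sigma = psf_sigma,
    supersample = as.integer(supersample), seed = as.integer(seed),
    origin = origin), class = "phantom_spec")
  # geometric neck check at every phase (errors if sphere and tube detach)
  invisible(phantom_radii(spec))
  spec
}

# squared distance from points to the vessel axis line
axis_dist2 <- function(px, py, pz, p0, v) {
  dx <- px - p0[1]; dy <- py - p0[2]; dz <- pz - p0[3]
  t <- dx * v[1] + dy * v[2] + dz * v[3]
  (dx - t * v[1])^2 + (dy - t * v[2])^2 + (dz - t * v[3])^2
}

# Analytic aneurysm (dome) volume for sphere radius R: the part of the
# sphere beyond the neck plane. The neck plane is perpendicular to the
# radial direction from vessel axis to sphere centre, at the radial offset
# where sphere and tube surfaces cross (their radical plane in the
# cross-section), a = (d^2 + rv^2 - R^2) / (2 d) from the axis.
dome_volume <- function(R, d, rv) {
  cc <- (d^2 + R^2 - rv^2) / (2 * d)  # plane distance from sphere centre
  if (abs(cc) >= R) return(NA_real_)  # plane misses sphere: no neck
  h <- R + cc
  pi * h^2 * (3 * R - h) / 3
}

# per-phase sphere radii realizing the linearly driven dome-volume targets
phantom_radii <- function(spec) {
  d <- {
    dp <- spec$aneurysm_center - spec$vessel_point
    t <- sum(dp * spec$vessel_axis)
    sqrt(sum((dp - t * spec$vessel_axis)^2))
  }
  rv <- spec$vessel_radius
  R0 <- spec$aneurysm_base_radius
  if (d <= rv)
    p4d_stop("aneurysm centre inside the vessel: no neck", "p4d_invalid_geometry")
  vmin <- dome_volume(R0, d, rv)
  if (is.na(vmin) || d >= R0 + rv)
    p4d_stop("aneurysm sphere and vessel do not intersect: no neck",
             "p4d_invalid_geometry")
  w <- spec$pulse_template
  targets <- vmin * (1 + (spec$pulsation_amplitude - 1) * w)
  radii <- vapply(targets, function(V) {
    if (abs(V - vmin) < .Machine$double.eps * vmin) return(R0)
    # targets are >= vmin, so the root lies at R >= R0 (V is monotone in R)
    # the neck exists only while R < d + rv (sphere not engulfing the tube)
    uniroot(function(R) dome_volume(R, d, rv) - V,
            lower = 0.999 * R0, upper = d + rv - 1e-9, tol = 1e-13)$root
  }, numeric(1))
  for (R in radii) {
    if (is.na(dome_volume(R, d, rv)) || d >= R + rv)
      p4d_stop("neck vanishes at some phase", "p4d_invalid_geometry")
  }
  list(radii = radii, volumes = targets, d = d, vmin = vmin)
}

# per-phase rigid transform (rotation about vessel axis through the
# aneurysm centre, then translation); identity when no motion requested
phantom_transforms <- function(spec) {
  n <- spec$n_phases
  lapply(seq_len(n), function(p) {
    tr <- c(0, 0, 0); ang <- 0
    if (!is.null(spec$rigid_motion)) {
      if (!is.null(spec$rigid_motion$translations))
        tr <- spec$rigid_motion$translations[p, ]
      if (!is.null(spec$rigid_motion$rotations_deg))
        ang <- spec$rigid_motion$rotations_deg[p]
    }
    R <- rotation_about_axis(spec$vessel_axis, ang)
    list(R = R, t = tr, pivot = spec$aneurysm_center, angle_deg = ang)
  })
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

apply_tf_points <- function(pts, tf) {
  sweep(sweep(pts, 2, tf$pivot) %*% t(tf$R), 2, tf$pivot + tf$t, "+")
}

#' Generate a synthetic 4D-CTA phantom with analytic ground truth
#'
#' Rasterizes the lumen (vessel tube union pulsating sphere) by supersampled
#' occupancy, maps occupancy fractions to HU, applies a Gaussian
#' partial-volume PSF and adds seeded i.i.d. Gaussian noise. The returned
#' ground truth carries the exact analytic dome volumes (their max/min ratio
#' equals the requested amplitude by construction), the per-phase neck ring
#' (circle where the neck plane cuts the sphere) and applied transforms.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a `ct_volume_4d`) and `truth`
#'   (class `phantom_truth`: `volumes`, `radii`, `neck_rings`, `neck_plane`,
#'   `transforms`, `dome_seed`, `spec`).
#' @export
generate_phantom_4d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_radii(spec)
  tfs <- phantom_transforms(spec)
  gs <- spec$grid_shape; sp <- spec$spacing; or <- spec$origin
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  nvox <- nx * ny * nz

  xs <- or[1] + (seq_len(nx) - 1) * sp[1]
  ys <- or[2] + (seq_len(ny) - 1) * sp[2]
  zs <- or[3] + (seq_len(nz) - 1) * sp[3]
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)

  S <- spec$supersample
  offs <- ((seq_len(S) - 0.5) / S - 0.5)
  grid_off <- expand.grid(ox = offs * sp[1], oy = offs * sp[2], oz = offs * sp[3])
  nshift <- nrow(grid_off)

  moving <- !is.null(spec$rigid_motion)
  # tube occupancy per shift is phase-invariant without rigid motion
  tube_in <- NULL
  if (!moving) {
    tube_in <- matrix(FALSE, nvox, nshift)
    for (s in seq_len(nshift)) {
      tube_in[, s] <- axis_dist2(X + grid_off$ox[s], Y + grid_off$oy[s],
                                 Z + grid_off$oz[s],
                                 spec$vessel_point, spec$vessel_axis) <=
        spec$vessel_radius^2
    }
  }

  vox <- array(0, dim = c(gs, spec$n_phases))
  rv2 <- spec$vessel_radius^2
  for (p in seq_len(spec$n_phases)) {
    tf <- tfs[[p]]
    ctr <- apply_tf_points(matrix(spec$aneurysm_center, 1), tf)[1, ]
    R2 <- geo$radii[p]^2
    acc <- numeric(nvox)
    if (moving) {
      p0 <- apply_tf_points(matrix(spec$vessel_point, 1), tf)[1, ]
      v <- as.vector(tf$R %*% spec$vessel_axis)
    }
    for (s in seq_len(nshift)) {
      px <- X + grid_off$ox[s]; py <- Y + grid_off$oy[s]; pz <- Z + grid_off$oz[s]
      sph <- (px - ctr[1])^2 + (py - ctr[2])^2 + (pz - ctr[3])^2 <= R2
      tub <- if (moving) axis_dist2(px, py, pz, p0, v) <= rv2 else tube_in[, s]
      acc <- acc + (sph | tub)
    }
    frac <- acc / nshift
    hu <- spec$background_hu + frac * (spec$lumen_hu - spec$background_hu)
    ph <- array(hu, dim = gs)
    if (spec$psf_sigma > 0) ph <- gaussian_blur_3d(ph, spec$psf_sigma, sp)
    vox[, , , p] <- ph
  }

  if (spec$noise_fraction > 0) {
    sd_hu <- spec$noise_fraction * spec$lumen_hu
    vox <- vox + with_seed(spec$seed,
                           array(rnorm(length(vox), 0, sd_hu), dim = dim(vox)))
  }

  # Ground-truth neck ring: the sphere-tube junction curve (the ostium a
  # rater traces on the 3D model). In the frame (u = radial from axis foot
  # to sphere centre, v = vessel axis, w2 = u x v) the curve satisfies
  # x = a + z^2/(2d), x^2 + y^2 = rv^2; parametrized so points lie on the
  # lumen surface all around the ostium. 24 points per phase.
  d <- geo$d
  dp <- spec$aneurysm_center - spec$vessel_point
  tpar <- sum(dp * spec$vessel_axis)
  foot <- spec$vessel_point + tpar * spec$vessel_axis
  u <- (spec$aneurysm_center - foot) / d
  w2 <- c(u[2] * spec$vessel_axis[3] - u[3] * spec$vessel_axis[2],
          u[3] * spec$vessel_axis[1] - u[1] * spec$vessel_axis[3],
          u[1] * spec$vessel_axis[2] - u[2] * spec$vessel_axis[1])
  rv <- spec$vessel_radius
  tt <- seq(0, 2 * pi, length.out = 25)[-25]
  rings <- lapply(seq_len(spec$n_phases), function(p) {
    R <- geo$radii[p]
    zmax <- sqrt(R^2 - (d - rv)^2)
    z <- zmax * sin(tt)
    x <- ((d^2 + rv^2 - R^2) + z^2) / (2 * d)
    y <- sign(cos(tt)) * sqrt(pmax(0, rv^2 - x^2))
    ring <- sweep(outer(x, u) + outer(y, w2) + outer(z, spec$vessel_axis),
                  2, foot, "+")
    apply_tf_points(ring, tfs[[p]])
  })
  a0 <- (d^2 + geo$radii[1]^2 - spec$vessel_radius^2) / (2 * d)

  truth <- structure(list(
    volumes = geo$volumes, radii = geo$radii, neck_rings = rings,
    neck_plane = list(normal = u, offset = d - a0, center_dist = d),
    transforms = tfs, dome_seed = spec$aneurysm_center, spec = spec),
    class = "phantom_truth")

  list(volume = ct_volume_4d(vox, spacing = sp, origin = or), truth = truth)
}

# separable truncated-Gaussian blur with border renormalization
gaussian_blur_3d <- function(arr, sigma_mm, spacing) {
  dims <- dim(arr)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    if (sig <= 0) next
    r <- max(1L, ceiling(3 * sig))
    n <- dims[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      g <- dnorm(j - i, sd = sig)
      K[i, j] <- g / sum(g)
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = dims[ax])
    m <- K %*% m
    a <- array(m, dim = dims[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Add seeded Gaussian CT noise to a 4D volume
#'
#' @param volume a `ct_volume_4d`.
#' @param sd_hu noise standard deviation in HU.
#' @param seed RNG seed.
#' @return A `ct_volume_4d` with noise added to every phase.
#' @export
add_ct_noise <- function(volume, sd_hu, seed = 1L) {
  stopifnot(inherits(volume, "ct_volume_4d"))
  vox <- volume$voxels +
    with_seed(seed, array(rnorm(length(volume$voxels), 0, sd_hu),
                          dim = dim(volume$voxels)))
  ct_volume_4d(vox, spacing = volume$spacing, origin = volume$origin)
}

#' Resample one phase volume under a small rigid transform
#'
#' Applies a rigid map (rotation about an axis through `pivot`, then
#' translation) to a 3D phase volume by trilinear interpolation — the
#' numerical emulation of bulk vasculature motion between phases.
#'
#' @param phase_volume 3D numeric array (HU).
#' @param translation length-3 mm translation.
#' @param rotation_deg rotation angle about `axis` in degrees.
#' @param spacing,origin grid geometry (mm).
#' @param axis rotation axis direction (default z).
#' @param pivot rotation centre, mm (default world centre of the grid).
#' @param fill HU value for samples mapped outside the grid (default the
#'   array minimum, i.e. background).
#' @return 3D array of the same shape.
#' @export
apply_rigid_motion <- function(phase_volume, translation = c(0, 0, 0),
                               rotation_deg = 0, spacing, origin,
                               axis = c(0, 0, 1), pivot = NULL, fill = NULL) {
  dims <- dim(phase_volume)
  if (length(dims) != 3L) p4d_stop("phase_volume must be 3D", "p4d_dimension_error")
  extent <- (dims - 1) * spacing
  if (any(abs(translation) > extent / 2))
    p4d_stop("translation moves the volume out of the grid", "p4d_out_of_bounds")
  if (is.null(pivot)) pivot <- origin + extent / 2
  if (is.null(fill)) fill <- min(phase_volume)
  R <- rotation_about_axis(axis, rotation_deg)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  X <- rep(origin[1] + (seq_len(nx) - 1) * spacing[1], times = ny * nz)
  Y <- rep(rep(origin[2] + (seq_len(ny) - 1) * spacing[2], each = nx), times = nz)
  Z <- rep(origin[3] + (seq_len(nz) - 1) * spacing[3], each = nx * ny)
  # inverse map: source = R^T (x - t - pivot) + pivot
  dx <- X - translation[1] - pivot[1]
  dy <- Y - translation[2] - pivot[2]
  dz <- Z - translation[3] - pivot[3]
  sx <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz + pivot[1]
  sy <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz + pivot[2]
  sz <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz + pivot[3]
  trilinear_sample(phase_volume, sx, sy, sz, spacing, origin, fill)
}

trilinear_sample <- function(arr, sx, sy, sz, spacing, origin, fill) {
  dims <- dim(arr)
  fx <- (sx - origin[1]) / spacing[1]
  fy <- (sy - origin[2]) / spacing[2]
  fz <- (sz - origin[3]) / spacing[3]
  eps <- 1e-9
  ok <- fx >= -eps & fy >= -eps & fz >= -eps &
    fx <= dims[1] - 1 + eps & fy <= dims[2] - 1 + eps & fz <= dims[3] - 1 + eps
  i0 <- pmin(pmax(floor(fx), 0), dims[1] - 2)
  j0 <- pmin(pmax(floor(fy), 0), dims[2] - 2)
  k0 <- pmin(pmax(floor(fz), 0), dims[3] - 2)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- rep(fill, length(sx))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; k0k <- k0[ok]
    wxk <- wx[ok]; wyk <- wy[ok]; wzk <- wz[ok]
    at <- function(di, dj, dk)
      arr[cbind(i0k + di + 1, j0k + dj + 1, k0k + dk + 1)]
    out[ok] <-
      (1 - wxk) * (1 - wyk) * (1 - wzk) * at(0, 0, 0) +
      wxk * (1 - wyk) * (1 - wzk) * at(1, 0, 0) +
      (1 - wxk) * wyk * (1 - wzk) * at(0, 1, 0) +
      wxk * wyk * (1 - wzk) * at(1, 1, 0) +
      (1 - wxk) * (1 - wyk) * wzk * at(0, 0, 1) +
      wxk * (1 - wyk) * wzk * at(1, 0, 1) +
      (1 - wxk) * wyk * wzk * at(0, 1, 1) +
      wxk * wyk * wzk * at(1, 1, 1)
  }
  array(out, dim = dims)
}
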