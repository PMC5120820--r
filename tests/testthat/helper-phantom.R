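# Shared phantom fixtures and the standard measurement path used by the
# phantom-validation tests. Results are cached per session because several
# test files interrogate the same noise-free phantom.

p4d_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(p4d_test_cache[[key]])) p4d_test_cache[[key]] <- force(expr)
  p4d_test_cache[[key]]
}

# Full measurement path on a phantom: threshold (160-890), component filter,
# half-maximum isosurface (220 HU for the 400/40 HU phantom), neck points
# from the phase-0 ground-truth ostium, ICP transfer, separation, curve.
measure_phantom <- function(spec, iso = 220, smooth = 0, npts = 12) {
  ph <- generate_phantom_4d(spec)
  cseed <- round(world_to_voxel(spec$aneurysm_center, spec$spacing,
                                spec$origin))
  mask <- keep_component(threshold_lumen(ph$volume), cseed)
  ms <- build_mesh_sequence(ph$volume, mask, iso = iso, smooth_sigma = smooth)
  idx <- round(seq(1, nrow(ph$truth$neck_rings[[1]]), length.out = npts + 1))
  pts0 <- neck_points(ph$truth$neck_rings[[1]][idx[-length(idx)], ])
  curve <- aneurysm_volume_curve(ms, pts0, spec$aneurysm_center)
  list(curve = curve, truth = ph$truth, mesh_seq = ms, mask = mask,
       volume = ph$volume, points0 = pts0)
}

default_noisefree <- function() {
  cached("nf106", measure_phantom(
    phantom_spec(pulsation_amplitude = 1.06, noise_fraction = 0)))
}

default_flat <- function() {
  cached("flat", measure_phantom(
    phantom_spec(pulsation_amplitude = 1, noise_fraction = 0)))
}

default_digital <- function() {  # no PSF: digital phantom for geometry oracles
  cached("digital", measure_phantom(
    phantom_spec(pulsation_amplitude = 1, noise_fraction = 0, psf_sigma = 0),
    npts = 24))
}

# dense analytic ostium (sphere-tube junction) curve for transfer accuracy
dense_junction <- function(truth, phase = 1L, n = 400) {
  spec <- truth$spec
  R <- truth$radii[phase]; rv <- spec$vessel_radius
  dp <- spec$aneurysm_center - spec$vessel_point
  tpar <- sum(dp * spec$vessel_axis)
  foot <- spec$vessel_point + tpar * spec$vessel_axis
  d <- sqrt(sum((dp - tpar * spec$vessel_axis)^2))
  u <- (spec$aneurysm_center - foot) / d
  w2 <- c(u[2] * spec$vessel_axis[3] - u[3] * spec$vessel_axis[2],
          u[3] * spec$vessel_axis[1] - u[1] * spec$vessel_axis[3],
          u[1] * spec$vessel_axis[2] - u[2] * spec$vessel_axis[1])
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  zmax <- sqrt(R^2 - (d - rv)^2)
  z <- zmax * sin(tt)
  x <- ((d^2 + rv^2 - R^2) + z^2) / (2 * d)
  y <- sign(cos(tt)) * sqrt(pmax(0, rv^2 - x^2))
  sweep(outer(x, u) + outer(y, w2) + outer(z, spec$vessel_axis), 2, foot, "+")
}

# 18%-noise pulsatile replicates at the Table-1-like amplitude 1.06; one
# measured amplitude and curve-to-pulse Hausdorff distance per noise seed
noisy_pulsatile_runs <- function(nseeds = 50) {
  cached(paste0("noisy106_", nseeds), {
    pw <- generate_pulse_template(10)
    out <- lapply(seq_len(nseeds), function(s) {
      r <- measure_phantom(phantom_spec(pulsation_amplitude = 1.06,
                                        noise_fraction = 0.18, seed = s),
                           smooth = 0.4)
      data.frame(seed = s, amp = pulsation_amplitude(r$curve),
                 hd = hausdorff_distance(normalize_minmax(r$curve), pw))
    })
    do.call(rbind, out)
  })
}

# zero-amplitude replicates: `m` independent noise realizations per
# replicate (pulsation_test needs >= 2 distances per group)
zero_amplitude_runs <- function(nrep = 50, m = 3) {
  cached(paste0("zero_", nrep, "_", m), {
    pw <- generate_pulse_template(10)
    lapply(seq_len(nrep), function(i) {
      vapply(seq_len(m), function(j) {
        s <- 1000L + (i - 1L) * m + j
        r <- measure_phantom(phantom_spec(pulsation_amplitude = 1,
                                          noise_fraction = 0.18, seed = s),
                             smooth = 0.4)
        hausdorff_distance(normalize_minmax(r$curve), pw)
      }, numeric(1))
    })
  })
}
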