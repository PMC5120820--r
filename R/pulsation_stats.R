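#' Hausdorff distance between two sampled curves
#'
#' Each curve of n samples is embedded as the planar point set
#' \{(t_i, v_i)\} with t_i = i/(n-1) in [0, 1]; the symmetric Hausdorff
#' distance max(h(A,B), h(B,A)) with h(A,B) = max_a min_b ||a - b||_2 is
#' returned. Both curves are expected on a comparable scale (min-max
#' normalized volume curves and the pulse-wave template). With
#' `value_only = TRUE` the time coordinate is dropped and the distance is
#' computed on the value sets alone.
#'
#' @param a,b numeric vectors or `volume_curve`s of equal length.
#' @param value_only drop the time coordinate (1-D Hausdorff on values).
#' @return Scalar distance (unitless).
#' @export
hausdorff_distance <- function(a, b, value_only = FALSE) {
  va <- as_curve_values(a); vb <- as_curve_values(b)
  if (length(va) != length(vb))
    p4d_stop("curves must have equal length", "p4d_invalid_argument")
  n <- length(va)
  if (value_only) {
    pa <- cbind(0, va); pb <- cbind(0, vb)
  } else {
    t <- seq(0, 1, length.out = n)
    pa <- cbind(t, va); pb <- cbind(t, vb)
  }
  # pairwise distances, n is small (cardiac phases)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  h_ab <- max(apply(d2, 1, min))
  h_ba <- max(apply(d2, 2, min))
  sqrt(max(h_ab, h_ba))
}

#' Generate the random-noise null curve set
#'
#' Random curves with the noise characteristics measured in the CT images:
#' each curve is `n_phases` i.i.d. Gaussian(mean = 0.5, sd = 0.2) draws,
#' clipped to [0, 1] and not re-normalized. Their Hausdorff distances to the
#' supplied pulse wave form the null distribution against which measured
#' volume-curve distances are tested.
#'
#' @param n_curves number of random curves (default 14, one per aneurysm in
#'   the validation cohort; use ~1000 for calibration work).
#' @param n_phases samples per curve.
#' @param seed RNG seed.
#' @param pulse optional `pulse_wave`; if supplied, distances are computed.
#' @param mean,sd Gaussian noise moments.
#' @param clip clip draws to [0, 1] (default TRUE).
#' @param renorm min-max re-normalize each random curve (default FALSE).
#' @param value_only passed to [hausdorff_distance()].
#' @return A list of class `random_null` with `curves` (matrix, one row per
#'   curve), `distances` (if `pulse` given) and the generation parameters.
#' @export
generate_random_null <- function(n_curves = 14L, n_phases = 10L, seed = 1L,
                                 pulse = NULL, mean = 0.5, sd = 0.2,
                                 clip = TRUE, renorm = FALSE, value_only = FALSE) {
  if (n_curves < 1L) p4d_stop("n_curves must be >= 1", "p4d_invalid_argument")
  curves <- with_seed(seed, matrix(rnorm(n_curves * n_phases, mean, sd),
                                   nrow = n_curves))
  if (clip) curves <- pmin(pmax(curves, 0), 1)
  if (renorm) {
    curves <- t(apply(curves, 1, function(r) {
      rg <- range(r); if (diff(rg) == 0) r * 0 else (r - rg[1]) / diff(rg)
    }))
  }
  distances <- NULL
  if (!is.null(pulse)) {
    distances <- apply(curves, 1, hausdorff_distance, b = pulse,
                       value_only = value_only)
  }
  structure(list(curves = curves, distances = distances, n_curves = n_curves,
                 n_phases = n_phases, mean = mean, sd = sd, seed = seed,
                 clip = clip, renorm = renorm),
            class = "random_null")
}

#' Compare curve distances against the random-noise null
#'
#' Two-sample two-sided Welch t-test between the Hausdorff distances of
#' measured volume curves and those of the random null curves. A
#' significantly smaller volume-curve mean indicates that the curves carry
#' pulsational information rather than image noise.
#'
#' @param curve_distances numeric vector of curve-to-pulse distances (>= 2).
#' @param null a `random_null` with distances, or a numeric vector.
#' @return List with `t`, `p`, `mean_curves`, `mean_null`, `df`.
#' @export
pulsation_test <- function(curve_distances, null) {
  nd <- if (inherits(null, "random_null")) {
    if (is.null(null$distances))
      p4d_stop("null has no distances; pass `pulse` to generate_random_null()",
               "p4d_invalid_argument")
    null$distances
  } else as.numeric(null)
  x <- as.numeric(curve_distances)
  if (length(x) < 2L || length(nd) < 2L)
    p4d_stop("both samples must have >= 2 values", "p4d_invalid_argument")
  if (sd(x) == 0 && sd(nd) == 0) {
    # degenerate variance: exact-equality fallback
    eq <- isTRUE(all.equal(mean(x), mean(nd)))
    return(list(t = 0, p = if (eq) 1 else 0, mean_curves = mean(x),
                mean_null = mean(nd), df = NA_real_))
  }
  tt <- t.test(x, nd, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_curves = mean(x), mean_null = mean(nd),
       df = unname(tt$parameter))
}

#' Classify a volume curve profile
#'
#' Heuristic three-way grouping of volume profiles: predominantly flat
#' (amplitude below `flat_threshold`), pulsation-like (Hausdorff distance to
#' the pulse wave below the `q`-th percentile of the null distances), or
#' randomly oscillating otherwise. The thresholds are package conveniences,
#' not part of the validated statistic.
#'
#' @param curve raw `volume_curve` or positive numeric vector.
#' @param pulse a `pulse_wave`.
#' @param null a `random_null` carrying distances to the same pulse wave.
#' @param flat_threshold amplitude below which the profile is called flat.
#' @param q percentile (0-100) of null distances defining "similar".
#' @return `"pulsatile"`, `"random"` or `"flat"`.
#' @export
classify_curve <- function(curve, pulse, null, flat_threshold = 1.02, q = 5) {
  v <- as_curve_values(curve)
  if (diff(range(v)) == 0) return("flat")
  if (pulsation_amplitude(v) < flat_threshold) return("flat")
  if (is.null(null$distances))
    p4d_stop("null has no distances", "p4d_invalid_argument")
  d <- hausdorff_distance(normalize_minmax(v), pulse)
  if (d < unname(stats::quantile(null$distances, q / 100))) "pulsatile" else "random"
}
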