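#' Construct a per-phase volume curve
#'
#' A volume curve holds one aneurysm volume (mm^3) per cardiac phase, with
#' phase fractions of the R-R interval, and tracks its normalization state.
#'
#' @param values numeric vector of per-phase volumes (mm^3 when raw).
#' @param label optional curve label.
#' @param state normalization state: `"raw"`, `"minmax01"` or `"mean1"`.
#' @param diagnostics optional per-phase diagnostics data frame.
#' @return An object of class `volume_curve`.
#' @export
volume_curve <- function(values, label = NULL, state = c("raw", "minmax01", "mean1"),
                         diagnostics = NULL) {
  state <- match.arg(state)
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    p4d_stop("a volume curve needs >= 2 finite per-phase values", "p4d_invalid_argument")
  if (state == "raw" && any(values <= 0))
    p4d_stop("raw volumes must be positive", "p4d_invalid_argument")
  structure(
    list(values = values,
         phase_frac = seq(0, by = 1 / length(values), length.out = length(values)),
         label = label, state = state, diagnostics = diagnostics),
    class = "volume_curve")
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf("<volume_curve> %d phases, state=%s%s\n", length(x$values), x$state,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
length.volume_curve <- function(x) length(x$values)

as_curve_values <- function(curve) {
  if (inherits(curve, "volume_curve")) curve$values else as.numeric(curve)
}

#' Min-max normalize a volume curve to [0, 1]
#'
#' Maps the curve to a minimum of 0 and a maximum of 1, the normalization
#' used before Hausdorff-distance comparison with the arterial pulse wave.
#'
#' @param curve a [volume_curve()] or numeric vector.
#' @return A `volume_curve` with state `"minmax01"`.
#' @export
normalize_minmax <- function(curve) {
  v <- as_curve_values(curve)
  rng <- range(v)
  if (diff(rng) == 0)
    p4d_stop("constant curve cannot be min-max normalized (flat profile)",
             "p4d_degenerate_curve")
  out <- (v - rng[1]) / diff(rng)
  volume_curve(out, label = if (inherits(curve, "volume_curve")) curve$label else NULL,
               state = "minmax01")
}

#' Normalize a volume curve to a mean of one
#'
#' Scales the curve so its mean is 1, used to overlay relative volume changes
#' of differently sized aneurysms.
#'
#' @inheritParams normalize_minmax
#' @return A `volume_curve` with state `"mean1"`.
#' @export
normalize_mean_one <- function(curve) {
  v <- as_curve_values(curve)
  m <- mean(v)
  if (m <= 0) p4d_stop("curve mean must be positive", "p4d_invalid_argument")
  volume_curve(v / m, label = if (inherits(curve, "volume_curve")) curve$label else NULL,
               state = "mean1")
}

#' Pulsation amplitude of a volume curve
#'
#' The ratio of maximal to minimal volume over the cardiac cycle,
#' Vmax / Vmin. Invariant under mean-one normalization.
#'
#' @inheritParams normalize_minmax
#' @return Scalar amplitude >= 1 (or > 0 for a decreasing ratio; for any real
#'   curve max >= min so the value is >= 1).
#' @export
pulsation_amplitude <- function(curve) {
  v <- as_curve_values(curve)
  if (any(v <= 0))
    p4d_stop("pulsation amplitude requires positive volumes", "p4d_invalid_argument")
  max(v) / min(v)
}
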