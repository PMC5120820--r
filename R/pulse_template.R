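#' Arterial pulse-wave template
#'
#' Returns an arterial pulse-wave curve sampled at `n_phases` equally spaced
#' fractions of the R-R interval and min-max normalized to [0, 1]. The
#' built-in `"mca_like"` shape emulates a transcranial-Doppler velocity
#' waveform of the middle cerebral artery: a steep systolic upstroke with an
#' early peak (within the first 40% of the cycle), a dicrotic shoulder and a
#' smooth diastolic decay. If `values` is supplied (e.g. a published
#' ultrasound template), those samples are min-max normalized instead and the
#' shape argument is ignored.
#'
#' @param n_phases number of cardiac phases (>= 2).
#' @param shape `"mca_like"` (built-in) or `"custom"` (requires `values`).
#' @param values optional numeric vector of length `n_phases` with raw
#'   template samples to be min-max normalized (order preserved).
#' @return A numeric vector of class `pulse_wave` with min 0 and max 1.
#' @export
generate_pulse_template <- function(n_phases = 10L, shape = c("mca_like", "custom"),
                                    values = NULL) {
  shape <- match.arg(shape)
  n_phases <- as.integer(n_phases)
  if (is.na(n_phases) || n_phases < 2L)
    p4d_stop("n_phases must be >= 2", "p4d_invalid_argument")
  if (shape == "custom" || !is.null(values)) {
    if (is.null(values))
      p4d_stop("shape='custom' requires `values`", "p4d_invalid_argument")
    if (length(values) != n_phases)
      p4d_stop("`values` length must equal n_phases", "p4d_invalid_argument")
    v <- as.numeric(values)
    src <- "custom"
  } else {
    t <- seq(0, by = 1 / n_phases, length.out = n_phases)
    # systolic peak at ~18% R-R, dicrotic shoulder at ~45%, diastolic decay
    v <- exp(-((t - 0.18) / 0.085)^2) +
      0.38 * exp(-((t - 0.45) / 0.11)^2) +
      0.15 * exp(-t / 0.45) * (1 - t)
    src <- "mca_like"
  }
  rng <- range(v)
  if (diff(rng) == 0)
    p4d_stop("template is constant and cannot be normalized", "p4d_degenerate_curve")
  out <- (v - rng[1]) / diff(rng)
  structure(out, class = "pulse_wave", source = src)
}

#' @export
print.pulse_wave <- function(x, ...) {
  cat(sprintf("<pulse_wave> %d phases (source: %s)\n", length(x),
              attr(x, "source")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read a pulse-wave template from CSV
#'
#' Expects a single-column CSV (header optional column name `value`) or a
#' two-column `phase,value` CSV. Values are min-max normalized.
#'
#' @param path CSV file path.
#' @return A `pulse_wave`.
#' @export
read_pulse_csv <- function(path) {
  if (!file.exists(path)) p4d_stop(paste0("file not found: ", path), "p4d_not_found")
  df <- read.csv(path)
  v <- if ("value" %in% names(df)) df$value else df[[ncol(df)]]
  pw <- generate_pulse_template(length(v), shape = "custom", values = v)
  attr(pw, "source") <- path
  pw
}
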