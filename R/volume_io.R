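#' Construct a 4D CT angiography volume
#'
#' Hounsfield-unit voxels indexed (x, y, z, phase) with spatial spacing and
#' origin. Voxel indices are 0-based in the coordinate convention: the world
#' coordinate of voxel centre (i, j, k) is origin + index * spacing.
#'
#' @param voxels 4D numeric array (x, y, z, phase).
#' @param spacing mm per spatial axis (length 3, > 0).
#' @param origin world mm of voxel (0,0,0) centre.
#' @return An object of class `ct_volume_4d`.
#' @export
ct_volume_4d <- function(voxels, spacing = c(0.39, 0.39, 0.5),
                         origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 4L)
    p4d_stop("voxels must be a 4D (x,y,z,phase) array", "p4d_dimension_error")
  if (dim(voxels)[4] < 2L)
    p4d_stop("need >= 2 cardiac phases", "p4d_invalid_argument")
  if (any(spacing <= 0)) p4d_stop("spacing must be > 0", "p4d_invalid_argument")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume_4d")
}

#' @export
print.ct_volume_4d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume_4d> %dx%dx%d voxels, %d phases, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Number of cardiac phases
#' @param volume a `ct_volume_4d`.
#' @export
n_phases <- function(volume) dim(volume$voxels)[4]

#' Read a 4D NIfTI volume (phase as dimension 4)
#'
#' @param path NIfTI file (.nii or .nii.gz), or a character vector of one 3D
#'   file per phase when `phase_files = TRUE`.
#' @param phase_files treat `path` as per-phase 3D files to be stacked.
#' @return A `ct_volume_4d` with spacing and origin from the header.
#' @export
read_volume_4d <- function(path, phase_files = FALSE) {
  if (!all(file.exists(path)))
    p4d_stop(paste0("file not found: ", paste(path[!file.exists(path)],
                                              collapse = ", ")), "p4d_not_found")
  if (phase_files) {
    imgs <- lapply(path, RNifti::readNifti)
    for (im in imgs) if (length(dim(im)) != 3L)
      p4d_stop("each phase file must be a 3D NIfTI", "p4d_dimension_error")
    arr <- array(0, dim = c(dim(imgs[[1]]), length(imgs)))
    for (p in seq_along(imgs)) arr[, , , p] <- imgs[[p]]
    hdr <- imgs[[1]]
  } else {
    hdr <- RNifti::readNifti(path)
    if (length(dim(hdr)) != 4L)
      p4d_stop("expected a 4D NIfTI (use phase_files=TRUE for per-phase 3D files)",
               "p4d_dimension_error")
    arr <- array(as.numeric(hdr), dim = dim(hdr))
  }
  sp <- RNifti::pixdim(hdr)[1:3]
  xf <- RNifti::xform(hdr)
  origin <- nifti_origin_from_xform(xf)
  ct_volume_4d(arr, spacing = abs(sp), origin = origin)
}

# NIfTI xforms are RAS-oriented; this package writes plain axis-aligned
# LPS-free grids, so the origin is recovered from the translation column with
# the sign convention used by write_volume_4d (negated x/y, per nifti RAS).
nifti_origin_from_xform <- function(xf) {
  o <- xf[1:3, 4]
  c(-o[1], -o[2], o[3])
}

#' Write a `ct_volume_4d` to NIfTI
#'
#' @param volume a `ct_volume_4d`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume_4d <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume_4d"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- c(volume$spacing, 1)
  mat <- diag(4)
  diag(mat)[1:3] <- volume$spacing
  # nifti qform is RAS: flip x/y so a plain axis-aligned grid round-trips
  mat[1, 1] <- -mat[1, 1]; mat[2, 2] <- -mat[2, 2]
  mat[1:3, 4] <- c(-volume$origin[1], -volume$origin[2], volume$origin[3])
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a volume curve as CSV
#'
#' Columns: phase (0-based), volume_mm3, and when available icp_rms and
#' watertight diagnostics.
#'
#' @param curve a [volume_curve()].
#' @param path CSV path.
#' @return `path` invisibly ([write_curve_csv()]), a `volume_curve`
#'   ([read_curve_csv()]).
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "volume_curve"))
  df <- data.frame(phase = seq_along(curve$values) - 1L,
                   volume_mm3 = curve$values)
  if (!is.null(curve$diagnostics)) {
    if (!is.null(curve$diagnostics$icp_rms)) df$icp_rms <- curve$diagnostics$icp_rms
    if (!is.null(curve$diagnostics$watertight))
      df$watertight <- curve$diagnostics$watertight
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) p4d_stop(paste0("file not found: ", path), "p4d_not_found")
  df <- read.csv(path)
  volume_curve(df$volume_mm3, state = "raw")
}

#' Read neck points (or any x,y,z point list) from CSV
#'
#' One point per row, columns x, y, z in mm.
#'
#' @param path CSV path.
#' @param phase phase index the points belong to (default 0).
#' @return A `neck_point_set`.
#' @export
read_neck_csv <- function(path, phase = 0L) {
  if (!file.exists(path)) p4d_stop(paste0("file not found: ", path), "p4d_not_found")
  df <- read.csv(path)
  neck_points(as.matrix(df[, c("x", "y", "z")]), phase = phase)
}

#' Export a surface mesh as PLY or STL (ASCII)
#'
#' @param mesh a `surface_mesh`.
#' @param path output path ending in `.ply` or `.stl`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(paste(V[, 1], V[, 2], V[, 3]), con)
    writeLines(paste(3, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  } else if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid pulse4d", con)
    for (i in seq_len(nrow(F))) {
      a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; c3 <- V[F[i, 3], ]
      n <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
             (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
             (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(paste("facet normal", n[1], n[2], n[3]),
                   "  outer loop",
                   paste("    vertex", a[1], a[2], a[3]),
                   paste("    vertex", b[1], b[2], b[3]),
                   paste("    vertex", c3[1], c3[2], c3[3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid pulse4d", con)
  } else {
    p4d_stop("mesh export supports .ply and .stl", "p4d_invalid_argument")
  }
  invisible(path)
}
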