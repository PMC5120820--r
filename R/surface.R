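#' Construct a surface mesh
#'
#' @param vertices n x 3 matrix of world coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param phase cardiac phase index (0-based) the mesh belongs to, or NA.
#' @param iso iso-value used to extract the surface, or NA.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, phase = NA_integer_, iso = NA_real_) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    p4d_stop("vertices and faces must have 3 columns", "p4d_invalid_argument")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    p4d_stop("face indices out of range", "p4d_invalid_argument")
  structure(list(vertices = vertices, faces = faces, phase = phase, iso = iso),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.na(x$phase)) "" else sprintf(", phase %d", x$phase),
              if (is.na(x$iso)) "" else sprintf(", iso %g HU", x$iso)))
  invisible(x)
}

#' Extract the sub-voxel lumen isosurface of one phase
#'
#' Marching-tetrahedra isosurface of the grayscale HU field restricted to the
#' segmented region: the mask is dilated by one voxel (so the interface can be
#' placed at sub-voxel positions between masked and unmasked voxels), HU above
#' the upper threshold is clamped to background (excluding bone and
#' calcification, as the thresholding intends) and everything outside the
#' dilated mask is set below the iso-value so the surface closes. Vertices are
#' in world mm; outward orientation is enforced.
#'
#' @param volume a [ct_volume_4d()].
#' @param mask a `lumen_mask_4d` on the same grid.
#' @param phase 0-based phase index.
#' @param iso iso-value in HU (default 160, the lower segmentation
#'   threshold; for phantoms with known lumen/background attenuation the
#'   half-maximum (lumen+background)/2 places the interface without bias).
#' @param clamp_high HU above this are clamped to background before
#'   isosurfacing (default the mask's upper threshold).
#' @param smooth_sigma optional Gaussian denoising of the HU field before
#'   isosurfacing, mm (default 0 = off). On noisy acquisitions this prevents
#'   spurious tunnels through the partial-volume shell at the interface.
#' @return A `surface_mesh`.
#' @export
extract_isosurface <- function(volume, mask, phase = 0L, iso = 160,
                               clamp_high = NULL, smooth_sigma = 0) {
  stopifnot(inherits(volume, "ct_volume_4d"), inherits(mask, "lumen_mask_4d"))
  p <- as.integer(phase) + 1L
  arr <- volume$voxels[, , , p]
  m <- mask$mask[, , , p]
  if (!any(m)) p4d_stop("empty mask: no surface to extract", "p4d_empty_mesh")
  if (is.null(clamp_high)) clamp_high <- mask$high
  fill <- min(min(arr), iso - 0.1 * abs(iso) - 1)
  arr[arr > clamp_high] <- fill
  if (smooth_sigma > 0) arr <- gaussian_blur_3d(arr, smooth_sigma, volume$spacing)
  # noise pores in the raw-data mask must not punch tunnels through the
  # denoised interface: widen the support when smoothing is on
  extra_dilate <- smooth_sigma > 0
  md <- dilate_26(m)
  if (extra_dilate) md <- dilate_26(md)
  arr[!md] <- fill

  # crop to the dilated-mask bounding box with one voxel of padding
  idx <- which(md, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(arr))
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_origin <- volume$origin + (lo - 1) * volume$spacing
  # pad with background so the surface is closed even at the grid boundary
  d <- dim(sub) + 2L
  padded <- array(fill, dim = d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- sub
  res <- mt_isosurface(as.numeric(padded), d, iso, volume$spacing,
                       sub_origin - volume$spacing)
  if (nrow(res$vertices) == 0)
    p4d_stop("iso-value produced an empty surface", "p4d_empty_mesh")
  mesh <- surface_mesh(res$vertices, res$faces, phase = phase, iso = iso)
  v <- signed_mesh_volume(mesh)
  if (v < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Build the per-phase surface model sequence (3D+t model)
#'
#' One [extract_isosurface()] call per cardiac phase, sharing the iso-value.
#'
#' @inheritParams extract_isosurface
#' @return A list of class `mesh_sequence`.
#' @export
build_mesh_sequence <- function(volume, mask, iso = 160, clamp_high = NULL,
                                smooth_sigma = 0) {
  np <- dim(volume$voxels)[4]
  meshes <- lapply(seq_len(np) - 1L, function(p)
    extract_isosurface(volume, mask, phase = p, iso = iso,
                       clamp_high = clamp_high, smooth_sigma = smooth_sigma))
  structure(list(meshes = meshes, iso = iso), class = "mesh_sequence")
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat(sprintf("<mesh_sequence> %d phases, iso %g HU\n", length(x$meshes), x$iso))
  invisible(x)
}

#' @export
length.mesh_sequence <- function(x) length(x$meshes)

# signed volume via the divergence theorem (tetrahedra against the origin)
signed_mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

mesh_surface_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# undirected edge keys for an m x 3 face matrix (vertex counts < 2^26)
edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  list(key = lo * 2^26 + hi, ends = cbind(lo, hi))
}

# connected components of faces (shared-edge adjacency); returns labels
face_components <- function(faces) {
  m <- nrow(faces)
  ek <- edge_keys(faces)
  eid <- match(ek$key, unique(ek$key))
  fos <- rep(seq_len(m), times = 3)
  ord <- order(eid)
  eo <- eid[ord]; fo <- fos[ord]
  first <- !duplicated(eo)
  ff <- fo[first]                 # first face on each edge
  eord <- cumsum(first)           # edge ordinal per ordered slot
  pa <- ff[eord[!first]]; pb <- fo[!first]
  adj <- split(c(pb, pa), c(pa, pb))
  comp <- integer(m)
  cur <- 0L
  for (f0 in seq_len(m)) {
    if (comp[f0] != 0L) next
    cur <- cur + 1L
    comp[f0] <- cur
    frontier <- f0
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

face_areas <- function(V, F) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Enclosed volume of a closed surface mesh
#'
#' Volume by the divergence theorem (sum of signed tetrahedra against the
#' origin). The mesh must be watertight: every undirected edge shared by
#' exactly two faces. An inward-oriented mesh is corrected with a warning.
#' The surface area is attached as attribute `"area"` (mm^2).
#'
#' @param mesh a `surface_mesh`.
#' @param check verify watertightness (default TRUE).
#' @return Positive volume in mm^3, with attribute `area`.
#' @export
mesh_enclosed_volume <- function(mesh, check = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) p4d_stop("mesh has no faces", "p4d_empty_mesh")
  if (check) {
    ek <- edge_keys(mesh$faces)
    cnt <- table(ek$key)
    bad <- sum(cnt != 2L)
    if (bad > 0)
      p4d_stop(sprintf("mesh is not watertight: %d boundary/non-manifold edges",
                       bad), "p4d_open_mesh")
  }
  v <- signed_mesh_volume(mesh)
  if (v < 0) {
    p4d_warn("mesh was inward-oriented; orientation corrected",
             "p4d_orientation_corrected")
    v <- -v
  }
  structure(v, area = mesh_surface_area(mesh))
}

#' Is a mesh watertight?
#'
#' @param mesh a `surface_mesh`.
#' @return TRUE iff every undirected edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(table(edge_keys(mesh$faces)$key) == 2L)
}

# A surface is "closed" for volume purposes when its directed edges balance:
# every directed edge is matched by its reverse with equal multiplicity.
# This admits pinched (non-manifold-vertex) boundaries where the divergence
# theorem still applies.
is_closed_surface <- function(faces) {
  if (nrow(faces) == 0) return(FALSE)
  de <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- de[, 1] * 2^26 + de[, 2]
  rkey <- de[, 2] * 2^26 + de[, 1]
  identical(sort(key), sort(rkey))
}
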