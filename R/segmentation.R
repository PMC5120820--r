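#' Threshold segmentation of the vascular lumen
#'
#' Includes a voxel iff low <= HU <= high (both bounds inclusive),
#' independently per cardiac phase. The default 160-890 HU window separates
#' contrast-enhanced lumen from cerebrospinal fluid and brain while excluding
#' bone and calcification.
#'
#' @param volume a [ct_volume_4d()].
#' @param low,high threshold bounds in HU (low < high).
#' @return A `lumen_mask_4d`: logical mask per phase on the same grid, with
#'   the bounds used.
#' @export
threshold_lumen <- function(volume, low = 160, high = 890) {
  stopifnot(inherits(volume, "ct_volume_4d"))
  if (low >= high) p4d_stop("need low < high", "p4d_invalid_argument")
  mask <- volume$voxels >= low & volume$voxels <= high
  if (!any(mask))
    p4d_warn("threshold produced an empty segmentation on all phases",
             "p4d_empty_segmentation")
  structure(list(mask = mask, spacing = volume$spacing, origin = volume$origin,
                 low = low, high = high),
            class = "lumen_mask_4d")
}

#' @export
print.lumen_mask_4d <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<lumen_mask_4d> %dx%dx%d, %d phases, [%g, %g] HU, %d voxels set\n",
              d[1], d[2], d[3], d[4], x$low, x$high, sum(x$mask)))
  invisible(x)
}

#' Restrict a lumen mask to a volume of interest
#'
#' The VOI is an axis-aligned box in 0-based voxel indices with half-open
#' bounds `c(x0, x1, y0, y1, z0, z1)` (start inclusive, end exclusive).
#' Voxels outside the box are cleared; grid metadata is preserved.
#'
#' @param mask a `lumen_mask_4d`.
#' @param voi integer vector of length 6.
#' @return The cropped `lumen_mask_4d`.
#' @export
crop_voi <- function(mask, voi) {
  stopifnot(inherits(mask, "lumen_mask_4d"))
  d <- dim(mask$mask)[1:3]
  voi <- as.integer(voi)
  if (length(voi) != 6L) p4d_stop("voi must be c(x0,x1,y0,y1,z0,z1)",
                                  "p4d_invalid_argument")
  lo <- voi[c(1, 3, 5)]; hi <- voi[c(2, 4, 6)]
  if (any(lo >= hi) || any(lo < 0) || any(hi > d))
    p4d_stop("voi must satisfy 0 <= start < end <= grid", "p4d_invalid_argument")
  keep <- array(FALSE, dim = d)
  keep[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- TRUE
  out <- mask
  for (p in seq_len(dim(mask$mask)[4])) out$mask[, , , p] <- mask$mask[, , , p] & keep
  if (!any(out$mask))
    p4d_warn("VOI cleared the entire segmentation", "p4d_empty_segmentation")
  out
}

#' Keep the 26-connected component containing a seed voxel
#'
#' Per phase, retains only the 26-connected component of the mask that
#' contains the seed (0-based voxel index). For phases where the exact seed
#' voxel is unmasked, the seed is transferred to the nearest masked voxel.
#' Isolates the aneurysm-bearing vessel from other thresholded structures.
#'
#' @param mask a `lumen_mask_4d`.
#' @param seed_point integer c(i, j, k), 0-based; must be inside the mask at
#'   phase 0.
#' @return The filtered `lumen_mask_4d`.
#' @export
keep_component <- function(mask, seed_point) {
  stopifnot(inherits(mask, "lumen_mask_4d"))
  d <- dim(mask$mask)
  seed_point <- as.integer(round(seed_point))
  if (any(seed_point < 0) || any(seed_point >= d[1:3]))
    p4d_stop("seed outside grid", "p4d_seed_error")
  if (!mask$mask[seed_point[1] + 1, seed_point[2] + 1, seed_point[3] + 1, 1])
    p4d_stop("seed voxel is not inside the mask at phase 0", "p4d_seed_error")
  out <- mask
  for (p in seq_len(d[4])) {
    m <- mask$mask[, , , p]
    sp <- seed_point
    if (!m[sp[1] + 1, sp[2] + 1, sp[3] + 1]) {
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx) == 0)
        p4d_stop(sprintf("phase %d mask is empty: no component", p - 1),
                 "p4d_seed_error")
      d2 <- colSums((t(idx) - (sp + 1))^2)
      sp <- idx[which.min(d2), ] - 1L
    }
    out$mask[, , , p] <- array(flood_fill_26(as.logical(m), d[1:3], sp), dim = d[1:3])
  }
  out
}

#' World coordinates of a voxel index
#'
#' @param index 0-based voxel index (vector or matrix with 3 columns).
#' @param spacing,origin grid geometry, mm.
#' @return World coordinates in mm.
#' @export
voxel_to_world <- function(index, spacing, origin) {
  if (is.matrix(index)) sweep(sweep(index, 2, spacing, "*"), 2, origin, "+")
  else origin + index * spacing
}

#' @rdname voxel_to_world
#' @param world world coordinates, mm.
#' @export
world_to_voxel <- function(world, spacing, origin) {
  if (is.matrix(world)) sweep(sweep(world, 2, origin), 2, spacing, "/")
  else (world - origin) / spacing
}

# 26-neighbourhood binary dilation by one voxel (per 3D array)
dilate_26 <- function(m) {
  d <- dim(m)
  out <- m
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src_i <- max(1, 1 - di):min(d[1], d[1] - di)
    src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
    src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
    out[src_i + di, src_j + dj, src_k + dk] <-
      out[src_i + di, src_j + dj, src_k + dk] | m[src_i, src_j, src_k]
  }
  out
}
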