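#' Rigid ICP alignment of two lumen surfaces around the neck
#'
#' Point-to-point iterative closest point registration restricted to source
#' vertices inside a focus sphere around the aneurysm neck (the transfer must
#' track the neck, not global vasculature motion). Correspondence is
#' nearest-neighbour (ties broken by lowest vertex index), alignment per
#' iteration is the closed-form orthogonal (Kabsch) solution, initialization
#' is the identity. Iteration stops when the RMS residual changes by less
#' than `tol` mm or after `max_iter` iterations.
#'
#' @param source_mesh,target_mesh `surface_mesh` objects.
#' @param focus_center mm; typically the neck-point centroid.
#' @param focus_radius mm; typically 1.5 x the neck ring radius.
#' @param max_iter,tol stopping rule.
#' @param max_source_points deterministic subsample cap on focus vertices.
#' @return A list of class `rigid_transform`: `R` (3 x 3 rotation,
#'   det = +1), `t` (mm), `rms` (mm), `iterations`, `converged`.
#' @export
fit_rigid_icp <- function(source_mesh, target_mesh, focus_center, focus_radius,
                          max_iter = 50L, tol = 1e-6,
                          max_source_points = 600L) {
  SV <- source_mesh$vertices; TV <- target_mesh$vertices
  if (nrow(SV) == 0 || nrow(TV) == 0)
    p4d_stop("empty mesh in ICP", "p4d_empty_mesh")
  d2s <- colSums((t(SV) - focus_center)^2)
  src <- SV[d2s <= focus_radius^2, , drop = FALSE]
  if (nrow(src) < 10L)
    p4d_stop(sprintf("only %d source vertices inside the focus sphere (need >= 10)",
                     nrow(src)), "p4d_focus_error")
  if (nrow(src) > max_source_points) {
    keep <- round(seq(1, nrow(src), length.out = max_source_points))
    src <- src[keep, , drop = FALSE]
  }
  # prefilter target to a generous neighbourhood of the focus for speed
  d2t <- colSums((t(TV) - focus_center)^2)
  tgt <- TV[d2t <= (2 * focus_radius)^2, , drop = FALSE]
  if (nrow(tgt) < 100L) tgt <- TV

  R <- diag(3); tr <- c(0, 0, 0)
  rms_prev <- Inf; it <- 0L; rms <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    cur <- src %*% t(R)
    cur <- sweep(cur, 2, tr, "+")
    ni <- nn_index(cur, tgt)
    match_pts <- tgt[ni, , drop = FALSE]
    cs <- colMeans(src); ct <- colMeans(match_pts)
    H <- t(sweep(src, 2, cs)) %*% sweep(match_pts, 2, ct)
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    tr <- ct - as.vector(R %*% cs)
    cur <- sweep(src %*% t(R), 2, tr, "+")
    rms <- sqrt(mean(rowSums((cur - match_pts)^2)))
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
  }
  converged <- it < max_iter || abs(rms_prev - rms) < tol
  if (!converged)
    p4d_warn("ICP did not converge; returning best transform",
             "p4d_icp_nonconvergence")
  structure(list(R = R, t = as.numeric(tr), rms = rms, iterations = it,
                 converged = converged),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> |t| = %.4g mm, rotation %.3g deg, RMS %.4g mm (%d iter%s)\n",
              sqrt(sum(x$t^2)), ang, x$rms, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix (mm).
#' @param transform a `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid_transform <- function(points, transform) {
  sweep(points %*% t(transform$R), 2, transform$t, "+")
}

#' Rotation angle of a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @return Angle in degrees.
#' @export
rotation_angle_deg <- function(transform) {
  acos(pmin(1, pmax(-1, (sum(diag(transform$R)) - 1) / 2))) * 180 / pi
}
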