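#' Construct a neck point set
#'
#' Ordered 3D points (mm) on the lumen surface delimiting the aneurysm neck
#' at one phase. At least 3 non-collinear points are required.
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param phase 0-based phase index.
#' @return A matrix of class `neck_point_set` with a `phase` attribute.
#' @export
neck_points <- function(points, phase = 0L) {
  points <- as.matrix(points); storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 3L)
    p4d_stop("need >= 3 points with x,y,z columns", "p4d_invalid_argument")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))$d
  if (sv[2] < 1e-9 * sv[1])
    p4d_stop("neck points are collinear", "p4d_invalid_geometry")
  structure(points, class = "neck_point_set", phase = as.integer(phase))
}

# snap points to the nearest mesh vertices
snap_to_mesh <- function(points, mesh) {
  idx <- nn_index(as.matrix(points), mesh$vertices)
  mesh$vertices[idx, , drop = FALSE]
}

#' Transfer neck points from phase 0 to all phases by ICP
#'
#' For each later phase, a rigid ICP transform from the phase-0 mesh to the
#' phase-t mesh (focused on the neck) is applied to the phase-0 points, which
#' are then snapped to the nearest vertex of the phase-t mesh so they lie on
#' the 3D+t model. Per-phase replacement points (the manual correction hook)
#' can be supplied via `corrections`.
#'
#' @param points0 a [neck_points()] set on the phase-0 mesh.
#' @param mesh_seq a [build_mesh_sequence()] result.
#' @param focus_radius ICP focus radius, mm; default 1.5 x the mean distance
#'   of the neck points from their centroid.
#' @param corrections optional named list (phase index as character, 0-based)
#'   of replacement n x 3 matrices.
#' @return List of `neck_point_set`, one per phase, with attribute
#'   `transforms` (per-phase `rigid_transform`, identity for phase 0).
#' @export
transfer_neck_points <- function(points0, mesh_seq, focus_radius = NULL,
                                 corrections = NULL) {
  stopifnot(inherits(mesh_seq, "mesh_sequence"))
  meshes <- mesh_seq$meshes
  ctr <- colMeans(points0)
  ring_r <- mean(sqrt(rowSums(sweep(points0, 2, ctr)^2)))
  if (is.null(focus_radius)) focus_radius <- 1.5 * ring_r
  out <- vector("list", length(meshes))
  tfs <- vector("list", length(meshes))
  snapped0 <- snap_to_mesh(points0, meshes[[1]])
  out[[1]] <- neck_points(snapped0, phase = 0L)
  tfs[[1]] <- structure(list(R = diag(3), t = c(0, 0, 0), rms = 0,
                             iterations = 0L, converged = TRUE),
                        class = "rigid_transform")
  for (p in seq_along(meshes)[-1]) {
    key <- as.character(p - 1L)
    if (!is.null(corrections) && !is.null(corrections[[key]])) {
      out[[p]] <- neck_points(snap_to_mesh(corrections[[key]], meshes[[p]]),
                              phase = p - 1L)
      tfs[[p]] <- NULL
      next
    }
    tf <- fit_rigid_icp(meshes[[1]], meshes[[p]], focus_center = ctr,
                        focus_radius = focus_radius)
    moved <- apply_rigid_transform(unclass(points0), tf)
    out[[p]] <- neck_points(snap_to_mesh(moved, meshes[[p]]), phase = p - 1L)
    tfs[[p]] <- tf
  }
  attr(out, "transforms") <- tfs
  out
}

#' Build the cut surface over ordered neck points
#'
#' Orders the points by angle about the best-fit plane normal through their
#' centroid (a canonical ordering, invariant to input permutation) and emits
#' the centroid triangle fan connecting them. The fan is a simple surface
#' bounded by the neck polygon and handles non-planar necks; with
#' `planar = TRUE` the points are first projected onto their least-squares
#' plane.
#'
#' @param points a [neck_points()] set (>= 3 non-collinear points).
#' @param planar project points onto the best-fit plane first.
#' @return A list of class `cut_surface`: `apex` (centroid), `points`
#'   (ordered), `faces` (fan triangles as rows (apex, i, j) with apex = 0),
#'   `normal` (best-fit plane unit normal), `area` (fan area, mm^2).
#' @export
build_cut_surface <- function(points, planar = FALSE) {
  pts <- unclass(as.matrix(points)); storage.mode(pts) <- "double"
  if (nrow(pts) < 3L) p4d_stop("need >= 3 points", "p4d_invalid_argument")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen)
  if (sv$d[2] < 1e-9 * sv$d[1])
    p4d_stop("neck points are collinear", "p4d_invalid_geometry")
  n <- sv$v[, 3]
  # deterministic normal sign: largest-magnitude component positive
  imax <- which.max(abs(n))
  if (n[imax] < 0) n <- -n
  if (planar) {
    pts <- sweep(cen - (cen %*% n) %*% t(n), 2, ctr, "+")
    cen <- sweep(pts, 2, ctr)
  }
  # canonical in-plane basis: anchor on the point farthest from the centroid
  # (lexicographic tie-break), so the ordering is independent of input order
  # even for rotationally symmetric point sets
  proj <- cen - (cen %*% n) %*% t(n)
  dctr <- sqrt(rowSums(proj^2))
  ref <- order(-round(dctr, 9), pts[, 1], pts[, 2], pts[, 3])[1]
  b1 <- proj[ref, ] / dctr[ref]
  b2 <- c(n[2] * b1[3] - n[3] * b1[2], n[3] * b1[1] - n[1] * b1[3],
          n[1] * b1[2] - n[2] * b1[1])
  ang <- atan2(proj %*% b2, proj %*% b1)
  ang[ref] <- 0
  ord <- order(ang)
  pts <- pts[ord, , drop = FALSE]
  np <- nrow(pts)
  faces <- cbind(0L, seq_len(np), c(seq_len(np)[-1], 1L))
  # fan area
  area <- 0
  for (i in seq_len(np)) {
    a <- pts[i, ] - ctr; b <- pts[if (i == np) 1 else i + 1, ] - ctr
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    area <- area + sqrt(sum(cr^2)) / 2
  }
  structure(list(apex = ctr, points = pts, faces = faces, normal = n,
                 area = area),
            class = "cut_surface")
}

#' @export
print.cut_surface <- function(x, ...) {
  cat(sprintf("<cut_surface> %d neck points, fan area %.3f mm^2\n",
              nrow(x$points), x$area))
  invisible(x)
}

# --- segment / fan-triangle intersection (Moller-Trumbore, vectorized over
# segments for one triangle at a time; the fan has few triangles) ------------
# Returns per-segment smallest crossing parameter t in (eps, 1-eps), NA if none.
segments_fan_hits <- function(P0, P1, tris, eps = 1e-9) {
  n <- nrow(P0)
  tbest <- rep(NA_real_, n)
  D <- P1 - P0
  for (k in seq_len(nrow(tris$A))) {
    A <- tris$A[k, ]; E1 <- tris$E1[k, ]; E2 <- tris$E2[k, ]
    # h = D x E2
    hx <- D[, 2] * E2[3] - D[, 3] * E2[2]
    hy <- D[, 3] * E2[1] - D[, 1] * E2[3]
    hz <- D[, 1] * E2[2] - D[, 2] * E2[1]
    a <- E1[1] * hx + E1[2] * hy + E1[3] * hz
    ok <- abs(a) > 1e-14
    if (!any(ok)) next
    f <- ifelse(ok, 1 / a, NA_real_)
    sx <- P0[, 1] - A[1]; sy <- P0[, 2] - A[2]; sz <- P0[, 3] - A[3]
    u <- f * (sx * hx + sy * hy + sz * hz)
    qx <- sy * E1[3] - sz * E1[2]
    qy <- sz * E1[1] - sx * E1[3]
    qz <- sx * E1[2] - sy * E1[1]
    v <- f * (D[, 1] * qx + D[, 2] * qy + D[, 3] * qz)
    t <- f * (E2[1] * qx + E2[2] * qy + E2[3] * qz)
    hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps &
      t > eps & t < 1 - eps
    upd <- hit & (is.na(tbest) | t < tbest)
    tbest[upd] <- t[upd]
  }
  tbest
}

# Curtain of quads leaving the neck polygon outward along per-point surface
# normals; makes the blocking surface meet the (grazing) lumen wall
# transversally beyond the neck points.
curtain_triangles <- function(cut, mesh, ring_idx, length_mm = NULL) {
  P <- cut$points; np <- nrow(P)
  V <- mesh$vertices; F <- mesh$faces
  fn <- face_normals(V, F)
  fc <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
           V[F[, 3], , drop = FALSE]) / 3
  # neighbourhood-averaged outward normals (noise-robust): all faces whose
  # centroid lies within 0.8 mm of the neck point
  vn <- matrix(0, np, 3)
  for (i in seq_len(np)) {
    d2 <- (fc[, 1] - P[i, 1])^2 + (fc[, 2] - P[i, 2])^2 + (fc[, 3] - P[i, 3])^2
    fi <- which(d2 <= 0.64)
    n <- if (length(fi) > 0) colSums(fn[fi, , drop = FALSE])
         else P[i, ] - cut$apex
    vn[i, ] <- n / max(sqrt(sum(n^2)), 1e-12)
  }
  ring_r <- mean(sqrt(rowSums(sweep(P, 2, cut$apex)^2)))
  if (is.null(length_mm)) length_mm <- max(1.2, 0.8 * ring_r)
  # two-sided strip: the transferred points scatter about the true ostium,
  # so the barrier must extend outward and slightly into the lumen
  Qo <- P + length_mm * vn
  Qi <- P - 0.5 * length_mm * vn
  nxt <- c(seq_len(np)[-1], 1L)
  # strip quads (Qi_i, Qi_j, Qo_j) and (Qi_i, Qo_j, Qo_i)
  A <- rbind(Qi, Qi)
  E1 <- rbind(Qi[nxt, , drop = FALSE] - Qi, Qo[nxt, , drop = FALSE] - Qi)
  E2 <- rbind(Qo[nxt, , drop = FALSE] - Qi, Qo - Qi)
  keep <- rowSums(E1^2) > 1e-16 & rowSums(E2^2) > 1e-16
  list(A = A[keep, , drop = FALSE], E1 = E1[keep, , drop = FALSE],
       E2 = E2[keep, , drop = FALSE])
}

face_normals <- function(V, F) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

# which points lie (within tolerance) on the triangle soup
points_on_surface <- function(P, tris, tol = 1e-8) {
  if (nrow(P) == 0) return(logical(0))
  on <- logical(nrow(P))
  for (k in seq_len(nrow(tris$A))) {
    A <- tris$A[k, ]; E1 <- tris$E1[k, ]; E2 <- tris$E2[k, ]
    n <- c(E1[2] * E2[3] - E1[3] * E2[2], E1[3] * E2[1] - E1[1] * E2[3],
           E1[1] * E2[2] - E1[2] * E2[1])
    nn2 <- sqrt(sum(n^2)); if (nn2 < 1e-14) next
    n <- n / nn2
    w1 <- sweep(P, 2, A)
    d <- abs(w1 %*% n)
    closep <- which(d < tol)
    if (length(closep) == 0) next
    w <- w1[closep, , drop = FALSE]
    d11 <- sum(E1 * E1); d12 <- sum(E1 * E2); d22 <- sum(E2 * E2)
    det <- d11 * d22 - d12^2; if (det < 1e-20) next
    wu <- w %*% E1; wv <- w %*% E2
    u <- (d22 * wu - d12 * wv) / det
    v <- (d11 * wv - d12 * wu) / det
    inside <- u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9
    on[closep[inside]] <- TRUE
  }
  on
}

fan_triangles <- function(cut, extend = 1) {
  P <- cut$points; np <- nrow(P); apex <- cut$apex
  B <- sweep(sweep(P, 2, apex), 1, rep(extend, np), "*")
  B <- sweep(B, 2, apex, "+")
  Anext <- B[c(seq_len(np)[-1], 1), , drop = FALSE]
  keep <- rowSums((B - Anext)^2) > 1e-16  # drop degenerate duplicate points
  list(A = matrix(apex, sum(keep), 3, byrow = TRUE),
       E1 = (B - matrix(apex, np, 3, byrow = TRUE))[keep, , drop = FALSE],
       E2 = (Anext - matrix(apex, np, 3, byrow = TRUE))[keep, , drop = FALSE])
}

#' Separate the aneurysm dome from the parent vessel at one phase
#'
#' Region-grows triangle faces from the face nearest `dome_seed`, never
#' crossing an edge that intersects the cut surface (the fan is extended
#' radially by `fan_extend` so it fully slices the lumen wall between and
#' beyond the neck points; edges incident to a mesh vertex coinciding with a
#' neck point are treated as cut). Triangles straddling the cut are clipped
#' exactly at the recorded edge intersection points; the aneurysm-side faces
#' plus a triangle cone from the cut centroid over the resulting boundary
#' form a closed mesh whose enclosed volume is the aneurysm volume. The
#' vessel side is closed with the identical (reversed) cap, so aneurysm and
#' vessel volumes sum exactly to the whole-lumen volume.
#'
#' @param mesh a watertight `surface_mesh` of the lumen at one phase.
#' @param cut a [build_cut_surface()] result.
#' @param dome_seed mm point inside/near the aneurysm dome.
#' @param fan_extend radial extension factor of the fan for intersection
#'   tests (default 1.5).
#' @param leak_fraction grow reaching more than this fraction of all faces
#'   raises a leak error (default 0.9).
#' @return A list of class `aneurysm_segmentation`: `volume` (mm^3), `area`
#'   (mm^2, dome without cap), `vessel_volume`, `total_volume`, `mesh`
#'   (closed dome mesh), `watertight`, `fraction_grown`, `phase`.
#' @export
partition_mesh <- function(mesh, cut, dome_seed, fan_extend = 1,
                           leak_fraction = 0.9) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(cut, "cut_surface"))
  V <- mesh$vertices; F <- mesh$faces
  # image noise produces small closed specks/bubbles as separate surface
  # components; the partition operates on the dominant (largest-area)
  # component, the lumen wall
  comp <- face_components(F)
  if (max(comp) > 1L) {
    areas <- face_areas(V, F)
    main <- which.max(vapply(seq_len(max(comp)),
                             function(ci) sum(areas[comp == ci]), numeric(1)))
    F <- F[comp == main, , drop = FALSE]
  }
  m <- nrow(F)

  # mesh vertices coinciding with neck points are "ring vertices"
  ring_idx <- nn_index(cut$points, V)
  ring_ok <- rowSums((V[ring_idx, , drop = FALSE] - cut$points)^2) < 1e-12
  ring_verts <- unique(ring_idx[ring_ok])

  # undirected edges and face adjacency
  ek <- edge_keys(F)
  ukey <- unique(ek$key)
  eid <- match(ek$key, ukey)                # 3m edge slots -> edge id
  face_of_slot <- rep(seq_len(m), times = 3)
  ends <- ek$ends[!duplicated(ek$key), , drop = FALSE]
  ends <- ends[order(match(ek$key[!duplicated(ek$key)], ukey)), , drop = FALSE]
  ne <- length(ukey)

  # blocking surface: the fan (optionally extended) plus a "curtain" of
  # quads leaving the neck polygon outward along the local surface normals,
  # so the cut meets the grazing lumen wall transversally
  tris <- fan_triangles(cut, extend = fan_extend)
  curt <- curtain_triangles(cut, mesh, ring_idx)
  btris <- list(A = rbind(tris$A, curt$A), E1 = rbind(tris$E1, curt$E1),
                E2 = rbind(tris$E2, curt$E2))
  allb <- rbind(btris$A, btris$A + btris$E1, btris$A + btris$E2)
  lo <- apply(allb, 2, min) - 1e-6; hi <- apply(allb, 2, max) + 1e-6
  P0 <- V[ends[, 1], , drop = FALSE]; P1 <- V[ends[, 2], , drop = FALSE]
  inbox <- (pmin(P0[, 1], P1[, 1]) <= hi[1]) & (pmax(P0[, 1], P1[, 1]) >= lo[1]) &
           (pmin(P0[, 2], P1[, 2]) <= hi[2]) & (pmax(P0[, 2], P1[, 2]) >= lo[2]) &
           (pmin(P0[, 3], P1[, 3]) <= hi[3]) & (pmax(P0[, 3], P1[, 3]) >= lo[3])
  # vertices lying exactly on the blocking surface behave like neck points
  # (the membrane may pass through lattice vertices); their edges are cut
  vin <- which(V[, 1] >= lo[1] & V[, 1] <= hi[1] &
               V[, 2] >= lo[2] & V[, 2] <= hi[2] &
               V[, 3] >= lo[3] & V[, 3] <= hi[3])
  oncut <- vin[points_on_surface(V[vin, , drop = FALSE], btris)]
  ring_verts <- union(ring_verts, oncut)
  ring_edge <- ends[, 1] %in% ring_verts | ends[, 2] %in% ring_verts
  cand <- which(inbox & !ring_edge)

  tcross <- rep(NA_real_, ne)     # fan crossings (used for exact clipping)
  bcross <- rep(NA_real_, ne)     # any blocking-surface crossing
  if (length(cand) > 0) {
    tcross[cand] <- segments_fan_hits(P0[cand, , drop = FALSE],
                                      P1[cand, , drop = FALSE], tris)
    bcross[cand] <- segments_fan_hits(P0[cand, , drop = FALSE],
                                      P1[cand, , drop = FALSE], curt)
  }
  crossed <- !is.na(tcross)
  blocked <- crossed | !is.na(bcross) | ring_edge
  if (!any(blocked))
    p4d_stop("cut surface does not intersect the mesh", "p4d_leak_error")

  # face adjacency across unblocked edges
  # edge id -> the two adjacent faces
  ord <- order(eid)
  eids <- eid[ord]; fs <- face_of_slot[ord]
  first <- !duplicated(eids)
  f1 <- integer(ne); f2 <- integer(ne)
  f1[eids[first]] <- fs[first]
  sec <- duplicated(eids) & !duplicated(eids, fromLast = FALSE) | FALSE
  # second occurrence per edge:
  second <- duplicated(eids)
  f2[eids[second]] <- fs[second]

  # BFS over faces
  fc <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
           V[F[, 3], , drop = FALSE]) / 3
  seed_face <- which.min(colSums((t(fc) - dome_seed)^2))
  inS <- logical(m)
  inS[seed_face] <- TRUE
  frontier <- seed_face
  open_eid <- which(!blocked & f2 != 0L)
  # neighbour lookup: for each face, its up to 3 unblocked neighbours
  nb1 <- f1[open_eid]; nb2 <- f2[open_eid]
  adj <- split(c(nb2, nb1), c(nb1, nb2))
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!inS[nxt]]
    inS[nxt] <- TRUE
    frontier <- nxt
  }
  frac <- mean(inS)
  if (frac > leak_fraction)
    p4d_stop(sprintf("region grow reached %.0f%% of all faces: cut failed to separate",
                     100 * frac), "p4d_leak_error")

  # --- exact clipping of straddling faces --------------------------------
  # face -> its crossed-edge ids
  face_cross <- split(eid[crossed[eid]], face_of_slot[crossed[eid]])
  ncross <- integer(m)
  ncross[as.integer(names(face_cross))] <- lengths(face_cross)
  clean <- ncross == 2L
  # an edge is split only while both adjacent faces are clipped; iterate to
  # a fixpoint so no T-vertices arise next to degenerate (1- or 3-crossing)
  # faces
  clipped <- clean
  repeat {
    esplit <- crossed & clipped[pmax(f1, 1L)] & clipped[pmax(f2, 1L)] &
      f1 != 0L & f2 != 0L
    newclip <- clean
    for (fi in which(clean)) {
      if (!all(esplit[face_cross[[as.character(fi)]]])) newclip[fi] <- FALSE
    }
    if (identical(newclip, clipped)) break
    clipped <- newclip
  }
  esplit <- crossed & clipped[pmax(f1, 1L)] & clipped[pmax(f2, 1L)] &
    f1 != 0L & f2 != 0L

  # new vertices at split points
  nV <- nrow(V)
  splits <- which(esplit)
  qidx <- integer(ne)
  if (length(splits) > 0) {
    qpts <- V[ends[splits, 1], , drop = FALSE] +
      tcross[splits] * (V[ends[splits, 2], , drop = FALSE] -
                          V[ends[splits, 1], , drop = FALSE])
    V <- rbind(V, qpts)
    qidx[splits] <- nV + seq_along(splits)
  }

  # assemble dome and vessel face lists
  dome_faces <- list(); vessel_faces <- list()
  edge_id_of <- function(a, b) {
    loh <- pmin(a, b); hih <- pmax(a, b)
    match(loh * 2^26 + hih, ukey)
  }
  for (fi in seq_len(m)) {
    tri <- F[fi, ]
    if (!clipped[fi]) {
      if (inS[fi]) dome_faces[[length(dome_faces) + 1L]] <- tri
      else vessel_faces[[length(vessel_faces) + 1L]] <- tri
      next
    }
    e3 <- edge_id_of(tri[c(1, 2, 3)], tri[c(2, 3, 1)])  # edges 1-2, 2-3, 3-1
    ce <- which(crossed[e3])
    if (length(ce) != 2L || !all(esplit[e3[ce]])) {
      if (inS[fi]) dome_faces[[length(dome_faces) + 1L]] <- tri
      else vessel_faces[[length(vessel_faces) + 1L]] <- tri
      next
    }
    # shared (lone-corner) vertex of the two crossed edges
    verts_of_edge <- list(c(1, 2), c(2, 3), c(3, 1))
    vv <- c(verts_of_edge[[ce[1]]], verts_of_edge[[ce[2]]])
    shared_local <- vv[duplicated(vv)]
    rot <- switch(shared_local, `1` = c(1, 2, 3), `2` = c(2, 3, 1), `3` = c(3, 1, 2))
    w <- tri[rot[1]]; a <- tri[rot[2]]; b <- tri[rot[3]]
    qa <- qidx[edge_id_of(w, a)]; qb <- qidx[edge_id_of(b, w)]
    quad <- list(c(qa, a, b), c(qa, b, qb))
    corner <- list(c(w, qa, qb))
    if (inS[fi]) {  # corner vertex lies across the cut (vessel side)
      dome_faces <- c(dome_faces, quad)
      vessel_faces <- c(vessel_faces, corner)
    } else {        # complement face: its lone corner is on the dome side
      vessel_faces <- c(vessel_faces, quad)
      dome_faces <- c(dome_faces, corner)
    }
  }
  DF <- do.call(rbind, dome_faces)
  VF <- do.call(rbind, vessel_faces)

  # cone cap from the cut centroid over the unmatched boundary edges
  apex_id <- nrow(V) + 1L
  V <- rbind(V, cut$apex)
  cap_for <- function(faces) {
    de <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    key <- de[, 1] * 2^26 + de[, 2]
    rkey <- de[, 2] * 2^26 + de[, 1]
    unmatched <- !(key %in% rkey)
    be <- de[unmatched, , drop = FALSE]
    if (nrow(be) == 0) return(NULL)
    cbind(apex_id, be[, 2], be[, 1])
  }
  dome_cap <- cap_for(DF)
  dome_all <- rbind(DF, dome_cap)
  vessel_all <- rbind(VF, if (!is.null(dome_cap)) dome_cap[, c(1, 3, 2)])

  dome_mesh <- surface_mesh(V, dome_all, phase = mesh$phase, iso = mesh$iso)
  if (!is_closed_surface(dome_all))
    p4d_stop("partitioned aneurysm mesh is not watertight", "p4d_open_mesh")
  wt <- is_watertight(dome_mesh)
  vol <- as.numeric(mesh_enclosed_volume(dome_mesh, check = FALSE))
  vmesh <- surface_mesh(V, vessel_all, phase = mesh$phase, iso = mesh$iso)
  vvol <- abs(signed_mesh_volume(vmesh))
  tot <- abs(signed_mesh_volume(surface_mesh(mesh$vertices, F)))
  area <- {
    dm <- surface_mesh(V, DF); mesh_surface_area(dm)
  }
  structure(list(volume = vol, area = area, vessel_volume = vvol,
                 total_volume = tot, mesh = dome_mesh, watertight = wt,
                 fraction_grown = frac, phase = mesh$phase),
            class = "aneurysm_segmentation")
}

#' @export
print.aneurysm_segmentation <- function(x, ...) {
  cat(sprintf("<aneurysm_segmentation> phase %s: volume %.3f mm^3 (vessel %.3f, total %.3f)\n",
              ifelse(is.na(x$phase), "?", x$phase), x$volume, x$vessel_volume,
              x$total_volume))
  invisible(x)
}

#' Per-phase aneurysm volume curve
#'
#' Runs the full separation for every cardiac phase: neck-point transfer by
#' ICP, cut-surface construction and dome/vessel partition, returning the
#' per-phase aneurysm volumes with diagnostics (ICP RMS residual,
#' watertightness). Phases that fail are reported and the curve is marked
#' incomplete.
#'
#' @param mesh_seq a [build_mesh_sequence()] result.
#' @param points0 phase-0 [neck_points()].
#' @param dome_seed mm point in the aneurysm dome.
#' @param focus_radius,corrections passed to [transfer_neck_points()].
#' @param fan_extend passed to [partition_mesh()].
#' @return A [volume_curve()] (state `"raw"`) with a `diagnostics` data frame
#'   (phase, icp_rms, watertight, fraction_grown). If any phase fails, a list
#'   of class `incomplete_volume_curve` with partial `values` and `errors`.
#' @export
aneurysm_volume_curve <- function(mesh_seq, points0, dome_seed,
                                  focus_radius = NULL, corrections = NULL,
                                  fan_extend = 1) {
  pts <- transfer_neck_points(points0, mesh_seq, focus_radius = focus_radius,
                              corrections = corrections)
  tfs <- attr(pts, "transforms")
  np <- length(mesh_seq$meshes)
  vols <- rep(NA_real_, np)
  rms <- rep(NA_real_, np)
  wt <- rep(NA, np)
  fg <- rep(NA_real_, np)
  errors <- list()
  for (p in seq_len(np)) {
    res <- tryCatch({
      cut <- build_cut_surface(pts[[p]])
      partition_mesh(mesh_seq$meshes[[p]], cut, dome_seed,
                     fan_extend = fan_extend)
    }, pulse4d_error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(p - 1L)]] <- conditionMessage(res)
    } else {
      vols[p] <- res$volume
      wt[p] <- res$watertight
      fg[p] <- res$fraction_grown
    }
    rms[p] <- if (!is.null(tfs[[p]])) tfs[[p]]$rms else NA_real_
  }
  diag_df <- data.frame(phase = seq_len(np) - 1L, icp_rms = rms,
                        watertight = wt, fraction_grown = fg)
  if (length(errors) > 0) {
    p4d_warn(sprintf("volume curve incomplete: %d phase(s) failed",
                     length(errors)), "p4d_incomplete_curve")
    return(structure(list(values = vols, diagnostics = diag_df,
                          errors = errors),
                     class = "incomplete_volume_curve"))
  }
  volume_curve(vols, state = "raw", diagnostics = diag_df)
}
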