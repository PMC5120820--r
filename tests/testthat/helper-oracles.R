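# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force symmetric Hausdorff distance between curves embedded as
# {(t_i, v_i)} point sets
bf_hausdorff <- function(a, b, value_only = FALSE) {
  n <- length(a)
  t <- if (value_only) rep(0, n) else seq(0, 1, length.out = n)
  pa <- cbind(t, a); pb <- cbind(t, b)
  h <- function(X, Y) {
    worst <- 0
    for (i in seq_len(nrow(X))) {
      best <- Inf
      for (j in seq_len(nrow(Y))) {
        d <- sqrt(sum((X[i, ] - Y[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(h(pa, pb), h(pb, pa))
}

# mid-rank Pearson correlation, written out explicitly
bf_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  ma <- mean(ra); mb <- mean(rb)
  sum((ra - ma) * (rb - mb)) /
    sqrt(sum((ra - ma)^2) * sum((rb - mb)^2))
}

# two-way ANOVA mean squares by explicit summation (subjects x raters)
bf_anova_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - g)^2
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  c(MSR = ssr / (n - 1), MSC = ssc / (k - 1), MSE = sse / ((n - 1) * (k - 1)))
}

bf_icc21 <- function(x) {
  ms <- bf_anova_ms(x)
  n <- nrow(x); k <- ncol(x)
  (ms["MSR"] - ms["MSE"]) /
    (ms["MSR"] + (k - 1) * ms["MSE"] + k * (ms["MSC"] - ms["MSE"]) / n)
}

# unit cube as a closed, outward-oriented triangle mesh
unit_cube_mesh <- function() {
  v <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1), ncol = 3, byrow = TRUE)
  f <- matrix(c(1, 3, 2, 1, 4, 3, 5, 6, 7, 5, 7, 8,
                1, 2, 6, 1, 6, 5, 2, 3, 7, 2, 7, 6,
                3, 4, 8, 3, 8, 7, 4, 1, 5, 4, 5, 8), ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}

# icosahedron inscribed in the unit sphere, with optional subdivision steps
icosphere_mesh <- function(subdiv = 0) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0, 1, phi, 0, -1, -phi, 0, 1, -phi, 0,
                0, -1, phi, 0, 1, phi, 0, -1, -phi, 0, 1, -phi,
                phi, 0, -1, phi, 0, 1, -phi, 0, -1, -phi, 0, 1),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
                2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
                4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
                5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2),
              ncol = 3, byrow = TRUE)
  for (s in seq_len(subdiv)) {
    nv <- v; nf <- NULL
    midcache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- rbind(nv, m)
      midcache[[key]] <- nrow(nv)
      nrow(nv)
    }
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c3 <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- nv; f <- nf
  }
  surface_mesh(v, f)
}

# digital sphere volume on a grid of spacing h: supersampled occupancy
# mapped to HU (background 40, lumen 400), two identical phases
digital_sphere_volume <- function(h = 0.25, R = 2.5, S = 3L) {
  n <- ceiling((2 * R + 2.5) / h); n <- n + (n %% 2)
  g <- c(n, n, n); orp <- -(g - 1) * h / 2
  xs <- orp[1] + (0:(n - 1)) * h
  X <- rep(xs, times = n * n)
  Y <- rep(rep(xs, each = n), times = n)
  Z <- rep(xs, each = n * n)
  offs <- ((seq_len(S) - 0.5) / S - 0.5) * h
  acc <- numeric(length(X))
  for (ox in offs) for (oy in offs) for (oz in offs)
    acc <- acc + (((X + ox)^2 + (Y + oy)^2 + (Z + oz)^2) <= R^2)
  hu <- 40 + (acc / S^3) * 360
  ct_volume_4d(array(rep(hu, 2), dim = c(g, 2)), spacing = c(h, h, h),
               origin = orp)
}

# Monte-Carlo volume of sphere-minus-cylinder (the aneurysm sphere outside
# the vessel tube). Seeded and deterministic.
mc_sphere_minus_cyl <- function(truth, phase = 1L, n = 2e6, seed = 98L) {
  spec <- truth$spec
  R <- truth$radii[phase]; rv <- spec$vessel_radius
  ctr <- spec$aneurysm_center
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  P <- cbind(runif(n, ctr[1] - R, ctr[1] + R),
             runif(n, ctr[2] - R, ctr[2] + R),
             runif(n, ctr[3] - R, ctr[3] + R))
  insph <- rowSums(sweep(P, 2, ctr)^2) <= R^2
  ax <- sweep(P, 2, spec$vessel_point)
  tpar <- ax %*% spec$vessel_axis
  incyl <- rowSums((ax - tpar %*% t(spec$vessel_axis))^2) <= rv^2
  (2 * R)^3 * mean(insph & !incyl)
}

# Monte-Carlo volume of the region the neck separation measures: inside the
# aneurysm sphere, and outside the vessel tube or above the centroid cone
# over the sphere-tube junction curve. Seeded and deterministic.
mc_membrane_volume <- function(truth, phase = 1L, n = 2e6, seed = 99L) {
  spec <- truth$spec
  R <- truth$radii[phase]; rv <- spec$vessel_radius
  ctr <- spec$aneurysm_center
  rim <- truth$neck_rings[[phase]]
  apex <- colMeans(rim)
  u <- truth$neck_plane$normal
  b1 <- spec$vessel_axis
  b2 <- c(u[2] * b1[3] - u[3] * b1[2], u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  rimc <- sweep(rim, 2, apex)
  phi_r <- atan2(rimc %*% b2, rimc %*% b1)
  r_r <- sqrt((rimc %*% b1)^2 + (rimc %*% b2)^2)
  h_r <- rimc %*% u
  ord <- order(phi_r)
  xs <- c(phi_r[ord], phi_r[ord][1] + 2 * pi)
  yr <- c(r_r[ord], r_r[ord][1]); yh <- c(h_r[ord], h_r[ord][1])
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  P <- cbind(runif(n, ctr[1] - R, ctr[1] + R),
             runif(n, ctr[2] - R, ctr[2] + R),
             runif(n, ctr[3] - R, ctr[3] + R))
  boxv <- (2 * R)^3
  insph <- rowSums(sweep(P, 2, ctr)^2) <= R^2
  ax <- sweep(P, 2, spec$vessel_point)
  tpar <- ax %*% spec$vessel_axis
  incyl <- rowSums((ax - tpar %*% t(spec$vessel_axis))^2) <= rv^2
  pc <- sweep(P, 2, apex)
  phi <- atan2(pc %*% b2, pc %*% b1)
  r_p <- sqrt((pc %*% b1)^2 + (pc %*% b2)^2)
  h_p <- pc %*% u
  phi2 <- ifelse(phi < xs[1], phi + 2 * pi, phi)
  rb <- approx(xs, yr, phi2)$y
  hb <- approx(xs, yh, phi2)$y
  above <- h_p * rb - hb * r_p > 0
  boxv * mean(insph & (!incyl | above))
}
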