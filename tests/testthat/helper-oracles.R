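# Independent oracles and small programmatic fixtures. The closest-point
# oracle is a plain all-triangles scan written directly from the geometry
# (unconstrained barycentric solution plus the three clamped edges), kept
# deliberately separate from the accelerated C++ path it checks.

oracle_closest_distance <- function(q, mesh) {
  V <- mesh$vertices
  Fc <- mesh$faces
  q <- as.matrix(q)
  best <- rep(Inf, nrow(q))
  for (i in seq_len(nrow(Fc))) {
    a <- V[Fc[i, 1L], ]; b <- V[Fc[i, 2L], ]; cc <- V[Fc[i, 3L], ]
    ab <- b - a; ac <- cc - a; bc <- cc - b
    A11 <- sum(ab * ab); A12 <- sum(ab * ac); A22 <- sum(ac * ac)
    det <- A11 * A22 - A12^2
    qp <- sweep(q, 2L, a)
    d1 <- as.vector(qp %*% ab)
    d2 <- as.vector(qp %*% ac)
    dist2 <- function(s, t) rowSums((qp - outer(s, ab) - outer(t, ac))^2)
    d_in <- rep(Inf, nrow(q))
    if (det > 1e-300) {
      s <- (A22 * d1 - A12 * d2) / det
      t <- (A11 * d2 - A12 * d1) / det
      inside <- s >= 0 & t >= 0 & s + t <= 1
      d_in[inside] <- dist2(s, t)[inside]
    }
    d_ab <- dist2(pmax(0, pmin(1, d1 / A11)), numeric(nrow(q)))
    d_ac <- dist2(numeric(nrow(q)), pmax(0, pmin(1, d2 / A22)))
    qb <- sweep(q, 2L, b)
    u_bc <- pmax(0, pmin(1, as.vector(qb %*% bc) / sum(bc * bc)))
    d_bc <- rowSums((qb - outer(u_bc, bc))^2)
    best <- pmin(best, d_in, d_ab, d_ac, d_bc)
  }
  sqrt(best)
}

# Rigid fit by direct numerical search over Euler angles (translation is
# the closed-form centroid match given the rotation) -- an optimizer
# oracle independent of the SVD route.
oracle_rigid_fit <- function(source, target) {
  obj <- function(ang) {
    R <- mirrormorph:::rotation_xyz_deg(ang[1], ang[2], ang[3])
    src_rot <- source %*% t(R)
    tr <- colMeans(target) - colMeans(src_rot)
    sum((sweep(src_rot, 2L, tr, "+") - target)^2)
  }
  fit <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  R <- mirrormorph:::rotation_xyz_deg(fit$par[1], fit$par[2], fit$par[3])
  list(rotation = R,
       translation = colMeans(target) - as.vector(colMeans(source %*% t(R))))
}

# An 8-vertex unit cube shell centred on the origin (12 triangles).
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                             z = c(-0.5, 0.5)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  triangle_mesh(v, f)
}

# A small random smooth open shell: z = quadratic + random smooth bumps
# over a grid. Deterministic given seed.
random_shell <- function(seed, n_side = 12) {
  set.seed(seed)
  g <- seq(-20, 20, length.out = n_side)
  xy <- as.matrix(expand.grid(x = g, y = g))
  cf <- rnorm(6, 0, 0.01)
  z <- cf[1] * xy[, 1]^2 / 20 + cf[2] * xy[, 2]^2 / 20 +
    cf[3] * xy[, 1] * xy[, 2] / 20 +
    5 * sin(xy[, 1] / (8 + abs(cf[4]) * 100)) * cos(xy[, 2] / 9)
  idx <- matrix(seq_len(n_side^2), n_side, n_side)
  a <- idx[-n_side, -n_side]; b <- idx[-1, -n_side]
  cc <- idx[-n_side, -1]; d <- idx[-1, -1]
  faces <- rbind(cbind(as.vector(a), as.vector(b), as.vector(d)),
                 cbind(as.vector(a), as.vector(d), as.vector(cc)))
  triangle_mesh(cbind(xy, z), faces)
}

# Default lesion geometry used across tests: mid-cheek on the +x side,
# centre on the surface of the default base face, spec-scale radius.
test_lesion <- function(depth, radius = 15) {
  atrophy_field(center = c(30, -12, 31), radius = radius, depth = depth)
}
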