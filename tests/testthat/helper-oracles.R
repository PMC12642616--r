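# Independent oracles and small fixture builders used across the tests.
# These deliberately avoid the package's own geometry code paths.

angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi  # axis, sign-free
}

# Monte-Carlo lumen area oracle: uniform samples in the padded bounding box;
# a sample is lumen if inside the convex hull of the projected centres
# (mgcv::in.out, an independent point-in-polygon test) and outside every
# atom disk.
mc_lumen_area <- function(pts, radii, n = 1e6, seed = 42) {
  withr::with_seed(seed, {
    bx <- range(pts[, 1]) + c(-5, 5)
    by <- range(pts[, 2]) + c(-5, 5)
    px <- runif(n, bx[1], bx[2])
    py <- runif(n, by[1], by[2])
    up <- unique(round(pts, 9))
    h <- grDevices::chull(up)
    bnd <- rbind(up[h, , drop = FALSE], up[h[1], , drop = FALSE])
    ok <- mgcv::in.out(bnd, cbind(px, py))
    radii <- rep_len(radii, nrow(pts))
    if (any(radii > 0)) {
      mind2 <- rep(Inf, n)
      for (i in seq_len(nrow(pts))) {
        if (radii[i] <= 0) next
        d2 <- (px - pts[i, 1])^2 + (py - pts[i, 2])^2 - radii[i]^2
        mind2 <- pmin(mind2, d2)
      }
      ok <- ok & mind2 > 0
    }
    mean(ok) * diff(bx) * diff(by)
  })
}

# Brute-force rejection-sampling SASA oracle: random points on each atom's
# probe-inflated sphere, accessible if outside every other inflated sphere.
mc_sasa <- function(xyz, radii, probe = 1.4, n = 1e4, seed = 42) {
  withr::with_seed(seed, {
    na <- nrow(xyz)
    rr <- radii + probe
    total <- 0
    per_atom <- numeric(na)
    for (i in seq_len(na)) {
      g <- matrix(rnorm(3 * n), n, 3)
      g <- g / sqrt(rowSums(g^2))
      p <- sweep(g * rr[i], 2, xyz[i, ], `+`)
      acc <- rep(TRUE, n)
      for (j in seq_len(na)[-i]) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        acc <- acc & d2 > rr[j]^2
      }
      per_atom[i] <- mean(acc) * 4 * pi * rr[i]^2
    }
    list(per_atom = per_atom, total = sum(per_atom))
  })
}

# rigid motion: rotation about an arbitrary axis + translation
rotate_model <- function(model, axis = c(1, 2, 3), angle = 0.7,
                         shift = c(11, -7, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- coords(model) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# straight-line test model: n atoms along +z, 1 A apart, one residue each
line_model <- function(n = 50) {
  structure_model(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resid = "GLY",
    chain = "A", resno = seq_len(n), x = 0, y = 0, z = seq_len(n) - 1,
    occupancy = 1, is_hetero = FALSE, vdw_radius = 1.7
  ))
}
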