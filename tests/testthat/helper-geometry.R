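# Independent geometry oracles (pure R, no shared code with the package's
# compiled path) and small mesh constructors.

# icosphere of radius r: subdivided icosahedron, vertices exactly on the
# sphere
icosphere <- function(r = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- new.env(parent = emptyenv())
    verts <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (is.null(id)) {
        m <- (verts[[a]] + verts[[b]])
        m <- m / sqrt(sum(m^2))
        verts[[length(verts) + 1]] <<- m
        id <- length(verts)
        edge_id[[key]] <- id
      }
      id
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, verts)
    f <- newf
  }
  surface_mesh(v * r, f)
}

# distance from point p to triangle (a, b, c): minimum over the plane
# projection (if its barycentric coordinates are inside), the three edge
# segments and the three vertices
point_tri_dist_ref <- function(p, a, b, c) {
  seg <- function(q, u, v) {
    w <- v - u
    t <- sum((q - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((q - (u + t * w))^2))
  }
  best <- min(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sum(n * n)
  if (nn > 0) {
    q <- p - sum((p - a) * n) / nn * n
    # barycentric test
    v0 <- c - a; v1 <- b - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    if (den > 0) {
      u <- (d11 * d20 - d01 * d21) / den
      w <- (d00 * d21 - d01 * d20) / den
      if (u >= 0 && w >= 0 && u + w <= 1)
        best <- min(best, sqrt(sum((p - q)^2)))
    }
  }
  best
}

# exhaustive all-triangles nearest distance (the brute-force oracle)
brute_force_distance <- function(mesh, points) {
  apply(points, 1, function(p) {
    min(apply(mesh$faces, 1, function(f)
      point_tri_dist_ref(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                         mesh$vertices[f[3], ])))
  })
}

random_rigid <- function() {
  ax <- stats::rnorm(3)
  rotation_about(ax, stats::runif(1, -30, 30),
                 center = stats::rnorm(3, sd = 5))
}
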