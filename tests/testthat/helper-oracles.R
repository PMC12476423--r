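# Independent oracles and tiny fixtures, built in code.

# Orthogonal Procrustes best-fit rotation via base R's full SVD,
# independent of the package's compiled polar decomposition.
procrustes_rotation <- function(current, rest) {
  A <- t(current) %*% rest
  s <- svd(A)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

rotation_about_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Axis-aligned unit cube mesh centered at the origin: 8 vertices, 12
# triangles, outward winding.
cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                             z = c(-0.5, 0.5))) * edge
  dimnames(v) <- NULL
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -  (outward -z)
    c(5, 6, 7), c(6, 8, 7),   # z = +
    c(1, 2, 5), c(2, 6, 5),   # y = -
    c(3, 7, 4), c(4, 7, 8),   # y = +
    c(1, 5, 3), c(3, 5, 7),   # x = -
    c(2, 4, 6), c(4, 8, 6))   # x = +
  surface_mesh(v, tr)
}

# Octahedron: vertices on the coordinate axes, so several coordinates sit
# exactly on internal cell boundaries of a level-1 grid.
octahedron_mesh <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  tr <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
              c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  surface_mesh(v, tr)
}

# A free-standing two-cube lattice (shared face, 12 corner particles)
# for solver tests that do not need a mesh.
bar_lattice <- function(edge = 1, base = c(0, 0, 0)) {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:1, z = 0:1))
  dimnames(g) <- NULL
  corner_rest <- sweep(g * edge, 2, base, `+`)
  id_of <- function(x, y, z) which(g[, 1] == x & g[, 2] == y & g[, 3] == z)
  corners <- t(vapply(0:1, function(cx) {
    c(id_of(cx, 0, 0), id_of(cx + 1, 0, 0), id_of(cx, 1, 0),
      id_of(cx + 1, 1, 0), id_of(cx, 0, 1), id_of(cx + 1, 0, 1),
      id_of(cx, 1, 1), id_of(cx + 1, 1, 1))
  }, integer(8)))
  structure(list(level = c(0L, 0L),
                 ijk = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)),
                 origin = rbind(base, base + c(edge, 0, 0)),
                 edge = c(edge, edge),
                 corners = corners,
                 intersects = c(TRUE, TRUE),
                 region = c("surface", "surface"),
                 corner_rest = corner_rest,
                 root_origin = base, root_edge = 2 * edge,
                 max_level = 0L,
                 vertex_cube = NULL, local_coords = NULL,
                 n_c = 2L),
            class = "octree_lattice")
}

# Brute-force voxelization oracle: every cell of the full level-`lev`
# grid tested against every triangle with a vectorized separating-axis
# triangle/box overlap, independent of the package's recursive builder.
brute_surface_cells <- function(mesh, lattice) {
  lev <- lattice$max_level
  side <- 2^lev
  L <- lattice$root_edge / side
  tr <- mesh$triangles
  A <- mesh$vertices[tr[, 1], , drop = FALSE]
  B <- mesh$vertices[tr[, 2], , drop = FALSE]
  C <- mesh$vertices[tr[, 3], , drop = FALSE]
  h <- L / 2
  hit_cell <- function(ijk) {
    ctr <- lattice$root_origin + (ijk + 0.5) * L
    v0 <- sweep(A, 2, ctr); v1 <- sweep(B, 2, ctr); v2 <- sweep(C, 2, ctr)
    alive <- rep(TRUE, nrow(v0))
    for (k in 1:3) {
      mn <- pmin(v0[, k], v1[, k], v2[, k])
      mx <- pmax(v0[, k], v1[, k], v2[, k])
      alive <- alive & !(mn > h | mx < -h)
    }
    if (!any(alive)) return(FALSE)
    e0 <- v1 - v0; f1 <- v2 - v0
    nrm <- cbind(e0[, 2] * f1[, 3] - e0[, 3] * f1[, 2],
                 e0[, 3] * f1[, 1] - e0[, 1] * f1[, 3],
                 e0[, 1] * f1[, 2] - e0[, 2] * f1[, 1])
    d <- rowSums(nrm * v0)
    alive <- alive & (abs(d) <= h * (abs(nrm[, 1]) + abs(nrm[, 2]) + abs(nrm[, 3])))
    if (!any(alive)) return(FALSE)
    edges <- list(v1 - v0, v2 - v1, v0 - v2)
    for (e in edges) {
      for (ax in 1:3) {
        # axis = cross(unit axis ax, edge)
        a <- matrix(0, nrow(e), 3)
        if (ax == 1) { a[, 2] <- -e[, 3]; a[, 3] <- e[, 2] }
        if (ax == 2) { a[, 1] <- e[, 3]; a[, 3] <- -e[, 1] }
        if (ax == 3) { a[, 1] <- -e[, 2]; a[, 2] <- e[, 1] }
        p0 <- rowSums(a * v0); p1 <- rowSums(a * v1); p2 <- rowSums(a * v2)
        rad <- h * (abs(a[, 1]) + abs(a[, 2]) + abs(a[, 3]))
        alive <- alive & !(pmin(p0, p1, p2) > rad | pmax(p0, p1, p2) < -rad)
      }
      if (!any(alive)) return(FALSE)
    }
    any(alive)
  }
  out <- list()
  for (i in 0:(side - 1)) for (j in 0:(side - 1)) for (k in 0:(side - 1))
    if (hit_cell(c(i, j, k))) out[[length(out) + 1L]] <- c(i, j, k)
  do.call(rbind, out)
}

cell_keys <- function(ijk, side) {
  if (is.null(ijk) || nrow(ijk) == 0) return(integer())
  sort(ijk[, 1] + side * (ijk[, 2] + side * ijk[, 3]))
}

# triangle multiset signature through global ids, order-insensitive
triangle_signature <- function(tris) {
  sorted <- t(apply(tris, 1, sort))
  sort(paste(sorted[, 1], sorted[, 2], sorted[, 3]))
}
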