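#' Trilinear interpolation of a point through a deformed cube cage
#'
#' Cascaded-lerp form: with local coordinates `(x, y, z)` and deformed
#' corners `C'_0 ... C'_7` in the fixed corner convention
#' (`C0=(0,0,0), C1=(1,0,0), C2=(0,1,0), C3=(1,1,0), C4=(0,0,1),
#' C5=(1,0,1), C6=(0,1,1), C7=(1,1,1)` in cube-local units), four x-lerps
#' produce interior points `D0..D3`, two y-lerps produce `D4, D5`, and a
#' final z-lerp gives `P' = z (D5 - D4) + D4`. Algebraically this equals
#' the weight sum `sum_i w_i C'_i` with trilinear weights. Local
#' coordinates outside `[0, 1]` extrapolate with the same formula.
#'
#' @param local length-3 local coordinates `(x, y, z)`.
#' @param corners `8 x 3` matrix of deformed corner positions.
#' @return Length-3 deformed position.
#' @examples
#' cage <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' trilinear_point(c(0.25, 0.5, 0.75), cage)  # identity cage
#' @export
trilinear_point <- function(local, corners) {
  if (!all(is.finite(local)) || !all(is.finite(corners)))
    stop("non-finite input to trilinear interpolation")
  x <- local[1]; y <- local[2]; z <- local[3]
  d0 <- x * (corners[2, ] - corners[1, ]) + corners[1, ]
  d1 <- x * (corners[4, ] - corners[3, ]) + corners[3, ]
  d2 <- x * (corners[6, ] - corners[5, ]) + corners[5, ]
  d3 <- x * (corners[8, ] - corners[7, ]) + corners[7, ]
  d4 <- y * (d1 - d0) + d0
  d5 <- y * (d3 - d2) + d2
  unname(z * (d5 - d4) + d4)
}

#' Trilinear corner weights for a set of local coordinates
#'
#' @param locals `n x 3` matrix of local coordinates.
#' @return `n x 8` weight matrix in the fixed corner convention; rows sum
#'   to 1.
#' @export
trilinear_weights <- function(locals) {
  locals <- as_mat3(locals, "locals")
  x <- locals[, 1]; y <- locals[, 2]; z <- locals[, 3]
  cbind((1 - x) * (1 - y) * (1 - z), x * (1 - y) * (1 - z),
        (1 - x) * y * (1 - z),       x * y * (1 - z),
        (1 - x) * (1 - y) * z,       x * (1 - y) * z,
        (1 - x) * y * z,             x * y * z)
}

# Partial derivatives of the weights, for the mapping Jacobian.
trilinear_weight_grads <- function(locals) {
  x <- locals[, 1]; y <- locals[, 2]; z <- locals[, 3]
  list(
    dx = cbind(-(1 - y) * (1 - z), (1 - y) * (1 - z), -y * (1 - z), y * (1 - z),
               -(1 - y) * z, (1 - y) * z, -y * z, y * z),
    dy = cbind(-(1 - x) * (1 - z), -x * (1 - z), (1 - x) * (1 - z), x * (1 - z),
               -(1 - x) * z, -x * z, (1 - x) * z, x * z),
    dz = cbind(-(1 - x) * (1 - y), -x * (1 - y), -(1 - x) * y, -x * y,
               (1 - x) * (1 - y), x * (1 - y), (1 - x) * y, x * y))
}

# rows of `normals` transformed by the inverse-transpose of per-vertex
# Jacobians; J stored columnwise as three n x 3 blocks (dP'/dx etc.).
# With columns c1, c2, c3: J^-T = [c2 x c3, c3 x c1, c1 x c2] / det, and
# det drops out (up to sign) after renormalization.
normal_by_jacobian <- function(normals, Jx, Jy, Jz) {
  m1 <- cbind(Jy[, 2] * Jz[, 3] - Jy[, 3] * Jz[, 2],
              Jy[, 3] * Jz[, 1] - Jy[, 1] * Jz[, 3],
              Jy[, 1] * Jz[, 2] - Jy[, 2] * Jz[, 1])
  m2 <- cbind(Jz[, 2] * Jx[, 3] - Jz[, 3] * Jx[, 2],
              Jz[, 3] * Jx[, 1] - Jz[, 1] * Jx[, 3],
              Jz[, 1] * Jx[, 2] - Jz[, 2] * Jx[, 1])
  m3 <- cbind(Jx[, 2] * Jy[, 3] - Jx[, 3] * Jy[, 2],
              Jx[, 3] * Jy[, 1] - Jx[, 1] * Jy[, 3],
              Jx[, 1] * Jy[, 2] - Jx[, 2] * Jy[, 1])
  out <- normals[, 1] * m1 + normals[, 2] * m2 + normals[, 3] * m3
  bad <- rowSums(out^2) < 1e-24
  if (any(bad)) out[bad, ] <- normals[bad, , drop = FALSE]
  normalize_rows(out)
}

map_normals <- function(locals, normals, corners, mode) {
  if (mode == "jacobian") {
    g <- trilinear_weight_grads(locals)
    normal_by_jacobian(normals, g$dx %*% corners, g$dy %*% corners,
                       g$dz %*% corners)
  } else {
    # literal trilinear blend: transform the rest normal by the mapping
    # Jacobian evaluated at each of the 8 cube corners, then blend the 8
    # candidates with the vertex's trilinear weights
    cl <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * 1.0
    gc <- trilinear_weight_grads(cl)
    acc <- matrix(0, nrow(locals), 3L)
    W <- trilinear_weights(locals)
    n <- nrow(locals)
    for (j in 1:8) {
      jx <- as.numeric(gc$dx[j, ] %*% corners)
      jy <- as.numeric(gc$dy[j, ] %*% corners)
      jz <- as.numeric(gc$dz[j, ] %*% corners)
      nj <- normal_by_jacobian(normals,
                               matrix(jx, n, 3L, byrow = TRUE),
                               matrix(jy, n, 3L, byrow = TRUE),
                               matrix(jz, n, 3L, byrow = TRUE))
      acc <- acc + W[, j] * nj
    }
    normalize_rows(acc)
  }
}

#' Map mesh vertices through the deformed lattice, vertex by vertex
#'
#' The per-vertex reference path: for every mesh vertex, gather the 8
#' deformed corners of its assigned surface cube and apply
#' [trilinear_point()] at the vertex's stored local coordinates. Rest
#' normals are carried through the deformation (see `normal_mode`) and
#' renormalized.
#'
#' @param lattice an assigned `octree_lattice`.
#' @param state a `lattice_state` (current corner positions).
#' @param mesh the original [surface_mesh()] (source of rest normals).
#' @param normal_mode `"jacobian"` (transform by the inverse-transpose
#'   Jacobian of the trilinear map at the vertex) or `"trilinear"`
#'   (blend corner-transformed normals with the trilinear weights).
#' @return list with `positions` (`n_v x 3`) and `normals` (`n_v x 3`,
#'   unit rows).
#' @export
map_vertices_reference <- function(lattice, state, mesh,
                                   normal_mode = c("jacobian", "trilinear")) {
  normal_mode <- match.arg(normal_mode)
  if (is.null(lattice$vertex_cube)) stop("lattice has no vertex assignment")
  if (any(lattice$region[lattice$vertex_cube] != "surface"))
    stop("a mapped vertex references an inside cube")
  nv <- nrow(mesh$vertices)
  pos <- matrix(NA_real_, nv, 3L)
  nrm <- matrix(NA_real_, nv, 3L)
  for (v in seq_len(nv)) {
    ids <- lattice$corners[lattice$vertex_cube[v], ]
    corners <- state$positions[ids, , drop = FALSE]
    lc <- lattice$local_coords[v, ]
    pos[v, ] <- trilinear_point(lc, corners)
    nrm[v, ] <- map_normals(matrix(lc, 1L), mesh$normals[v, , drop = FALSE],
                            corners, normal_mode)
  }
  list(positions = pos, normals = nrm)
}

#' Map mesh pieces through the deformed lattice, vertex by vertex
#'
#' Per-vertex evaluation of the same per-piece assignment that
#' [map_vertices_batched()] consumes: every piece vertex is pushed through
#' [trilinear_point()] one at a time against its piece's cube. This is the
#' loop the batched path replaces, so the two outputs are congruent
#' row-for-row; comparing them isolates the batching itself (duplicated
#' boundary vertices are evaluated through the *same* cube on both
#' paths). [map_vertices_reference()] instead uses the lattice's own
#' vertex assignment and returns one row per original mesh vertex.
#'
#' @inheritParams map_vertices_batched
#' @return Same shape as [map_vertices_batched()].
#' @export
map_pieces_reference <- function(pieces, state,
                                 normal_mode = c("jacobian", "trilinear")) {
  normal_mode <- match.arg(normal_mode)
  np <- length(pieces)
  out_p <- vector("list", np); out_n <- vector("list", np)
  for (i in seq_len(np)) {
    pc <- pieces[[i]]
    corners <- state$positions[pc$corner_ids, , drop = FALSE]
    k <- nrow(pc$local_vertices)
    pos <- matrix(NA_real_, k, 3L)
    nrm <- matrix(NA_real_, k, 3L)
    for (v in seq_len(k)) {
      lc <- pc$local_vertices[v, ]
      pos[v, ] <- trilinear_point(lc, corners)
      nrm[v, ] <- map_normals(matrix(lc, 1L),
                              pc$local_normals[v, , drop = FALSE],
                              corners, normal_mode)
    }
    out_p[[i]] <- pos; out_n[[i]] <- nrm
  }
  list(positions = do.call(rbind, out_p),
       normals = do.call(rbind, out_n),
       global_ids = unlist(lapply(pieces, `[[`, "global_ids")),
       piece_id = rep(seq_len(np),
                      vapply(pieces, function(p) nrow(p$local_vertices),
                             integer(1))))
}

#' Map mesh pieces through the deformed lattice, batched per cube
#'
#' The shader-style path: each piece carries exactly one cube id and its
#' vertices as normalized cube-local coordinates, so the 8 deformed
#' corners are gathered once per piece and all piece vertices are
#' transformed in one matrix product (`W %*% corners`). Output is
#' concatenated in (piece, within-piece vertex) order.
#'
#' @param pieces list of `mesh_piece` from [split_mesh()].
#' @param state a `lattice_state`.
#' @param normal_mode see [map_vertices_reference()].
#' @return list with `positions`, `normals`, `global_ids` (original mesh
#'   vertex index of each output row) and `piece_id`.
#' @export
map_vertices_batched <- function(pieces, state,
                                 normal_mode = c("jacobian", "trilinear")) {
  normal_mode <- match.arg(normal_mode)
  np <- length(pieces)
  out_p <- vector("list", np); out_n <- vector("list", np)
  for (i in seq_len(np)) {
    pc <- pieces[[i]]
    if (any(pc$corner_ids > nrow(state$positions)))
      stop(sprintf("piece %d references corner ids missing from the state", i))
    corners <- state$positions[pc$corner_ids, , drop = FALSE]
    W <- trilinear_weights(pc$local_vertices)
    out_p[[i]] <- W %*% corners
    out_n[[i]] <- map_normals(pc$local_vertices, pc$local_normals, corners,
                              normal_mode)
  }
  list(positions = do.call(rbind, out_p),
       normals = do.call(rbind, out_n),
       global_ids = unlist(lapply(pieces, `[[`, "global_ids")),
       piece_id = rep(seq_len(np),
                      vapply(pieces, function(p) nrow(p$local_vertices),
                             integer(1))))
}
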