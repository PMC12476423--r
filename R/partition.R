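#' Split the render mesh into per-cube pieces
#'
#' Mirrors the per-object split a shader implementation needs: each piece
#' references exactly one surface cube and stores its vertices as
#' normalized cube-local coordinates, so the 8 deformed corner positions
#' are the only per-piece state the mapping requires. Each triangle is
#' assigned to exactly one surface cube - the cube whose half-open extent
#' contains its centroid, falling back to the assigned cube of its first
#' vertex when the centroid's cell is not a surface cube. Vertices of a
#' triangle that lie outside the owning cube are duplicated into the
#' piece with extrapolated local coordinates (components outside
#' `[0, 1]`), so the triangle multiset over all pieces equals the
#' original mesh's exactly. Pieces are ordered by ascending cube id,
#' vertices within a piece by ascending original (global) id.
#'
#' @param mesh a [surface_mesh()].
#' @param lattice an assigned `octree_lattice` built over `mesh`.
#' @return A list of `mesh_piece` objects (class `mesh_pieces`), each
#'   with `cube_id`, `corner_ids`, `local_vertices`, `local_normals`,
#'   `triangles` (1-based into the piece), `global_ids`.
#' @export
split_mesh <- function(mesh, lattice) {
  if (is.null(lattice$vertex_cube)) stop("lattice has no vertex assignment")
  tr <- mesh$triangles
  nt <- nrow(tr)
  cent <- (mesh$vertices[tr[, 1], , drop = FALSE] +
           mesh$vertices[tr[, 2], , drop = FALSE] +
           mesh$vertices[tr[, 3], , drop = FALSE]) / 3
  # centroid cell at the finest level, half-open rule
  lev <- lattice$max_level
  L <- lattice$root_edge / 2^lev
  side <- 2^lev
  idx <- floor(sweep(cent, 2, lattice$root_origin) / L)
  key <- idx[, 1] + side * (idx[, 2] + side * idx[, 3])
  at <- which(lattice$level == lev)
  ck <- lattice$ijk[at, , drop = FALSE]
  ckey <- ck[, 1] + side * (ck[, 2] + side * ck[, 3])
  tri_cube <- at[match(key, ckey)]
  bad <- is.na(tri_cube) | lattice$region[tri_cube] != "surface"
  tri_cube[bad] <- lattice$vertex_cube[tr[bad, 1]]
  if (any(lattice$region[tri_cube] != "surface"))
    stop("triangle falls in no surface cube")

  pieces <- list()
  for (cid in sort(unique(tri_cube))) {
    tsel <- which(tri_cube == cid)
    gids <- sort(unique(as.integer(tr[tsel, ])))
    lookup <- match(as.integer(tr[tsel, ]), gids)
    ltris <- matrix(lookup, ncol = 3L)
    cube <- list(origin = lattice$origin[cid, ],
                 edge_length = lattice$edge[cid])
    piece <- structure(list(
      cube_id = cid,
      corner_ids = lattice$corners[cid, ],
      local_vertices = local_coordinates(
        mesh$vertices[gids, , drop = FALSE], cube),
      local_normals = mesh$normals[gids, , drop = FALSE],
      triangles = ltris,
      global_ids = gids), class = "mesh_piece")
    pieces[[length(pieces) + 1L]] <- piece
  }
  structure(pieces, class = "mesh_pieces")
}

#' @export
print.mesh_pieces <- function(x, ...) {
  nv <- vapply(x, function(p) nrow(p$local_vertices), integer(1))
  nt <- vapply(x, function(p) nrow(p$triangles), integer(1))
  cat(sprintf("mesh_pieces: %d pieces, %d triangles, %d vertex slots (%d unique)\n",
              length(x), sum(nt), sum(nv),
              length(unique(unlist(lapply(x, `[[`, "global_ids"))))))
  invisible(x)
}

#' Reassemble mapped pieces into a single mesh
#'
#' Inverse of [split_mesh()] for export and comparison: one output vertex
#' per original global id, original triangle connectivity restored.
#' Boundary vertices duplicated into several pieces are averaged; their
#' per-duplicate spread is reported (not hidden) in the `weld_report`
#' attribute, since copies mapped through different cubes agree only
#' where the shared face deforms consistently.
#'
#' @param pieces the `mesh_pieces` from [split_mesh()].
#' @param mapped result of [map_vertices_batched()] on the same pieces.
#' @param mesh the original [surface_mesh()] (connectivity source).
#' @return A [surface_mesh()] with attribute `weld_report`: a data frame
#'   of duplicated global ids, copy counts, and max coordinate spread.
#' @export
weld_pieces <- function(pieces, mapped, mesh) {
  gid <- mapped$global_ids
  nv <- nrow(mesh$vertices)
  if (!all(seq_len(nv) %in% gid)) stop("weld: missing global id")
  counts <- tabulate(gid, nbins = nv)
  pos <- rowsum(mapped$positions, gid) / counts
  nrm <- rowsum(mapped$normals, gid)
  dup <- which(counts > 1L)
  spread <- vapply(dup, function(g) {
    rows <- mapped$positions[gid == g, , drop = FALSE]
    max(apply(rows, 2, function(col) diff(range(col))))
  }, numeric(1))
  out <- surface_mesh(pos, mesh$triangles, normals = nrm)
  attr(out, "weld_report") <- data.frame(global_id = dup,
                                         n_copies = counts[dup],
                                         max_spread = spread)
  out
}
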