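#' Construct a surface mesh
#'
#' A `surface_mesh` is the render-model container used throughout the
#' package: an `n_v x 3` matrix of vertex positions (model units, world
#' frame), an `n_t x 3` integer matrix of 1-based triangle vertex indices,
#' and unit per-vertex normals. Normals are recomputed from the geometry
#' (area-weighted) when not supplied.
#'
#' @param vertices numeric matrix, `n_v x 3`.
#' @param triangles integer matrix, `n_t x 3`, 1-based vertex indices.
#' @param normals optional numeric matrix `n_v x 3`; renormalized on input.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `normals`.
#' @examples
#' m <- make_synthetic_organ("icosphere", 200)
#' m2 <- surface_mesh(m$vertices, m$triangles)
#' @export
surface_mesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as_mat3(vertices, "vertices")
  if (nrow(vertices) == 0L) stop("mesh has no vertices")
  triangles <- matrix(as.integer(as_mat3(triangles, "triangles")), ncol = 3L)
  if (nrow(triangles) > 0L) {
    rng <- range(triangles)
    if (rng[1] < 1L || rng[2] > nrow(vertices))
      stop(sprintf("triangle index %d out of range 1..%d",
                   if (rng[1] < 1L) rng[1] else rng[2], nrow(vertices)))
  }
  if (is.null(normals)) {
    normals <- compute_vertex_normals(vertices, triangles)
  } else {
    normals <- normalize_rows(as_mat3(normals, "normals"))
    if (nrow(normals) != nrow(vertices))
      stop("normals and vertices differ in length")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals),
            class = "surface_mesh")
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (length(x) == 0L) return(matrix(numeric(), 0L, 3L))
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- if (what == "triangles") "integer" else "double"
  dimnames(x) <- NULL
  x
}

normalize_rows <- function(m) {
  len <- sqrt(rowSums(m^2))
  len[len == 0] <- 1
  m / len
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the normalized sum of the (unnormalized) incident
#' triangle cross products; the cross-product magnitude is twice the
#' triangle area, so larger faces weigh more.
#'
#' @param vertices `n_v x 3` matrix.
#' @param triangles `n_t x 3` 1-based index matrix.
#' @return `n_v x 3` matrix of unit normals.
#' @export
compute_vertex_normals <- function(vertices, triangles) {
  n <- matrix(0, nrow(vertices), 3L)
  if (nrow(triangles) == 0L) return(n)
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (k in 1:3) {
    acc <- rowsum(fn, group = triangles[, k], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    n[idx, ] <- n[idx, ] + acc
  }
  normalize_rows(n)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox: [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Each (sorted) edge of a watertight orientable closed mesh is used by
# exactly two triangles.
#' Check that every edge is shared by exactly two triangles
#' @param mesh a `surface_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}
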