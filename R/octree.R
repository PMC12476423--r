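#' Build the hierarchical cube lattice over a surface mesh
#'
#' The root cube is the padded axis-aligned bounding cube of the mesh. It
#' is subdivided recursively: a cell that intersects the mesh surface
#' (exact triangle/box separating-axis test) subdivides until `max_level`;
#' a cell entirely inside the mesh (generalized winding number at its
#' center) stops subdividing and is kept as an *inside* cube at its
#' current level; a cell entirely outside is discarded. All
#' surface-intersecting leaves therefore sit at `max_level`, and coarser
#' cubes are inside cubes. Coincident corners of adjacent cubes share one
#' entry of the corner-particle pool.
#'
#' With `assign = TRUE` (the default) every mesh vertex is then assigned
#' to its containing finest-level cube and cubes are labelled
#' `surface`/`inside` by vertex presence; see [classify_and_assign()].
#'
#' @param mesh a watertight [surface_mesh()].
#' @param max_level finest subdivision level, 0 (root only) to 8; level 0
#'   cubes are the largest.
#' @param root_padding padding of the root cube as a fraction of the
#'   bounding-cube edge, so no vertex sits on the outer boundary.
#' @param assign run [classify_and_assign()] before returning.
#' @return An object of class `octree_lattice`: cube table (`level`,
#'   `origin`, `edge`, `corners`, `intersects`, `region`), the shared
#'   `corner_rest` position pool, root geometry, and (after assignment)
#'   `vertex_cube`, `local_coords` and the surface-cube count `n_c`.
#' @examples
#' m <- make_synthetic_organ("icosphere", 500)
#' lat <- build_octree(m, max_level = 2)
#' lat$n_c
#' @export
build_octree <- function(mesh, max_level = 2L, root_padding = 0.02,
                         assign = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (max_level < 0 || max_level > 8) stop("max_level must be in [0, 8]")
  if (!is_watertight(mesh))
    stop("mesh is not watertight; inside/outside tests need a closed surface")
  V <- mesh$vertices
  F0 <- mesh$triangles - 1L  # 0-based for the compiled kernels
  bb <- apply(V, 2, range)
  ext <- max(bb[2, ] - bb[1, ])
  edge0 <- ext * (1 + 2 * root_padding)
  origin0 <- colMeans(bb) - edge0 / 2

  acc <- new.env(parent = emptyenv())
  acc$level <- integer(); acc$ijk <- list(); acc$intersects <- logical()
  recurse <- function(level, ijk, tri_idx) {
    L <- edge0 / 2^level
    lo <- origin0 + ijk * L
    hit <- if (length(tri_idx))
      tri_idx[tri_box_overlap_cpp(V, F0, tri_idx, lo, L)] else integer()
    if (length(hit)) {
      if (level < max_level) {
        for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
          recurse(level + 1L, 2L * ijk + c(dx, dy, dz), hit)
      } else {
        k <- length(acc$level) + 1L
        acc$level[k] <- level; acc$ijk[[k]] <- ijk; acc$intersects[k] <- TRUE
      }
    } else {
      ctr <- matrix(lo + L / 2, 1L, 3L)
      wn <- winding_number_cpp(ctr, V, F0)
      if (abs(wn) > 0.5) {
        k <- length(acc$level) + 1L
        acc$level[k] <- level; acc$ijk[[k]] <- ijk; acc$intersects[k] <- FALSE
      }
    }
  }
  recurse(0L, c(0L, 0L, 0L), seq_len(nrow(F0)) - 1L)
  if (length(acc$level) == 0L) stop("octree construction retained no cubes")

  level <- acc$level
  ijk <- do.call(rbind, acc$ijk)
  m <- length(level)
  edge <- edge0 / 2^level
  origin <- ijk * edge + rep(origin0, each = m)

  # shared corner pool: integer grid coordinates at max_level resolution
  offsets <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
                   c(0L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 1L))
  scale <- 2L^(max_level - level)
  side <- 2L^max_level + 1L
  corner_keys <- matrix(0, m, 8L)
  for (j in 1:8) {
    ic <- (ijk + rep(offsets[j, ], each = m)) * scale
    corner_keys[, j] <- ic[, 1] + side * (ic[, 2] + side * ic[, 3])
  }
  ukeys <- sort(unique(as.numeric(corner_keys)))
  corners <- matrix(match(as.numeric(corner_keys), ukeys), m, 8L)
  kz <- floor(ukeys / side^2)
  ky <- floor((ukeys - kz * side^2) / side)
  kx <- ukeys - side * (ky + side * kz)
  fine <- edge0 / 2^max_level
  corner_rest <- cbind(kx, ky, kz) * fine + rep(origin0, each = length(ukeys))

  lat <- structure(list(
    level = level, ijk = ijk, origin = origin, edge = edge,
    corners = corners, intersects = acc$intersects,
    region = rep("inside", m),
    corner_rest = corner_rest,
    root_origin = origin0, root_edge = edge0, max_level = as.integer(max_level),
    vertex_cube = NULL, local_coords = NULL, n_c = NA_integer_),
    class = "octree_lattice")
  if (assign) lat <- classify_and_assign(lat, mesh) else lat
}

#' Assign mesh vertices to cubes and label the surface region
#'
#' Every mesh vertex is assigned to the unique finest-level cube whose
#' half-open extent `[origin, origin + L)` contains it (a vertex exactly
#' on a shared face belongs to the cube where that coordinate maps to
#' local 0). Cubes holding at least one vertex are labelled `surface`,
#' all others `inside`; the surface-cube count is `n_c`. Normalized local
#' coordinates `(P - C0) / L` are stored per vertex.
#'
#' @param lattice an `octree_lattice` built over `mesh`.
#' @param mesh the same [surface_mesh()].
#' @return The lattice with `vertex_cube`, `local_coords`, `region` and
#'   `n_c` filled in.
#' @export
classify_and_assign <- function(lattice, mesh) {
  stopifnot(inherits(lattice, "octree_lattice"))
  V <- mesh$vertices
  nv <- nrow(V)
  vertex_cube <- rep(NA_integer_, nv)
  # level-by-level half-open grid lookup, finest first
  for (lev in sort(unique(lattice$level), decreasing = TRUE)) {
    sel <- which(is.na(vertex_cube))
    if (!length(sel)) break
    at <- which(lattice$level == lev)
    L <- lattice$root_edge / 2^lev
    side <- 2^lev
    idx <- floor(sweep(V[sel, , drop = FALSE], 2, lattice$root_origin) / L)
    ok <- rowSums(idx >= 0 & idx <= side - 1) == 3L
    key <- idx[, 1] + side * (idx[, 2] + side * idx[, 3])
    ck <- lattice$ijk[at, , drop = FALSE]
    ckey <- ck[, 1] + side * (ck[, 2] + side * ck[, 3])
    hit <- match(key, ckey)
    hit[!ok] <- NA_integer_
    vertex_cube[sel] <- at[hit]
  }
  if (anyNA(vertex_cube))
    stop(sprintf(paste0("vertex %d falls in no retained cube; ",
                        "increase root_padding"),
                 which(is.na(vertex_cube))[1]))
  lc <- (V - lattice$origin[vertex_cube, , drop = FALSE]) /
    lattice$edge[vertex_cube]
  counts <- tabulate(vertex_cube, nbins = length(lattice$level))
  lattice$region <- ifelse(counts > 0L, "surface", "inside")
  lattice$vertex_cube <- vertex_cube
  lattice$local_coords <- lc
  lattice$n_c <- sum(counts > 0L)
  lattice
}

#' Normalized local coordinates of a point in a cube
#'
#' `(P - C0) / L`, where `C0` is the cube's origin corner and `L` its edge
#' length. Values outside `[0, 1]` are permitted (the trilinear map
#' extrapolates).
#'
#' @param position numeric vector of length 3 or an `n x 3` matrix.
#' @param cube a list with `origin` (length-3) and `edge_length` (> 0),
#'   e.g. from [lattice_cube()].
#' @return Local coordinates, same shape as `position`.
#' @examples
#' local_coordinates(c(3, 1, 0), list(origin = c(2, 0, -1), edge_length = 2))
#' @export
local_coordinates <- function(position, cube) {
  if (cube$edge_length <= 0) stop("cube edge_length must be > 0")
  if (is.matrix(position))
    sweep(position, 2, cube$origin) / cube$edge_length
  else (position - cube$origin) / cube$edge_length
}

#' Extract one cube of a lattice
#' @param lattice an `octree_lattice`.
#' @param id cube index.
#' @return list with `level`, `origin`, `edge_length`, `corner_ids`,
#'   `region`, `intersects_surface`.
#' @export
lattice_cube <- function(lattice, id) {
  stopifnot(id >= 1, id <= length(lattice$level))
  list(level = lattice$level[id],
       origin = lattice$origin[id, ],
       edge_length = lattice$edge[id],
       corner_ids = lattice$corners[id, ],
       region = lattice$region[id],
       intersects_surface = lattice$intersects[id])
}

#' Grid indices of the surface-intersecting finest-level cells
#'
#' The construction-time surface set: all retained `max_level` cells that
#' pass the exact triangle/box overlap test (this can be a superset of the
#' `surface`-labelled cubes, which require an assigned vertex).
#'
#' @param lattice an `octree_lattice`.
#' @return integer matrix of `(i, j, k)` cell indices at `max_level`.
#' @export
surface_cells <- function(lattice) {
  sel <- lattice$intersects & lattice$level == lattice$max_level
  lattice$ijk[sel, , drop = FALSE]
}

#' @export
print.octree_lattice <- function(x, ...) {
  cat(sprintf("octree_lattice: %d cubes, %d shared corners, root edge %.4g\n",
              length(x$level), nrow(x$corner_rest), x$root_edge))
  for (lev in sort(unique(x$level))) {
    n <- sum(x$level == lev)
    ns <- sum(x$level == lev & x$region == "surface")
    if (ns > 0)
      cat(sprintf("  Cube level %d: %d (%d)\n", lev, n, ns))
    else
      cat(sprintf("  Cube level %d: %d\n", lev, n))
  }
  if (!is.na(x$n_c))
    cat(sprintf("  Total: %d (%d)   [n_c = surface cubes, in parentheses]\n",
                length(x$level), x$n_c))
  invisible(x)
}

#' Serialize a lattice to JSON
#' @param lattice an `octree_lattice`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  doc <- lattice
  class(doc) <- NULL
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a lattice written by [write_lattice()]
#' @param path JSON file.
#' @return An `octree_lattice`.
#' @export
read_lattice <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lat <- list(
    level = as.integer(doc$level),
    ijk = matrix(as.integer(doc$ijk), ncol = 3L),
    origin = matrix(as.numeric(doc$origin), ncol = 3L),
    edge = as.numeric(doc$edge),
    corners = matrix(as.integer(doc$corners), ncol = 8L),
    intersects = as.logical(doc$intersects),
    region = as.character(doc$region),
    corner_rest = matrix(as.numeric(doc$corner_rest), ncol = 3L),
    root_origin = as.numeric(doc$root_origin),
    root_edge = as.numeric(doc$root_edge),
    max_level = as.integer(doc$max_level),
    vertex_cube = if (length(doc$vertex_cube)) as.integer(doc$vertex_cube),
    local_coords = if (length(doc$local_coords))
      matrix(as.numeric(doc$local_coords), ncol = 3L),
    n_c = as.integer(doc$n_c %||% NA_integer_))
  class(lat) <- "octree_lattice"
  lat
}
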