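#' Generate a synthetic organ-like surface mesh
#'
#' Stands in for CT-derived organ surfaces when exercising the pipeline at
#' controlled resolutions. Three kinds are available:
#' \describe{
#'   \item{`icosphere`}{unit geodesic sphere (icosahedron subdivided at
#'     frequency `f`, giving `10 f^2 + 2` vertices).}
#'   \item{`ellipsoid`}{icosphere scaled by semi-axes `(1, 0.65, 0.45)`,
#'     roughly the aspect of a liver-like solid.}
#'   \item{`blob`}{icosphere with a smooth pseudo-random radial bump field
#'     (a seeded sum of Gaussian lobes on the sphere), deterministic in
#'     `seed`.}
#' }
#' The subdivision frequency is chosen so the vertex count is as close as
#' possible to `target_vertices` (always within 20% for targets >= 12).
#' All outputs are watertight with outward normals and no degenerate
#' triangles.
#'
#' @param kind `"icosphere"`, `"ellipsoid"` or `"blob"`.
#' @param target_vertices requested vertex count (>= 12).
#' @param seed integer seed for the blob bump field (ignored otherwise).
#' @param bump_amplitude blob radial perturbation as a fraction of the
#'   radius; keep below 1 so the surface stays star-shaped.
#' @return A [surface_mesh()].
#' @examples
#' b <- make_synthetic_organ("blob", 2000, seed = 1, bump_amplitude = 0.15)
#' nrow(b$vertices)
#' @export
make_synthetic_organ <- function(kind = c("icosphere", "ellipsoid", "blob"),
                                 target_vertices, seed = 1L,
                                 bump_amplitude = 0.15) {
  kind <- match.arg(kind)
  if (target_vertices < 12) stop("target_vertices must be >= 12")
  f <- max(1L, as.integer(round(sqrt((target_vertices - 2) / 10))))
  # nearest of f-1, f, f+1 in vertex count
  cand <- unique(pmax(1L, f + (-1L:1L)))
  f <- cand[which.min(abs(10 * cand^2 + 2 - target_vertices))]
  mesh <- icosphere(f)
  if (kind == "ellipsoid") {
    v <- mesh$vertices %*% diag(c(1, 0.65, 0.45))
    mesh <- surface_mesh(v, mesh$triangles)
  } else if (kind == "blob") {
    u <- mesh$vertices  # unit directions
    field <- blob_field(u, seed)
    r <- 1 + bump_amplitude * field
    mesh <- surface_mesh(u * r, mesh$triangles)
  }
  mesh
}

# Smooth bump field on the unit sphere: K Gaussian lobes with seeded
# directions/widths/signs, rescaled to max |field| = 1. Uses a private RNG
# stream so the caller's .Random.seed is untouched.
blob_field <- function(u, seed, lobes = 8L) {
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  d <- normalize_rows(matrix(rnorm(3 * lobes), lobes, 3))
  amp <- runif(lobes, -1, 1)
  width <- runif(lobes, 0.3, 0.8)
  field <- rep(0, nrow(u))
  for (k in seq_len(lobes))
    field <- field + amp[k] * exp(-(1 - u %*% d[k, ]) / width[k]^2)
  m <- max(abs(field))
  if (m > 0) field <- field / m
  as.numeric(field)
}

# Geodesic icosphere at frequency f: each icosahedron face is divided into
# f^2 triangles on a barycentric grid, grid points projected to the unit
# sphere, shared edge/corner points welded exactly by grid key.
icosphere <- function(f = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward winding on the base solid
  for (i in seq_len(nrow(faces))) {
    a <- v[faces[i, 1], ]; b <- v[faces[i, 2], ]; c_ <- v[faces[i, 3], ]
    n <- cross3(b - a, c_ - a)
    if (sum(n * (a + b + c_)) < 0) faces[i, ] <- faces[i, c(1, 3, 2)]
  }
  if (f == 1L) return(surface_mesh(v, faces))

  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(); nvert <- 0L
  # canonical key for a barycentric grid point: corner ids weighted by
  # integer coordinates, order-independent
  point_id <- function(ids, w, pos) {
    o <- order(ids, -w)
    key <- paste(ids[o], w[o], sep = ":", collapse = "|")
    hit <- key_env[[key]]
    if (!is.null(hit)) return(hit)
    nvert <<- nvert + 1L
    verts[[nvert]] <<- pos
    key_env[[key]] <- nvert
    nvert
  }
  tris <- vector("list", nrow(faces))
  for (fi in seq_len(nrow(faces))) {
    ids3 <- faces[fi, ]
    A <- v[ids3[1], ]; B <- v[ids3[2], ]; C <- v[ids3[3], ]
    grid <- matrix(0L, f + 1L, f + 1L)
    for (i in 0:f) for (j in 0:(f - i)) {
      w <- c(f - i - j, i, j)
      pos <- (w[1] * A + w[2] * B + w[3] * C) / f
      pos <- pos / sqrt(sum(pos^2))
      keep <- w > 0L
      grid[i + 1L, j + 1L] <- point_id(ids3[keep], w[keep], pos)
    }
    tt <- vector("list", f * f)
    n <- 0L
    for (i in 0:(f - 1L)) for (j in 0:(f - 1L - i)) {
      n <- n + 1L
      tt[[n]] <- c(grid[i + 1L, j + 1L], grid[i + 2L, j + 1L], grid[i + 1L, j + 2L])
      if (j < f - 1L - i) {
        n <- n + 1L
        tt[[n]] <- c(grid[i + 2L, j + 1L], grid[i + 2L, j + 2L], grid[i + 1L, j + 2L])
      }
    }
    tris[[fi]] <- do.call(rbind, tt[seq_len(n)])
  }
  surface_mesh(do.call(rbind, verts), do.call(rbind, tris))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
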