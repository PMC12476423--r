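identity_cage <- function() {
  m <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * 1.0
  dimnames(m) <- NULL
  m
}

test_that("the cascaded-lerp form equals the trilinear weight sum", {
  set.seed(21)
  for (rep in 1:100) {
    cage <- identity_cage() + matrix(rnorm(24, sd = 0.4), 8)
    local <- runif(3, -0.3, 1.3)
    direct <- trilinear_point(local, cage)
    oracle <- as.numeric(trilinear_weights(matrix(local, 1)) %*% cage)
    expect_lt(max(abs(direct - oracle)), 1e-12)
  }
  expect_equal(rowSums(trilinear_weights(matrix(runif(30), 10))),
               rep(1, 10), tolerance = 1e-12)
})

test_that("corner and identity-cage evaluations are exact", {
  cage <- identity_cage()
  for (j in 1:8)
    expect_equal(trilinear_point(cage[j, ], cage + 0), cage[j, ])
  set.seed(3)
  for (rep in 1:20) {
    local <- runif(3)
    expect_equal(trilinear_point(local, cage), local, tolerance = 1e-15)
  }
  # displacing only C'_7 moves the center by the corner-7 weight 0.125
  cage7 <- cage
  cage7[8, ] <- cage7[8, ] + c(1, 1, 1)
  expect_equal(trilinear_point(c(0.5, 0.5, 0.5), cage7),
               c(0.625, 0.625, 0.625))
  expect_error(trilinear_point(c(NA, 0, 0), cage), "finite")
})

test_that("affine cages reproduce the affine map", {
  set.seed(5)
  M <- matrix(rnorm(9), 3) + diag(3)
  t0 <- c(0.5, -1, 2)
  cage <- identity_cage() %*% t(M) + rep(t0, each = 8)
  for (rep in 1:50) {
    local <- runif(3, -0.5, 1.5)
    expect_lt(max(abs(trilinear_point(local, cage) -
                        (as.numeric(M %*% local) + t0))), 1e-9)
  }
})

deformed_setup <- function(n = 800, frames = 5, max_level = 2) {
  m <- make_synthetic_organ("blob", n, seed = 9)
  lat <- build_octree(m, max_level)
  pieces <- split_mesh(m, lat)
  cfg <- simulation_config(tray = list(point = c(0, -1.3, 0),
                                       normal = c(0, 1, 0)))
  st <- simulate_frames(lat, lattice_state(lat), cfg, frames)
  list(mesh = m, lat = lat, pieces = pieces, state = st)
}

test_that("undeformed and rigidly moved lattices map vertices exactly", {
  s <- deformed_setup(frames = 0)
  st <- lattice_state(s$lat)
  mapped <- map_vertices_reference(s$lat, st, s$mesh)
  expect_lt(max(abs(mapped$positions - s$mesh$vertices)), 1e-9)
  expect_lt(max(abs(mapped$normals - s$mesh$normals)), 1e-9)
  # translation
  st_t <- st; st_t$positions <- st$positions + rep(c(1, 2, 3), each = nrow(st$positions))
  mt <- map_vertices_reference(s$lat, st_t, s$mesh)
  expect_lt(max(abs(mt$positions - (s$mesh$vertices +
                                      rep(c(1, 2, 3), each = nrow(s$mesh$vertices))))), 1e-9)
  # rotation about the origin
  R0 <- rotation_about_z(0.7)
  st_r <- st; st_r$positions <- st$positions %*% t(R0)
  mr <- map_vertices_reference(s$lat, st_r, s$mesh)
  expect_lt(max(abs(mr$positions - s$mesh$vertices %*% t(R0))), 1e-9)
  expect_lt(max(abs(mr$normals - s$mesh$normals %*% t(R0))), 1e-9)
})

test_that("batched and per-vertex mapping agree on deformed states", {
  s <- deformed_setup()
  for (mode in c("jacobian", "trilinear")) {
    mb <- map_vertices_batched(s$pieces, s$state, mode)
    mr <- map_pieces_reference(s$pieces, s$state, mode)
    expect_identical(mb$global_ids, mr$global_ids)
    expect_lt(max(abs(mb$positions - mr$positions)), 1e-6)
    expect_lt(max(abs(mb$normals - mr$normals)), 1e-6)
    expect_lt(max(abs(sqrt(rowSums(mb$normals^2)) - 1)), 1e-9)
    # the whole-mesh per-vertex path agrees wherever the piece's cube is
    # the vertex's own assigned cube (elsewhere the difference is the
    # cross-cube crack, reported by the weld step)
    mw <- map_vertices_reference(s$lat, s$state, s$mesh, mode)
    piece_cube <- vapply(s$pieces, `[[`, integer(1), "cube_id")[mr$piece_id]
    same_cube <- piece_cube == s$lat$vertex_cube[mb$global_ids]
    expect_lt(max(abs(mb$positions[same_cube, ] -
                        mw$positions[mb$global_ids[same_cube], ])), 1e-9)
  }
})

test_that("perturbing one cube moves only the vertices it owns", {
  s <- deformed_setup(frames = 0)
  st <- lattice_state(s$lat)
  base <- map_vertices_reference(s$lat, st, s$mesh)
  cid <- s$pieces[[1]]$cube_id
  ids <- s$lat$corners[cid, ]
  # corners of this cube not shared with any other surface cube
  others <- unique(as.integer(s$lat$corners[-cid, ]))
  private <- setdiff(ids, others)
  skip_if(length(private) == 0)
  st$positions[private, ] <- st$positions[private, , drop = FALSE] + 0.05
  moved <- map_vertices_reference(s$lat, st, s$mesh)
  delta <- rowSums(abs(moved$positions - base$positions))
  owners <- s$lat$vertex_cube == cid
  expect_true(all(delta[!owners] == 0))
})

test_that("mapping refuses vertices assigned to inside cubes", {
  s <- deformed_setup(frames = 0)
  lat_bad <- s$lat
  lat_bad$region[lat_bad$vertex_cube[1]] <- "inside"
  expect_error(map_vertices_reference(lat_bad, lattice_state(s$lat), s$mesh),
               "inside cube")
})
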