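#' Simulation configuration
#'
#' Parameters of the position-based-dynamics frame loop. Defaults follow
#' the 30 fps framing of an interactive simulator: `dt = 1/30` s, 30
#' Gauss-Seidel iterations of the constraint solver per frame, stiffness
#' 0.9, gravity `(0, -9.8, 0)` model-units/s^2, and a horizontal tray
#' plane the organ falls onto.
#'
#' @param dt frame time step in seconds.
#' @param solver_iterations constraint sweeps per frame (>= 1).
#' @param gravity length-3 acceleration vector.
#' @param stiffness shape-matching stiffness in (0, 1].
#' @param tray `NULL` for no collision plane, or a list with `point`
#'   (length 3) and `normal` (length 3, normalized on input). The default
#'   plane sits at `y = -2` so a unit-scale organ at the origin falls
#'   before touching it; a plane intersecting the rest shape at frame 0
#'   makes the first projection violent.
#' @param seed integer seed recorded for provenance (the solver itself is
#'   deterministic).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 1 / 30, solver_iterations = 30L,
                              gravity = c(0, -9.8, 0), stiffness = 0.9,
                              tray = list(point = c(0, -2, 0),
                                          normal = c(0, 1, 0)),
                              seed = 1L) {
  stopifnot(dt > 0, solver_iterations >= 1,
            stiffness > 0, stiffness <= 1, length(gravity) == 3)
  if (!is.null(tray)) {
    stopifnot(length(tray$point) == 3, length(tray$normal) == 3)
    nl <- sqrt(sum(tray$normal^2))
    if (nl == 0) stop("tray normal must be nonzero")
    tray$normal <- tray$normal / nl
  }
  structure(list(dt = dt, solver_iterations = as.integer(solver_iterations),
                 gravity = as.numeric(gravity), stiffness = stiffness,
                 tray = tray, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Initial dynamic state of the lattice corner particles
#'
#' @param lattice an `octree_lattice`.
#' @param velocities optional `n x 3` initial velocities (default zero).
#' @param inverse_masses optional non-negative per-corner inverse masses;
#'   0 pins a corner. Default: unit mass everywhere.
#' @return A `lattice_state` with `positions`, `velocities`,
#'   `inverse_masses`.
#' @export
lattice_state <- function(lattice, velocities = NULL, inverse_masses = NULL) {
  n <- nrow(lattice$corner_rest)
  velocities <- velocities %||% matrix(0, n, 3L)
  inverse_masses <- inverse_masses %||% rep(1, n)
  stopifnot(nrow(velocities) == n, length(inverse_masses) == n,
            all(inverse_masses >= 0))
  structure(list(positions = lattice$corner_rest,
                 velocities = as_mat3(velocities, "velocities"),
                 inverse_masses = as.numeric(inverse_masses)),
            class = "lattice_state")
}

# centered rest offsets of every cube, stacked 8 rows per cube
rest_offsets <- function(lattice) {
  off <- lattice$corner_rest[t(lattice$corners), , drop = FALSE]
  m <- nrow(lattice$corners)
  cen <- rowsum(off, rep(seq_len(m), each = 8L)) / 8
  off - cen[rep(seq_len(m), each = 8L), , drop = FALSE]
}

#' Explicit prediction step
#'
#' Integrates gravity into the velocities of unpinned corners and forms
#' candidate positions `predicted = positions + dt * velocities`. The
#' constraint projections then act on `predicted`.
#'
#' @param state a `lattice_state`.
#' @param config a [simulation_config()].
#' @return The state with a `predicted` matrix added.
#' @export
predict_state <- function(state, config) {
  free <- state$inverse_masses > 0
  v <- state$velocities
  v[free, ] <- v[free, , drop = FALSE] +
    rep(config$dt * config$gravity, each = sum(free))
  p <- state$positions
  p[free, ] <- p[free, , drop = FALSE] + config$dt * v[free, , drop = FALSE]
  state$velocities <- v
  state$predicted <- p
  state
}

#' Best-fit rotation between two centered point sets
#'
#' Returns the rotation factor of the polar decomposition of the
#' covariance `A = sum(current_i %o% rest_i)`, reflection-corrected to
#' det +1. If the covariance is rank-deficient (corners collinear or
#' coincident) the identity is returned with `degenerate = TRUE`.
#'
#' @param current `k x 3` matrix of centered current positions.
#' @param rest `k x 3` matrix of centered rest positions.
#' @return list with `R` (3x3 rotation) and `degenerate` (logical).
#' @examples
#' q <- as.matrix(expand.grid(0:1, 0:1, 0:1)) - 0.5
#' extract_rotation(q, q)$R  # identity
#' @export
extract_rotation <- function(current, rest) {
  stopifnot(nrow(current) == nrow(rest), ncol(current) == 3, ncol(rest) == 3)
  if (max(abs(colSums(current))) > 1e-9 * max(1, max(abs(current))) ||
      max(abs(colSums(rest))) > 1e-9 * max(1, max(abs(rest))))
    stop("point sets must be centered")
  A <- crossprod(current, rest)  # t(current) %*% rest = sum current_i rest_i^T
  out <- polar_rotation_cpp(A)
  list(R = out$R, degenerate = out$degenerate)
}

#' Project one cube's shape-matching constraint
#'
#' Pulls the cube's predicted corners toward the best-fit rigid transform
#' of its rest shape: with centroid `c` of the predicted corners and
#' rotation `R` from [extract_rotation()], each unpinned corner moves
#' `stiffness * (R q_i + c - p_i)`.
#'
#' @param lattice an `octree_lattice`.
#' @param cube_id index of the cube to project.
#' @param state a `lattice_state` carrying a `predicted` matrix (see
#'   [predict_state()]).
#' @param stiffness constraint stiffness in (0, 1].
#' @return The state with updated `predicted`.
#' @export
project_shape_matching <- function(lattice, cube_id, state, stiffness = 1) {
  ids <- lattice$corners[cube_id, ]
  p <- state$predicted[ids, , drop = FALSE]
  cen <- colMeans(p)
  q <- lattice$corner_rest[ids, , drop = FALSE]
  q <- sweep(q, 2, colMeans(q))
  rot <- extract_rotation(sweep(p, 2, cen), q)
  goal <- q %*% t(rot$R) + rep(cen, each = 8L)
  free <- state$inverse_masses[ids] > 0
  p[free, ] <- p[free, , drop = FALSE] +
    stiffness * (goal[free, , drop = FALSE] - p[free, , drop = FALSE])
  state$predicted[ids, ] <- p
  state
}

#' Project predicted corners out of the tray plane
#'
#' Any unpinned predicted corner with negative signed distance to the
#' tray plane is moved to the plane surface along the normal.
#'
#' @param state a `lattice_state` with `predicted`.
#' @param config a [simulation_config()] with a non-`NULL` tray.
#' @return The state with updated `predicted`.
#' @export
project_tray_collision <- function(state, config) {
  if (is.null(config$tray)) return(state)
  n <- config$tray$normal
  d <- as.numeric(sweep(state$predicted, 2, config$tray$point) %*% n)
  fix <- which(d < 0 & state$inverse_masses > 0)
  if (length(fix))
    state$predicted[fix, ] <- state$predicted[fix, , drop = FALSE] -
      d[fix] %o% n
  state
}

#' Advance the lattice one frame
#'
#' One PBD frame: predict under gravity, then `solver_iterations`
#' Gauss-Seidel sweeps over all cube shape-matching constraints in
#' ascending cube-id order, each sweep followed by the tray-collision
#' projection; finally `velocities = (predicted - positions) / dt` and
#' `positions = predicted`. Runs in compiled code; the trajectory is
#' deterministic for a given lattice and configuration.
#'
#' @param lattice an `octree_lattice`.
#' @param state a `lattice_state`.
#' @param config a [simulation_config()].
#' @return The updated `lattice_state`.
#' @export
pbd_step <- function(lattice, state, config) {
  bad <- which(!is.finite(rowSums(state$positions) +
                            rowSums(state$velocities)))
  if (length(bad))
    stop(sprintf("numerical divergence: corner %d is non-finite", bad[1]))
  tray <- config$tray
  out <- pbd_step_cpp(state$positions, state$velocities,
                      state$inverse_masses,
                      lattice$corners - 1L, rest_offsets(lattice),
                      config$stiffness, config$dt, config$solver_iterations,
                      config$gravity,
                      !is.null(tray),
                      if (is.null(tray)) c(0, 0, 0) else tray$point,
                      if (is.null(tray)) c(0, 1, 0) else tray$normal)
  state$positions <- out$positions
  state$velocities <- out$velocities
  state$predicted <- NULL
  state
}

#' Run several frames, optionally recording the trajectory
#'
#' @param lattice an `octree_lattice`.
#' @param state initial `lattice_state`.
#' @param config a [simulation_config()].
#' @param frames number of frames to advance.
#' @param record keep every frame's corner positions.
#' @return The final state; with `record = TRUE` the list of per-frame
#'   position matrices is attached as attribute `"trajectory"`.
#' @export
simulate_frames <- function(lattice, state, config, frames, record = FALSE) {
  traj <- if (record) vector("list", frames)
  for (f in seq_len(frames)) {
    state <- pbd_step(lattice, state, config)
    if (record) traj[[f]] <- state$positions
  }
  if (record) attr(state, "trajectory") <- traj
  state
}

#' Kinetic energy of the corner particles
#' @param state a `lattice_state`.
#' @return Scalar `sum(m v^2) / 2` over unpinned corners (unit masses
#'   assumed where `inverse_mass > 0`).
#' @export
kinetic_energy <- function(state) {
  free <- state$inverse_masses > 0
  sum(0.5 / state$inverse_masses[free] *
        rowSums(state$velocities[free, , drop = FALSE]^2))
}
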