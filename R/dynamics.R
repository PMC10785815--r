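#' Integrator parameters for overdamped Brownian dynamics
#'
#' Position-Langevin update `x <- x + (dt/gamma) F + sqrt(2 kBT dt/gamma) xi`
#' with per-species Stokes-like friction (gamma proportional to bead radius)
#' and kBT = 1 in reduced units.  Only configurational statistics are
#' analysed, so no velocities are carried.
#'
#' @param dt time step in reduced time tau.
#' @param n_steps number of steps.
#' @param frame_stride steps between stored frames.
#' @param seed integer seed for the thermal noise.
#' @param temperature_K nominal temperature (conversions only; the dynamics
#'   run at kBT = 1).
#' @param skin Verlet-list skin (nm); the list is rebuilt when any bead has
#'   drifted more than skin/2.
#' @param max_step_disp instability guard: a single-step displacement above
#'   this (nm) aborts with an error.
#' @param clamp_disp displacement cap (nm): steps larger than this are
#'   rescaled to this length before the guard is applied, stabilising rare
#'   steep WCA contacts; set to 0 to disable clamping (pure Euler-Maruyama).
#' @return an `integrator_params` list.
#' @export
integrator_params <- function(dt = 0.005, n_steps, frame_stride = 1000L,
                              seed = 1L, temperature_K = 298,
                              skin = 2.0, max_step_disp = 1.0,
                              clamp_disp = 0.5) {
  stopifnot(dt > 0, n_steps >= 0, frame_stride >= 1, skin >= 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 frame_stride = as.integer(frame_stride),
                 seed = as.integer(seed), temperature_K = temperature_K,
                 skin = skin, max_step_disp = max_step_disp,
                 clamp_disp = clamp_disp),
            class = "integrator_params")
}

#' Run a Brownian-dynamics trajectory
#'
#' Integrates all mobile beads of the topology; fixed (core) beads never
#' move.  Identical `(topology, params, seed)` give bit-identical
#' trajectories (single-threaded contract).
#'
#' @param topo a `cg_topology`.
#' @param ff a `forcefield_params`.
#' @param ip an `integrator_params`.
#' @return a `cg_trajectory`: `frames` (N x 3 x n_frames array of positions,
#'   nm), `times` (tau), plus the topology, parameters and seed for
#'   provenance.
#' @export
run_bd <- function(topo, ff, ip) {
  stopifnot(inherits(topo, "cg_topology"), inherits(ff, "forcefield_params"),
            inherits(ip, "integrator_params"))
  a <- topo_arrays(topo)
  res <- cpp_run_bd(a$pos, a$species, a$charge, a$radius, a$fixed, a$gamma,
                    a$bonds, a$bond_r0, a$bond_k,
                    a$angles, a$ang_t0, a$ang_kap,
                    ff_to_cpp(ff), box_to_cpp(topo$box),
                    ip$dt, ip$n_steps, ip$frame_stride, ip$seed,
                    ip$skin, ip$max_step_disp, ip$clamp_disp)
  structure(list(frames = res$frames, times = res$times,
                 n_rebuilds = res$n_rebuilds, n_clamped = res$n_clamped,
                 topology = topo, forcefield = ff, integrator = ip,
                 seed = ip$seed),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cg_trajectory> %d beads, %d frames, t = 0..%.1f tau (seed %d)\n",
              d[1], d[3], max(x$times), x$seed))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Positions of one frame
#' @param traj a `cg_trajectory`.
#' @param frame 1-based frame index.
#' @return N x 3 matrix (nm).
#' @export
frame_positions <- function(traj, frame) {
  matrix(traj$frames[, , frame], ncol = 3)
}

#' Indices of frames in the analysis window
#'
#' The default window is the last half of the trajectory: condensation is
#' still slowly accumulating, so the window is reported with results rather
#' than assumed converged.
#'
#' @param traj a `cg_trajectory`.
#' @param fraction fraction of the trajectory to keep, from the end.
#' @return integer frame indices.
#' @export
analysis_window <- function(traj, fraction = 0.5) {
  nf <- n_frames(traj)
  keep <- max(1L, floor(nf * fraction))
  seq.int(nf - keep + 1L, nf)
}
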