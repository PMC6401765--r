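# Shared helpers: independent numerical oracles and small builders.

# central finite-difference gradient of the total energy; independent check
# of the analytic forces
numeric_gradient <- function(state, ff = forcefield_params(), h = 1e-5) {
  N <- nrow(state$positions)
  g <- matrix(NA_real_, N, 3)
  for (i in seq_len(N)) {
    for (d in 1:3) {
      sp <- state
      sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- state
      sm$positions[i, d] <- sm$positions[i, d] - h
      g[i, d] <- (total_energy_and_forces(sp, ff)$energy -
                    total_energy_and_forces(sm, ff)$energy) / (2 * h)
    }
  }
  g
}

# Boltzmann average of cos(turn angle) for the discrete WLC bending energy
# b*kT*(1 + cos theta), computed by numerical quadrature (independent of the
# closed form used in the package)
quadrature_cos_turn <- function(b) {
  num <- stats::integrate(function(t) t * exp(b * t), -1, 1,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(t) exp(b * t), -1, 1,
                          rel.tol = 1e-12)$value
  num / den
}

# wrap a bare position matrix (or N x 3 x nf array) as a trajectory
as_test_traj <- function(pos, topology = NULL, array = NULL) {
  positions <- if (length(dim(pos)) == 3L) pos else
    array(pos, dim = c(nrow(pos), 3L, 1L))
  tr <- list(positions = positions,
             times = seq_len(dim(positions)[3L]) - 1,
             topology = topology, array = array)
  class(tr) <- "trajectory"
  tr
}

# a simulation_state without going through initial_conformation
as_test_state <- function(pos, topology, array = NULL) {
  st <- list(positions = pos, velocities = matrix(0, nrow(pos), 3),
             topology = topology, array = array, time = 0)
  class(st) <- "simulation_state"
  st
}

# drop all but the selected frames
traj_frames <- function(traj, sel) {
  traj$positions <- traj$positions[, , sel, drop = FALSE]
  traj$times <- traj$times[sel]
  traj
}
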