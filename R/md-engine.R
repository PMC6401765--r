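#' Integrator / thermostat configuration
#'
#' NVT leap-frog settings in reduced units (`tau = sigma*sqrt(m/epsilon)`).
#' The Langevin thermostat is the default (ergodic for a single chain); the
#' Nose-Hoover chain thermostat with relaxation time 0.1 tau mirrors the
#' reference protocol of nanopost-array studies. Equilibrium averages are
#' thermostat- and friction-independent (a tested property). Defaults are
#' desk-scale; production-scale step counts are accepted but long-running.
#'
#' @param dt time step (tau); default 0.005
#' @param T temperature (epsilon/kB); default 1
#' @param thermostat `"langevin"`, `"nose_hoover"` or `"none"` (NVE)
#' @param gamma Langevin friction (m/tau); default 1
#' @param tau_T Nose-Hoover relaxation time (tau); default 0.1
#' @param n_equil,n_prod equilibration (discarded) and production step counts
#' @param sample_interval steps between stored frames
#' @param seed RNG seed applied at the start of [integrate_chain()];
#'   `NULL` leaves the R RNG state untouched
#' @param replicas number of independent replicas for [run_experiment()]
#' @return an object of class `integrator_config`
#' @export
integrator_config <- function(dt = 0.005, T = 1,
                              thermostat = c("langevin", "nose_hoover", "none"),
                              gamma = 1, tau_T = 0.1,
                              n_equil = 10000L, n_prod = 100000L,
                              sample_interval = 1000L, seed = NULL,
                              replicas = 3L) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, T > 0, sample_interval >= 1, n_equil >= 0, n_prod >= 0,
            gamma > 0, tau_T > 0, replicas >= 1)
  obj <- list(dt = dt, T = T, thermostat = thermostat, gamma = gamma,
              tau_T = tau_T, n_equil = as.integer(n_equil),
              n_prod = as.integer(n_prod),
              sample_interval = as.integer(sample_interval),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              replicas = as.integer(replicas))
  class(obj) <- "integrator_config"
  obj
}

#' Propagate a chain with the leap-frog algorithm in the NVT ensemble
#'
#' Runs `n_equil` discarded steps followed by `n_prod` production steps,
#' storing every `sample_interval`-th frame. Velocities follow the
#' half-step leap-frog convention; sampled kinetic energies use on-step
#' interpolated velocities. A bond reaching `R_o` or a bead penetrating a
#' post aborts the run with the offending step reported (no clamping).
#' Given `cfg$seed`, runs are bit-reproducible on the same platform.
#'
#' @param state a `simulation_state` (see [initial_conformation()])
#' @param ff a [forcefield_params()]
#' @param cfg an [integrator_config()]
#' @return an object of class `trajectory`: `positions` (`N x 3 x n_frames`),
#'   `times`, `pe`, `ke`, `topology`, `array`, `config`, `final_state`
#' @examples
#' top <- chain_topology(10, "flexible")
#' st <- initial_conformation(top, velocities = "zero")
#' tr <- integrate_chain(st, cfg = integrator_config(
#'   n_equil = 100, n_prod = 400, sample_interval = 100, seed = 1))
#' n_frames(tr)
#' @export
integrate_chain <- function(state, ff = forcefield_params(),
                            cfg = integrator_config()) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(cfg, "integrator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  arr <- state$array
  code <- match(cfg$thermostat, c("none", "langevin", "nose_hoover")) - 1L
  res <- md_run_cpp(state$positions, state$velocities,
                    state$topology$angle_b * cfg$T,
                    ff$kappa, ff$R_o, ff$pair_wca,
                    !is.null(arr),
                    if (is.null(arr)) 0 else arr$S_p,
                    if (is.null(arr)) 0 else arr$D_p,
                    cfg$dt, cfg$T, code, cfg$gamma, cfg$tau_T,
                    state$time, cfg$n_equil, cfg$n_prod,
                    cfg$sample_interval, TRUE)
  nf <- res$n_frames
  pos <- res$frames
  if (nf > 0) {
    # stored as 3 x N x nf; expose as N x 3 x nf
    pos <- aperm(array(pos, dim = c(3, state$topology$N, nf)), c(2, 1, 3))
    dimnames(pos) <- list(NULL, c("x", "y", "z"), NULL)
  } else {
    pos <- array(numeric(0), dim = c(state$topology$N, 3, 0))
  }
  final <- state
  final$positions <- res$pos
  final$velocities <- res$vel
  final$time <- res$time
  traj <- list(positions = pos, times = res$times, pe = res$pe, ke = res$ke,
               topology = state$topology, array = state$array,
               config = cfg, final_state = final)
  class(traj) <- "trajectory"
  traj
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' Extract one frame's positions
#' @param traj a `trajectory`
#' @param k frame index
#' @return an `N x 3` position matrix
#' @export
get_frame <- function(traj, k) traj$positions[, , k]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: N = %d beads, %d frames, t in [%g, %g] tau\n",
              x$topology$N, n_frames(x),
              if (n_frames(x)) min(x$times) else NA,
              if (n_frames(x)) max(x$times) else NA))
  invisible(x)
}

#' Run a full experiment (replicas x orientation) from a configuration
#'
#' Builds the topology, array and initial conformation from a configuration
#' list (see [default_config()] / [read_config()]), runs `replicas`
#' independent simulations, and optionally writes extended-XYZ trajectories
#' plus a JSON manifest recording every seed. Replicas differ only by their
#' seeds, derived from the master seed as `seed + 7919 * (replica - 1)`
#' (recorded in the manifest), so runs are reproducible bit-for-bit.
#'
#' @param config a configuration list or a path to a JSON config file
#' @param out_dir directory for trajectories + manifest, or `NULL` to skip
#'   writing
#' @return invisibly, a list with `trajectories` (one per replica) and
#'   `manifest`
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  array <- if (is.null(config$d_p) && is.null(config$D_p)) NULL else
    nanopost_array(config$S_p, D_p = config$D_p, d_p = config$d_p,
                   n_y = config$n_y, n_z = config$n_z)
  top <- chain_topology(config$N, config$blocks, config$b)
  seeds <- as.integer((config$seed + 7919 * (seq_len(config$replicas) - 1)) %%
                        .Machine$integer.max)
  cfg0 <- integrator_config(dt = config$dt, T = config$T,
                            thermostat = config$thermostat,
                            gamma = if (config$thermostat == "langevin")
                              config$gamma_or_tau else 1,
                            tau_T = if (config$thermostat == "nose_hoover")
                              config$gamma_or_tau else 0.1,
                            n_equil = config$n_equil, n_prod = config$n_prod,
                            sample_interval = config$sample_interval,
                            replicas = config$replicas)
  trajs <- vector("list", config$replicas)
  paths <- character(config$replicas)
  for (r in seq_len(config$replicas)) {
    cfg <- cfg0
    cfg$seed <- seeds[r]
    set.seed(seeds[r])
    st <- initial_conformation(top, array, orientation = config$orientation,
                               velocities = "maxwell", T = config$T)
    trajs[[r]] <- integrate_chain(st, forcefield_params(), cfg)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      paths[r] <- file.path(out_dir, sprintf("replica-%02d.xyz", r))
      write_xyz(trajs[[r]], paths[r])
    }
  }
  manifest <- list(config = config, seeds = seeds,
                   package_version = as.character(utils::packageVersion("nanopost")),
                   trajectories = if (is.null(out_dir)) character(0) else paths)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trajectories = trajs, manifest = manifest))
}
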