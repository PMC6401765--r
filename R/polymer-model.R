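#' Linear bead-spring chain topology
#'
#' Builds the topology of a linear touching-bead chain: `N` beads, `N - 1`
#' FENE bonds and `N - 2` valence angles. Stiffness enters through the
#' dimensionless wormlike-chain parameter `b = B/(l*kB*T)`; flexible angles
#' have `b = 0`, semi-flexible angles `b = b_stiff` (default 20, the
#' conventional value mapping a touching-bead chain onto double-stranded
#' DNA at high ionic strength).
#'
#' For `kind = "diblock"` the chain splits at `N/2`: beads `1..N/2` form the
#' flexible block and beads `N/2+1..N` the semi-flexible block. The junction
#' bond (connecting the two blocks) is counted as flexible, and an angle is
#' stiff only when *both* of its bonds are semi-flexible, so the junction
#' angle is free. This is the minimal-stiffness reading of a symmetric
#' diblock with 499 + 499 assigned bonds out of 999 for N = 1000.
#'
#' @param N number of beads (>= 2; even for `kind = "diblock"`)
#' @param kind `"flexible"`, `"semiflexible"` or `"diblock"`
#' @param b_stiff dimensionless bending stiffness of semi-flexible angles
#' @return an object of class `chain_topology` with fields `N`, `kind`,
#'   `bonds` (an `(N-1) x 2` matrix), `angle_b` (length `N - 2`),
#'   `block` (per-bead label) and `b_stiff`
#' @examples
#' top <- chain_topology(1000, "diblock", b_stiff = 20)
#' sum(top$angle_b > 0)  # 498 stiff angles
#' @export
chain_topology <- function(N, kind = c("flexible", "semiflexible", "diblock"),
                           b_stiff = 20) {
  kind <- match.arg(kind)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    npa_stop("N must be an integer >= 2", "nanopost_topology_error")
  if (b_stiff < 0)
    npa_stop("b_stiff must be >= 0", "nanopost_topology_error")
  N <- as.integer(N)
  if (kind == "diblock" && N %% 2L != 0L)
    npa_stop("diblock chains must have even N (symmetric split at N/2)",
             "nanopost_topology_error")
  n_ang <- max(N - 2L, 0L)
  angle_b <- numeric(n_ang)
  block <- rep("flexible", N)
  if (kind == "semiflexible") {
    angle_b[] <- b_stiff
    block[] <- "semiflexible"
  } else if (kind == "diblock") {
    half <- N %/% 2L
    block[(half + 1L):N] <- "semiflexible"
    # bond k joins beads k, k+1; it is semi-flexible iff k > half (the
    # junction bond k = half stays flexible). Angle k uses bonds k, k+1 and
    # is stiff only when both are semi-flexible.
    if (n_ang > 0) {
      k <- seq_len(n_ang)
      angle_b[k > half] <- b_stiff
    }
  }
  obj <- list(N = N, kind = kind,
              bonds = cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L),
              angle_b = angle_b, block = block, b_stiff = b_stiff)
  class(obj) <- "chain_topology"
  obj
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("Linear %s chain: N = %d beads, %d bonds, %d angles (%d stiff, b = %g)\n",
              x$kind, x$N, nrow(x$bonds), length(x$angle_b),
              sum(x$angle_b > 0), x$b_stiff))
  invisible(x)
}

#' Beads belonging to a block
#'
#' @param topology a [chain_topology()]
#' @param block `"flexible"`, `"semiflexible"` or `"all"`
#' @return integer vector of bead indices
#' @export
block_beads <- function(topology, block = c("all", "flexible", "semiflexible")) {
  block <- match.arg(block)
  if (block == "all") return(seq_len(topology$N))
  which(topology$block == block)
}

#' Serialize / restore a chain topology (exact round-trip)
#'
#' @param topology a [chain_topology()]
#' @param path file to write / read
#' @return `read_topology` returns the restored `chain_topology`
#' @export
write_topology <- function(topology, path) {
  jsonlite::write_json(
    list(N = topology$N, kind = topology$kind, b_stiff = topology$b_stiff),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chain_topology(x$N, x$kind, as.numeric(x$b_stiff))
}

#' Build a straight initial conformation inside (or outside) the array
#'
#' The chain starts completely straightened with consecutive beads spaced
#' `bond0` (default 0.97, the equilibrium effective bond length of the
#' WCA+FENE bond, which minimises initial bond stress). Two placements are
#' supported inside an array:
#' \describe{
#'   \item{parallel}{along the post axes (x), on the centre line of
#'     interstitial cell (0, 0), i.e. at `y = z = S_p/2`;}
#'   \item{perpendicular}{along y at `z = S_p/2`, threading cell centres and
#'     the passage apertures between posts.}
#' }
#' With `array = NULL` a free chain along x is built. Initial velocities are
#' drawn from the Maxwell distribution at temperature `T` (or zero).
#'
#' For free-chain calibration runs, `conformation = "wlc"` draws the initial
#' conformation from the ideal discretized-WLC Boltzmann distribution
#' instead (each turn angle sampled from `exp(b cos gamma)`, uniform
#' azimuth), which removes the slow relaxation of long-wavelength
#' orientation modes that a rod start entails; it is only available for
#' free chains, where placement feasibility is not an issue.
#'
#' @param topology a [chain_topology()]
#' @param array a [nanopost_array()] or `NULL` for a free chain
#' @param orientation `"parallel"` or `"perpendicular"` to the post axes
#' @param bond0 initial bond length (must be < R_o = 1.5)
#' @param velocities `"maxwell"` or `"zero"`
#' @param T temperature (epsilon/kB units) for Maxwell velocities
#' @param conformation `"straight"` (default) or `"wlc"` (free chains only)
#' @return an object of class `simulation_state`: `positions`, `velocities`
#'   (`N x 3`), `topology`, `array`, `time`
#' @export
initial_conformation <- function(topology, array = NULL,
                                 orientation = c("parallel", "perpendicular"),
                                 bond0 = 0.97,
                                 velocities = c("maxwell", "zero"), T = 1.0,
                                 conformation = c("straight", "wlc")) {
  orientation <- match.arg(orientation)
  velocities <- match.arg(velocities)
  conformation <- match.arg(conformation)
  stopifnot(inherits(topology, "chain_topology"))
  N <- topology$N
  s <- (seq_len(N) - 1) * bond0
  if (conformation == "wlc") {
    if (!is.null(array))
      npa_stop("conformation = 'wlc' is only supported for free chains",
               "nanopost_placement_error")
    pos <- sample_wlc_positions(topology, bond0, T)
  } else if (is.null(array)) {
    pos <- cbind(s, 0, 0)
  } else if (orientation == "parallel") {
    pos <- cbind(s, array$S_p / 2, array$S_p / 2)
  } else {
    pos <- cbind(0, array$S_p / 2 + s, array$S_p / 2)
  }
  colnames(pos) <- c("x", "y", "z")
  if (!is.null(array)) {
    d <- min_distance_to_post_axis(pos[, c("y", "z"), drop = FALSE], array)
    if (any(d <= array$D_p / 2))
      npa_stop(sprintf(
        "cannot place the straight %s chain without bead-post overlap (min axis distance %.3g <= D_p/2 = %.3g)",
        orientation, min(d), array$D_p / 2), "nanopost_placement_error")
  }
  vel <- if (velocities == "maxwell")
    matrix(stats::rnorm(3 * N, sd = sqrt(T)), ncol = 3) else
    matrix(0, N, 3)
  state <- list(positions = pos, velocities = vel,
                topology = topology, array = array, time = 0)
  class(state) <- "simulation_state"
  validate_state(state)
  state
}

#' Check the invariants of a simulation state
#'
#' Every bead must lie outside the bare posts (axis distance >= D_p/2) and
#' every bond must be strictly shorter than the FENE maximum extension
#' R_o = 1.5.
#'
#' @param state a `simulation_state`
#' @param R_o maximum bond extension
#' @return `state`, invisibly; errors otherwise
#' @export
validate_state <- function(state, R_o = 1.5) {
  stopifnot(inherits(state, "simulation_state"))
  bl <- bond_lengths(state$positions)
  if (any(bl >= R_o))
    npa_stop(sprintf("bond %d has length %.4g >= R_o = %g",
                     which.max(bl >= R_o), max(bl), R_o),
             "nanopost_overstretch")
  if (!is.null(state$array)) {
    d <- min_distance_to_post_axis(state$positions[, 2:3, drop = FALSE],
                                   state$array)
    if (any(d < state$array$D_p / 2))
      npa_stop(sprintf("bead %d lies inside a bare post", which.min(d)),
               "nanopost_overlap")
  }
  invisible(state)
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("simulation_state: N = %d beads, t = %g tau, %s\n",
              x$topology$N, x$time,
              if (is.null(x$array)) "free chain" else
                sprintf("array S_p = %g, d_p = %g", x$array$S_p, x$array$d_p)))
  invisible(x)
}

# Sample bead positions from the ideal discretized-WLC distribution: the
# turn angle gamma between consecutive bonds has density prop. to
# exp((b/kT') cos gamma) sin gamma, sampled by inverse CDF on cos gamma;
# azimuths are uniform. Overlapping non-bonded pairs (r < 0.85) are
# resampled a few times to avoid extreme initial WCA forces.
sample_wlc_positions <- function(topology, bond0, T) {
  N <- topology$N
  angle_b <- topology$angle_b
  for (attempt in seq_len(50L)) {
    u <- matrix(NA_real_, N - 1L, 3L)
    u[1L, ] <- c(0, 0, 1)
    for (k in seq_len(N - 2L)) {
      b <- angle_b[k]
      r <- stats::runif(1)
      ct <- if (b == 0) 2 * r - 1 else 1 + log(r + (1 - r) * exp(-2 * b)) / b
      st <- sqrt(max(0, 1 - ct^2))
      phi <- stats::runif(1, 0, 2 * pi)
      e3 <- u[k, ]
      ref <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * e3) * e3
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(e3[2L] * e1[3L] - e3[3L] * e1[2L],
              e3[3L] * e1[1L] - e3[1L] * e1[3L],
              e3[1L] * e1[2L] - e3[2L] * e1[1L])
      u[k + 1L, ] <- ct * e3 + st * (cos(phi) * e1 + sin(phi) * e2)
    }
    pos <- rbind(c(0, 0, 0), apply(u * bond0, 2L, cumsum))
    # bonded pairs sit at bond0, so the global minimum doubles as a
    # non-bonded clash check
    if (min(stats::dist(pos)) > 0.85) {
      colnames(pos) <- c("x", "y", "z")
      return(pos)
    }
  }
  # ideal draws of very flexible chains always self-clash; fall back to the
  # rod start rather than seeding the run with divergent WCA forces
  message("wlc draw kept clashing after 50 attempts; using the straight start")
  pos <- cbind((seq_len(N) - 1) * bond0, 0, 0)
  colnames(pos) <- c("x", "y", "z")
  pos
}

# instantaneous bond lengths of a position matrix
bond_lengths <- function(pos) {
  d <- diff(pos)
  sqrt(rowSums(d^2))
}
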