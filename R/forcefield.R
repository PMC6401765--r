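#' Force-field parameters (reduced Lennard-Jones units)
#'
#' The model energy has four terms: purely repulsive WCA excluded volume
#' between all bead pairs (bonded pairs included), a FENE spring on each
#' bond, a discretized wormlike-chain bending penalty
#' `U_b = (B/l)(1 + cos theta)` on each angle, and the same shifted WCA
#' repulsion between beads and post walls. The bending prefactor `B/l` is
#' fixed at `b*kB*T` via the nominal bond length `l = 0.97` (a
#' discretized-WLC convention; an instantaneous-length prefactor would not
#' be force-conservative).
#'
#' The compiled engine works in reduced units, so `epsilon` and `sigma`
#' must both be 1 there; the scalar energy functions accept general values.
#'
#' @param epsilon,sigma Lennard-Jones energy and length units
#' @param kappa FENE spring constant (30 epsilon/sigma^2)
#' @param R_o maximum bond extension (1.5 sigma)
#' @param l nominal bond length entering the bending prefactor
#' @param pair_wca logical; `FALSE` gives a phantom chain: non-bonded
#'   excluded volume is dropped while the bonded WCA+FENE interaction is
#'   kept (dropping the bonded WCA too would collapse bonds and make the
#'   bending forces singular). Used for ideal-chain oracles.
#' @return an object of class `forcefield_params`
#' @export
forcefield_params <- function(epsilon = 1, sigma = 1, kappa = 30, R_o = 1.5,
                              l = 0.97, pair_wca = TRUE) {
  stopifnot(epsilon > 0, sigma > 0, kappa > 0, R_o > 0, l > 0)
  obj <- list(epsilon = epsilon, sigma = sigma, kappa = kappa, R_o = R_o,
              l = l, cutoff = 2^(1/6) * sigma, pair_wca = isTRUE(pair_wca))
  class(obj) <- "forcefield_params"
  obj
}

#' WCA pair energy
#'
#' Purely repulsive Lennard-Jones interaction, truncated and shifted at its
#' minimum `2^(1/6) sigma`, where it vanishes continuously:
#' `U(r) = 4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for `r < 2^(1/6) sigma`,
#' zero beyond.
#'
#' @param r pair distance(s), > 0
#' @param epsilon,sigma Lennard-Jones parameters
#' @return energy (epsilon units), vectorized over `r`
#' @export
wca_pair_energy <- function(r, epsilon = 1, sigma = 1) {
  if (any(r <= 0))
    npa_stop("divergent overlap: pair distance r <= 0", "nanopost_overlap")
  s6 <- (sigma / r)^6
  ifelse(r < 2^(1/6) * sigma, 4 * epsilon * (s6^2 - s6) + epsilon, 0)
}

#' Bead-post energy
#'
#' The WCA form evaluated at the gap between the bead centre and the post
#' surface, `U(r_axis) = U_WCA(r_axis - D_p/2)`: zero beyond
#' `D_p/2 + 2^(1/6) sigma`. With `D_p = 0` it reduces to a repulsive line
#' potential identical to [wca_pair_energy()].
#'
#' @param r_axis distance(s) from the bead centre to the post axis
#' @param D_p bare post diameter
#' @inheritParams wca_pair_energy
#' @return energy, vectorized
#' @export
post_energy <- function(r_axis, D_p, epsilon = 1, sigma = 1) {
  if (any(r_axis <= D_p / 2))
    npa_stop("bead inside post: r_axis <= D_p/2", "nanopost_overlap")
  wca_pair_energy(r_axis - D_p / 2, epsilon, sigma)
}

#' FENE bond energy
#'
#' `U(l) = -(kappa/2) R_o^2 log(1 - (l/R_o)^2)`, diverging at the maximum
#' extension `R_o`. Bond lengths at or beyond `R_o` are a hard error (the
#' simulation aborts rather than clamps: silent clamping corrupts
#' statistics). The total bonded interaction of the model is FENE plus the
#' WCA term of the same pair.
#'
#' @param l_ij bond length(s), in `[0, R_o)`
#' @param kappa spring constant
#' @param R_o maximum extension
#' @return energy, vectorized
#' @export
fene_energy <- function(l_ij, kappa = 30, R_o = 1.5) {
  if (any(l_ij < 0))
    npa_stop("negative bond length", "nanopost_overstretch")
  if (any(l_ij >= R_o))
    npa_stop(sprintf("bond overstretch: l = %.4g >= R_o = %g",
                     max(l_ij), R_o), "nanopost_overstretch")
  -0.5 * kappa * R_o^2 * log(1 - (l_ij / R_o)^2)
}

#' Bending energy of a valence angle
#'
#' Discretized wormlike-chain penalty `U_b(theta) = b*kT*(1 + cos theta)`,
#' where `theta` is the valence angle at a bead between the two bond vectors
#' pointing *away* from it, so a straight chain has `theta = pi` and zero
#' energy. `b = B/(l*kB*T)` is the dimensionless stiffness (0 for flexible
#' angles, 20 by default for semi-flexible ones).
#'
#' @param theta valence angle(s) in radians, in `[0, pi]`
#' @param b dimensionless stiffness
#' @param kT thermal energy (1 in reduced units)
#' @return energy, vectorized
#' @export
bending_energy <- function(theta, b, kT = 1) {
  b * kT * (1 + cos(theta))
}

#' Total energy and forces of a configuration
#'
#' Sums the four energy terms over a `simulation_state` and returns exact
#' negative-gradient forces. The short-range pair search uses a Verlet
#' neighbour list by default; `neighbour = "all"` forces the all-pairs
#' reference path (both give bit-identical energies, a tested property).
#' Overlaps (`r = 0`, bead inside a bare post) and bond overstretch raise
#' classed errors.
#'
#' @param state a `simulation_state`
#' @param ff a [forcefield_params()] (reduced units: epsilon = sigma = 1)
#' @param kT thermal energy scaling the bending prefactor
#' @param neighbour `"verlet"` or `"all"`
#' @return list with `energy`, per-term `components`, and an `N x 3`
#'   `forces` matrix
#' @export
total_energy_and_forces <- function(state, ff = forcefield_params(), kT = 1,
                                    neighbour = c("verlet", "all")) {
  neighbour <- match.arg(neighbour)
  stopifnot(inherits(state, "simulation_state"),
            inherits(ff, "forcefield_params"))
  if (ff$epsilon != 1 || ff$sigma != 1)
    npa_stop("the compiled engine requires reduced units (epsilon = sigma = 1)",
             "nanopost_units_error")
  arr <- state$array
  res <- ef_compute_cpp(state$positions, state$topology$angle_b * kT,
                        ff$kappa, ff$R_o, ff$pair_wca,
                        !is.null(arr),
                        if (is.null(arr)) 0 else arr$S_p,
                        if (is.null(arr)) 0 else arr$D_p,
                        neighbour)
  if (res$bad_bond > 0)
    npa_stop(sprintf("bond overstretch at bond %d", res$bad_bond),
             "nanopost_overstretch")
  if (res$bad_bead > 0)
    npa_stop(sprintf("divergent overlap at bead %d", res$bad_bead),
             "nanopost_overlap")
  list(energy = res$energy,
       components = c(wca = res$wca, fene = res$fene,
                      bend = res$bend, post = res$post),
       forces = res$forces)
}
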