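# Confinement free-energy theory: channel and slit penalties in the Odijk
# (strong, deflection-segment) and de Gennes (moderate, blob) regimes, and
# the predicted single-to-multiple-occupancy penetration transitions
# obtained by equating the passage-aperture (quasi-slit of height w) and
# interstitial-volume (quasi-channel of diameter d_c) penalties.

check_pos <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    npa_stop("all theory parameters must be positive and finite",
             "nanopost_theory_error")
}

#' Odijk channel confinement free energy
#'
#' Free-energy penalty of a semi-flexible chain in a square channel under
#' strong confinement (deflection regime, channel width below the
#' persistence length): `dA/kT = 2.2072 * L * P^(-1/3) * D^(-2/3)`.
#' The caller is responsible for the regime (`D` of order `P` or below).
#'
#' @param L contour length
#' @param P persistence length
#' @param D channel width
#' @return `dA/kT`
#' @export
odijk_channel_free_energy <- function(L, P, D) {
  check_pos(L, P, D)
  2.2072 * L * P^(-1/3) * D^(-2/3)
}

#' de Gennes channel confinement free energy
#'
#' Blob-regime penalty of a chain in a square channel under moderate
#' confinement: `dA/kT = 4.0 * L * (P*a)^(1/3) * D^(-5/3)`, with `a` the
#' monomer size.
#'
#' @inheritParams odijk_channel_free_energy
#' @param a monomer (bead) size
#' @return `dA/kT`
#' @export
degennes_channel_free_energy <- function(L, P, a, D) {
  check_pos(L, P, a, D)
  4.0 * L * (P * a)^(1/3) * D^(-5/3)
}

#' Slit free energy from the channel value
#'
#' The penalty of a chain in a square channel is, to a good approximation,
#' twice that in a slit of height equal to the channel width; so the slit
#' value is the channel value halved.
#'
#' @param channel_value `dA/kT` in the channel of width equal to the slit
#'   height
#' @return `dA/kT` in the slit
#' @export
slit_free_energy <- function(channel_value) channel_value / 2

#' Predicted penetration transition for a semi-flexible chain
#'
#' Equating the Odijk penalty in the quasi-slit passage (height `w`, halved
#' for the slit) with the de Gennes penalty in the quasi-channel interstitial
#' volume (diameter `d_c`) gives the closed form
#' `d_c/w = 2.165 * (P/w)^(2/5) * (a/w)^(1/5)`; the chain spreads over
#' several interstitial volumes once the actual ratio exceeds this value.
#' The prefactor is `(8/2.2072)^(3/5)`; [transition_ratio_root()] recovers
#' the same number by numerical root finding.
#'
#' @param P persistence length
#' @param w passage width
#' @param a monomer size
#' @return predicted `d_c/w` at the transition
#' @examples
#' semiflexible_transition_ratio(P = 19.23, w = 2, a = 0.97)  # 4.63
#' @export
semiflexible_transition_ratio <- function(P, w, a) {
  check_pos(P, w, a)
  2.165 * (P / w)^(2/5) * (a / w)^(1/5)
}

#' Predicted penetration transition for a flexible chain
#'
#' A flexible chain follows the de Gennes regime in both the passage and the
#' interstitial volume; equating the channel penalty at `d_c` with half the
#' channel penalty at `w` cancels every parameter and leaves the constant
#' `d_c/w = 2^(3/5) = 1.52`.
#'
#' @return `2^(3/5)`
#' @export
flexible_transition_ratio <- function() 2^(3/5)

#' Numerical equal-free-energy root for the penetration transition
#'
#' Independent cross-check of the closed forms: solves
#' `channel(d_c) = slit(w)` for `d_c/w` by root finding, with the slit
#' penalty the halved channel penalty at `w`. For
#' `regime = "semiflexible"` the slit side uses the Odijk form and the
#' channel side the de Gennes form; for `regime = "flexible"` both sides use
#' the de Gennes form (the result is then parameter-free).
#'
#' @param P,w,a theory parameters (the flexible root does not depend on them)
#' @param L contour length (cancels; kept to demonstrate extensivity)
#' @param regime `"semiflexible"` or `"flexible"`
#' @return the root `d_c/w`
#' @export
transition_ratio_root <- function(P = 19.23, w = 2, a = 0.97, L = 1,
                                  regime = c("semiflexible", "flexible")) {
  regime <- match.arg(regime)
  check_pos(P, w, a, L)
  slit <- if (regime == "semiflexible")
    slit_free_energy(odijk_channel_free_energy(L, P, w))
  else
    slit_free_energy(degennes_channel_free_energy(L, P, a, w))
  g <- function(ratio) degennes_channel_free_energy(L, P, a, ratio * w) - slit
  stats::uniroot(g, c(1e-3, 1e3), tol = 1e-12)$root
}

#' Locate the penetration transition on a sampled occupation curve
#'
#' The transition is the coordinate at which the mean occupation number
#' first exceeds 1 (practically, `1 + delta`); on a sampled curve it is
#' located by linear interpolation between the bracketing grid points, in
#' the direction of increasing `n`. Several coordinate columns (e.g. `F`
#' and `d_c/w`) can be interpolated at once.
#'
#' @param coords numeric vector or data.frame of curve coordinates
#' @param n mean occupation numbers at those coordinates
#' @param delta threshold margin above 1 (default 0.05; the located
#'   transition depends mildly on this reading, so report sensitivity when
#'   it matters)
#' @return named numeric vector of interpolated coordinates at the crossing
#' @export
detect_transition <- function(coords, n, delta = 0.05) {
  thr <- 1 + delta
  cdf <- if (is.data.frame(coords)) coords else data.frame(coord = coords)
  if (nrow(cdf) != length(n))
    npa_stop("coords and n must have the same length", "nanopost_fit_error")
  if (all(n <= thr))
    npa_stop("occupation curve never exceeds the threshold: no transition",
             "nanopost_no_transition")
  if (all(n > thr))   # transition lies before the sampled range: report the
    return(setNames(as.numeric(cdf[which.min(n), ]), names(cdf)))  # closest point
  # first adjacent pair (in curve order) straddling the threshold
  below <- n <= thr
  k <- which(below[-length(n)] != below[-1L])[1L]
  f <- (thr - n[k]) / (n[k + 1L] - n[k])
  lo <- as.numeric(cdf[k, ]); hi <- as.numeric(cdf[k + 1L, ])
  setNames(lo + f * (hi - lo), names(cdf))
}
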