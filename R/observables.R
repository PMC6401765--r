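# Conformational observables computed from trajectories. All accept either
# a trajectory produced by integrate_chain()/read_xyz() and a bead subset
# (indices, or a block name resolved against the topology).

resolve_subset <- function(traj, subset) {
  if (is.null(subset)) return(seq_len(dim(traj$positions)[1]))
  if (is.character(subset)) {
    if (is.null(traj$topology))
      npa_stop("block subsets need a trajectory with topology metadata",
               "nanopost_subset_error")
    return(block_beads(traj$topology, subset))
  }
  as.integer(subset)
}

# standard error of a correlated series via batch means
batch_se <- function(x, n_batch = 10L) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  n_batch <- max(2L, min(n_batch, n %/% 2L))
  b <- floor(n / n_batch)
  m <- vapply(seq_len(n_batch),
              function(k) mean(x[((k - 1) * b + 1):(k * b)]), numeric(1))
  stats::sd(m) / sqrt(n_batch)
}

#' Axial span of the chain along the post axes
#'
#' Per frame, `max(x_i) - min(x_i)` over the selected beads, then averaged
#' over frames: the standard extension observable of single-molecule DNA
#' experiments in nanofluidic devices. Block-resolved spans are obtained by
#' passing `subset = "flexible"` or `"semiflexible"`.
#'
#' @param traj a `trajectory`
#' @param subset bead indices, a block name, or `NULL` for the whole chain
#' @return list with `mean`, `se` (batch-means standard error) and the
#'   `per_frame` series
#' @export
axial_span <- function(traj, subset = NULL) {
  idx <- resolve_subset(traj, subset)
  if (length(idx) < 1L || n_frames(traj) < 1L)
    npa_stop("axial_span needs at least one bead and one frame",
             "nanopost_subset_error")
  x <- traj$positions[idx, 1L, , drop = FALSE]
  per <- apply(x, 3L, function(v) max(v) - min(v))
  list(mean = mean(per), se = batch_se(per), per_frame = per)
}

#' Radius-of-gyration components parallel and perpendicular to the posts
#'
#' Per frame, the squared gyration components about the subset centroid are
#' accumulated; ensemble averaging happens *before* the square root:
#' `Rg_par = sqrt(<Rg_x^2>)`, `Rg_perp = sqrt((<Rg_y^2> + <Rg_z^2>)/2)`, and
#' `Rg = sqrt(<Rg_x^2> + <Rg_y^2> + <Rg_z^2>)` (equivalently
#' `sqrt(<Rg_par^2> + 2 <Rg_perp^2>)`).
#'
#' @inheritParams axial_span
#' @return list with `Rg`, `Rg_par`, `Rg_perp`, their standard errors on the
#'   squared components, and the `per_frame` matrix of squared components
#' @export
gyration_components <- function(traj, subset = NULL) {
  idx <- resolve_subset(traj, subset)
  if (length(idx) < 2L)
    npa_stop("gyration components are undefined for fewer than 2 beads",
             "nanopost_subset_error")
  nf <- n_frames(traj)
  per <- matrix(NA_real_, nf, 3L,
                dimnames = list(NULL, c("Rgx2", "Rgy2", "Rgz2")))
  for (k in seq_len(nf)) {
    p <- traj$positions[idx, , k, drop = TRUE]
    per[k, ] <- colMeans(scale(p, scale = FALSE)^2)
  }
  m <- colMeans(per)
  list(Rg = sqrt(sum(m)),
       Rg_par = sqrt(m[["Rgx2"]]),
       Rg_perp = sqrt((m[["Rgy2"]] + m[["Rgz2"]]) / 2),
       se2 = apply(per, 2L, batch_se),
       per_frame = per)
}

#' Interstitial occupation number
#'
#' Per frame, the number of distinct interstitial cells containing at least
#' one bead of the subset (a cell is occupied at one bead or more; a
#' minimum-bead threshold is configurable), averaged over frames. Labels use
#' unwrapped coordinates, so the count is invariant under lattice
#' translations of the whole configuration.
#'
#' @inheritParams axial_span
#' @param array a [nanopost_array()]; defaults to the trajectory's own
#' @param min_beads minimum beads for a cell to count as occupied
#' @return list with `mean`, `se`, `per_frame`
#' @export
occupation_number <- function(traj, subset = NULL, array = NULL,
                              min_beads = 1L) {
  array <- if (is.null(array)) traj$array else array
  if (is.null(array))
    npa_stop("occupation_number needs a nanopost_array", "nanopost_subset_error")
  idx <- resolve_subset(traj, subset)
  nf <- n_frames(traj)
  per <- numeric(nf)
  for (k in seq_len(nf)) {
    ci <- cell_index(traj$positions[idx, 2:3, k, drop = TRUE], array)
    tab <- table(paste(ci[, 1L], ci[, 2L]))
    per[k] <- sum(tab >= min_beads)
  }
  list(mean = mean(per), se = batch_se(per), per_frame = per)
}

#' Single-chain structure factor
#'
#' The orientation-averaged double sum
#' `S(q) = (1/n^2) < sum_ij sin(q r_ij)/(q r_ij) >`, with the diagonal terms
#' contributing 1 each, ensemble-averaged over frames. Limits: `S(q) -> 1`
#' as `q -> 0` and `S(q) -> 1/n` at large `q`. For chains spread over
#' several interstitial cells the geometry shows up as a hump near
#' `q = 2*pi/S_p`. The default grid is logarithmic from `2*pi/L_max` (with
#' `L_max` the largest frame extent) to `2*pi/0.5`, 120 points.
#'
#' @inheritParams axial_span
#' @param q wave-number grid (1/sigma); `NULL` for the default
#' @param method `"direct"` double sum or `"histogram"` (pair distances
#'   binned at `dr`, much faster for many frames; agrees with the direct
#'   sum to ~1e-6)
#' @param dr histogram bin width
#' @return list with `q`, `S`, and the length scale `Omega = 2*pi/q`
#' @export
structure_factor <- function(traj, subset = NULL, q = NULL,
                             method = c("direct", "histogram"), dr = 1e-4) {
  method <- match.arg(method)
  idx <- resolve_subset(traj, subset)
  if (n_frames(traj) < 1L)
    npa_stop("structure_factor needs at least one frame", "nanopost_subset_error")
  if (is.null(q)) {
    ext <- max(apply(traj$positions[idx, , , drop = FALSE], 3L, function(p)
      max(apply(p, 2L, function(v) diff(range(v))))), 1)
    q <- exp(seq(log(2 * pi / ext), log(2 * pi / 0.5), length.out = 120L))
  }
  fr <- aperm(traj$positions, c(2, 1, 3))   # back to 3 x N x nf for the core
  S <- if (method == "direct")
    sq_direct_cpp(fr, idx - 1L, q)
  else
    sq_hist_cpp(fr, idx - 1L, q, dr)
  list(q = q, S = S, Omega = 2 * pi / q)
}

# bond-orientation correlation <u_i . u_{i+k}> averaged over i and frames
bond_orientation_correlation <- function(traj, subset = NULL, k_max = 20L) {
  idx <- resolve_subset(traj, subset)
  if (any(diff(idx) != 1L))
    npa_stop("bond correlations need a contiguous bead subset",
             "nanopost_subset_error")
  nb <- length(idx) - 1L
  k_max <- min(k_max, nb - 1L)
  nf <- n_frames(traj)
  acc <- numeric(k_max); cnt <- numeric(k_max); lbar <- 0
  for (f in seq_len(nf)) {
    p <- traj$positions[idx, , f, drop = TRUE]
    d <- diff(p)
    l <- sqrt(rowSums(d^2))
    u <- d / l
    lbar <- lbar + mean(l)
    for (k in seq_len(k_max)) {
      dots <- rowSums(u[1:(nb - k), , drop = FALSE] *
                      u[(1 + k):nb, , drop = FALSE])
      acc[k] <- acc[k] + sum(dots)
      cnt[k] <- cnt[k] + length(dots)
    }
  }
  list(k = seq_len(k_max), C = acc / cnt, mean_bond = lbar / nf)
}

#' Persistence length from bond-orientation correlations
#'
#' Fits the exponential decay `<u_i . u_{i+k}> = exp(-k*<l>/P)` of the unit
#' bond-vector correlations by log-linear least squares over separations
#' `k <= k_max` (default 20, about one persistence length of the b = 20
#' chain in bonds). Requires a free or weakly confined chain. Correlations
#' that have not decayed at all (a rigid rod) give `P = Inf`; non-positive
#' correlations inside the window are a fit-failure error (the chain is too
#' flexible for this estimator at that window).
#'
#' @inheritParams axial_span
#' @param k_max largest bond separation in the fit window
#' @return list with `P`, the fitted correlations, and the mean bond length
#' @export
persistence_length <- function(traj, subset = NULL, k_max = 20L) {
  bc <- bond_orientation_correlation(traj, subset, k_max)
  if (any(bc$C <= 0))
    npa_stop("non-positive bond correlations in the fit window: chain too flexible for the exponential-decay estimator",
             "nanopost_fit_error")
  if (all(bc$C > 1 - 1e-12))
    return(list(P = Inf, k = bc$k, C = bc$C, mean_bond = bc$mean_bond))
  fit <- stats::lm(log(bc$C) ~ bc$k)
  slope <- stats::coef(fit)[[2L]]
  if (slope >= 0)
    npa_stop("non-decaying bond correlations: persistence length undefined",
             "nanopost_fit_error")
  list(P = -bc$mean_bond / slope, k = bc$k, C = bc$C,
       mean_bond = bc$mean_bond)
}

#' Ensemble persistence length from several independent trajectories
#'
#' The bond-orientation correlation `C_k` of a *single* chain has both a
#' large sample variance and a long autocorrelation time at separations
#' `k` approaching the persistence length, so single-run estimates scatter
#' by 10% and more at desk scale. This estimator pools `C_k` over
#' independent replicas and fits the exponential decay by
#' inverse-variance-weighted log-linear least squares over the same
#' `k <= k_max` window (the replicate scatter of each `C_k` supplies the
#' weights; unweighted least squares is available with
#' `weighted = FALSE`).
#'
#' @param trajs list of `trajectory` objects (independent replicas)
#' @param subset bead subset, as in [persistence_length()]
#' @param k_max largest bond separation in the fit window
#' @param weighted use inverse-variance weights from the replicate scatter
#' @return list with `P`, the pooled correlations `C`, their standard
#'   errors, and the mean bond length
#' @export
ensemble_persistence <- function(trajs, subset = NULL, k_max = 20L,
                                 weighted = TRUE) {
  stopifnot(length(trajs) >= 2L)
  Cm <- t(vapply(trajs, function(tr)
    bond_orientation_correlation(tr, subset, k_max)$C, numeric(k_max)))
  lbar <- mean(vapply(trajs, function(tr)
    bond_orientation_correlation(tr, subset, 1L)$mean_bond, numeric(1)))
  C <- colMeans(Cm)
  if (any(C <= 0))
    npa_stop("non-positive pooled bond correlations in the fit window",
             "nanopost_fit_error")
  v <- apply(Cm, 2L, stats::var) / nrow(Cm)
  k <- seq_len(k_max)
  w <- if (weighted) C^2 / pmax(v, 1e-300) else rep(1, k_max)
  fit <- stats::lm(log(C) ~ k, weights = w)
  slope <- stats::coef(fit)[[2L]]
  if (slope >= 0)
    npa_stop("non-decaying pooled bond correlations", "nanopost_fit_error")
  list(P = -lbar / slope, k = k, C = C, se = sqrt(v), mean_bond = lbar)
}

#' Ideal discretized-WLC turn-angle average and persistence length
#'
#' For a phantom chain with bending energy `b*kT*(1 + cos theta)` the bond
#' turn angle `gamma = pi - theta` has Boltzmann average
#' `<cos gamma> = coth(b) - 1/b`, giving `P = -l / log(<cos gamma>)`.
#' Used as the analytic reference for the phantom-chain oracle tests.
#'
#' @param b dimensionless stiffness
#' @param l bond length
#' @return list with `cos_gamma` and `P`
#' @export
wlc_ideal_persistence <- function(b, l = 0.97) {
  cg <- if (b == 0) 0 else 1 / tanh(b) - 1 / b
  list(cos_gamma = cg, P = if (cg <= 0) 0 else -l / log(cg))
}

#' Fit the span-versus-channel-diameter scaling exponent
#'
#' Least-squares slope of `log(R_s)` against `log(d_c)`, sign-flipped, for
#' chains in the single-occupancy regime where `R_s ~ d_c^-x` (x = 2/3 for a
#' flexible chain in the blob regime, 1 for a semi-flexible chain in the
#' deflection regime).
#'
#' @param d_c effective channel diameters (>= 3 values)
#' @param R_s corresponding mean axial spans
#' @return list with the exponent `x` and the `lm` fit
#' @export
fit_span_scaling <- function(d_c, R_s) {
  if (length(d_c) < 3L || length(R_s) != length(d_c))
    npa_stop("need at least 3 (d_c, R_s) points", "nanopost_fit_error")
  fit <- stats::lm(log(R_s) ~ log(d_c))
  list(x = -stats::coef(fit)[[2L]], fit = fit)
}
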