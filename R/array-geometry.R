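#' Square-lattice nanopost array geometry
#'
#' Defines the square lattice of parallel cylindrical posts and derives every
#' confinement parameter used downstream. Posts are infinite cylinders
#' parallel to the x axis with axes at the lattice points `(i*S_p, j*S_p)` in
#' the y-z plane; the interstitial cell `(i, j)` has its centre at
#' `((i + 1/2)*S_p, (j + 1/2)*S_p)`. Because a bead and a post wall repel
#' each other through the same excluded-volume potential as two beads, the
#' effective post diameter is broadened by the bead size:
#' `d_p = D_p + 0.9`. Derived quantities:
#' \describe{
#'   \item{`w = S_p - d_p`}{passage (quasi-slit) width between two posts}
#'   \item{`d_c = sqrt(2)*S_p - d_p`}{effective interstitial quasi-channel diameter}
#'   \item{`F = pi*d_p^2/(4*S_p^2)`}{post filling fraction, at most `pi/4`}
#' }
#' Exactly one of `D_p` (bare) or `d_p` (effective) must be given. All
#' lengths are in Lennard-Jones sigma units.
#'
#' @param S_p post centre-to-centre spacing (> 0)
#' @param D_p bare post diameter (>= 0)
#' @param d_p effective post diameter (alternative to `D_p`)
#' @param n_y,n_z lattice repeat counts of the nominal box (bookkeeping for
#'   trajectory metadata; the potential treats the lattice as infinite)
#' @return an object of class `nanopost_array` with fields `S_p`, `D_p`,
#'   `d_p`, `w`, `d_c`, `F`, `n_y`, `n_z`
#' @examples
#' a <- nanopost_array(S_p = 12, d_p = 11.1)
#' a$F            # 0.672
#' confinement_ratio(a)  # 6.52
#' @export
nanopost_array <- function(S_p, D_p = NULL, d_p = NULL, n_y = 8L, n_z = 8L) {
  if (!is.numeric(S_p) || length(S_p) != 1L || S_p <= 0)
    npa_stop("S_p must be a single positive length", "nanopost_geometry_error")
  if (is.null(d_p) == is.null(D_p))
    npa_stop("give exactly one of D_p (bare) or d_p (effective) post diameter",
             "nanopost_geometry_error")
  if (is.null(d_p)) {
    if (D_p < 0)
      npa_stop("D_p must be non-negative", "nanopost_geometry_error")
    d_p <- D_p + 0.9
  } else {
    D_p <- d_p - 0.9
  }
  w <- S_p - d_p
  if (w <= 0)
    npa_stop(sprintf(
      "infeasible geometry: passage width w = S_p - d_p = %.4g <= 0 (posts close the passage)", w),
      "nanopost_geometry_error")
  obj <- list(S_p = S_p, D_p = D_p, d_p = d_p,
              w = w,
              d_c = sqrt(2) * S_p - d_p,
              F = pi * d_p^2 / (4 * S_p^2),
              n_y = as.integer(n_y), n_z = as.integer(n_z))
  class(obj) <- "nanopost_array"
  obj
}

#' @export
print.nanopost_array <- function(x, ...) {
  cat("Square-lattice nanopost array (sigma units)\n")
  cat(sprintf("  S_p = %g, D_p = %g (effective d_p = %g)\n", x$S_p, x$D_p, x$d_p))
  cat(sprintf("  passage width w = %g, interstitial diameter d_c = %g\n", x$w, x$d_c))
  cat(sprintf("  filling fraction F = %.4g, confinement ratio d_c/w = %.4g\n",
              x$F, x$d_c / x$w))
  invisible(x)
}

#' Confinement ratio d_c/w of a nanopost array
#'
#' The ratio of the effective interstitial channel diameter to the passage
#' width; it governs whether a chain stays in a single interstitial volume
#' or spreads over several.
#'
#' @param array a [nanopost_array()]
#' @return `d_c / w`
#' @export
confinement_ratio <- function(array) {
  stopifnot(inherits(array, "nanopost_array"))
  array$d_c / array$w
}

#' Map y-z points to interstitial cell labels
#'
#' Returns the lattice cell whose centre is nearest to each point; a point
#' exactly equidistant from two centres (on a passage midline) is assigned
#' the lexicographically smallest label, so occupation numbers are
#' deterministic.
#'
#' @param points numeric vector `c(y, z)` or an n x 2 matrix of y-z positions
#' @param array a [nanopost_array()]
#' @param wrap fold labels into `[0, n_y) x [0, n_z)` (default `FALSE`:
#'   unwrapped labels, appropriate for a single unwrapped chain)
#' @return an n x 2 integer matrix of cell labels `(i, j)`
#' @export
cell_index <- function(points, array, wrap = FALSE) {
  stopifnot(inherits(array, "nanopost_array"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 2L)
  # cell (i,j) owns [i*S_p, (i+1)*S_p); ceiling(y/S_p) - 1 sends a boundary
  # point to the lower (lexicographically smaller) cell
  idx <- cbind(as.integer(ceiling(p[, 1L] / array$S_p) - 1),
               as.integer(ceiling(p[, 2L] / array$S_p) - 1))
  colnames(idx) <- c("i", "j")
  if (wrap) {
    idx[, 1L] <- idx[, 1L] %% array$n_y
    idx[, 2L] <- idx[, 2L] %% array$n_z
  }
  idx
}

#' Distance from y-z points to the nearest post axis
#'
#' Euclidean distance in the y-z plane to the nearest lattice axis, using the
#' (infinite) periodic lattice; never exceeds the cell half-diagonal
#' `S_p/sqrt(2)`.
#'
#' @inheritParams cell_index
#' @return numeric vector of distances
#' @export
min_distance_to_post_axis <- function(points, array) {
  stopifnot(inherits(array, "nanopost_array"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 2L)
  dy <- p[, 1L] - array$S_p * round(p[, 1L] / array$S_p)
  dz <- p[, 2L] - array$S_p * round(p[, 2L] / array$S_p)
  sqrt(dy^2 + dz^2)
}

#' Derived-geometry table for a set of effective post diameters
#'
#' Convenience wrapper used by the sweep driver and the `theory geometry`
#' CLI subcommand: tabulates `d_p`, `w`, `d_c`, `F` and `d_c/w` for one or
#' more geometries. Infeasible rows (w <= 0) are dropped with a message.
#'
#' @param S_p spacing(s), recycled against `d_p`
#' @param d_p effective post diameter(s)
#' @return a data.frame with one row per feasible geometry
#' @export
geometry_table <- function(S_p, d_p) {
  n <- max(length(S_p), length(d_p))
  S_p <- rep_len(S_p, n); d_p <- rep_len(d_p, n)
  rows <- lapply(seq_len(n), function(k) {
    a <- tryCatch(nanopost_array(S_p[k], d_p = d_p[k]),
                  nanopost_geometry_error = function(e) NULL)
    if (is.null(a)) {
      message(sprintf("skipping infeasible geometry S_p = %g, d_p = %g",
                      S_p[k], d_p[k]))
      return(NULL)
    }
    data.frame(S_p = a$S_p, D_p = a$D_p, d_p = a$d_p, w = a$w,
               d_c = a$d_c, F = a$F, dc_over_w = a$d_c / a$w)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
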