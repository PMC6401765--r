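# Configuration handling, extended-XYZ persistence, analytic fixtures, the
# geometry sweep driver and a small command-line interface.

config_keys <- c("N", "blocks", "b", "S_p", "n_y", "n_z", "dt", "T",
                 "thermostat", "gamma_or_tau", "n_equil", "n_prod",
                 "sample_interval", "seed", "replicas", "orientation")

#' Default run configuration
#'
#' A complete desk-scale configuration list; override any key through
#' `...`. Exactly one of `d_p` / `D_p` may be set (or neither, for a free
#' chain). `gamma_or_tau` is the Langevin friction or the Nose-Hoover
#' relaxation time, depending on `thermostat`.
#'
#' @param ... overrides for any configuration key
#' @return a validated configuration list
#' @export
default_config <- function(...) {
  cfg <- list(N = 100L, blocks = "flexible", b = 20, S_p = 12,
              D_p = NULL, d_p = 6.9, n_y = 8L, n_z = 8L,
              dt = 0.005, T = 1, thermostat = "langevin", gamma_or_tau = 1,
              n_equil = 10000L, n_prod = 100000L, sample_interval = 1000L,
              seed = 1L, replicas = 3L, orientation = "parallel")
  over <- list(...)
  if ("D_p" %in% names(over) && !("d_p" %in% names(over))) cfg$d_p <- NULL
  cfg[names(over)] <- over
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks presence and type of every required key; validation errors name
#' the offending key.
#'
#' @param config a configuration list
#' @return the configuration, with integer-valued keys coerced
#' @export
validate_config <- function(config) {
  for (key in config_keys)
    if (is.null(config[[key]]))
      npa_stop(sprintf("config key '%s' is missing", key),
               "nanopost_config_error")
  both <- !is.null(config$d_p) && !is.null(config$D_p)
  if (both)
    npa_stop("config keys 'd_p' and 'D_p' are mutually exclusive",
             "nanopost_config_error")
  num_keys <- c("N", "b", "S_p", "n_y", "n_z", "dt", "T", "gamma_or_tau",
                "n_equil", "n_prod", "sample_interval", "seed", "replicas")
  for (key in num_keys)
    if (!is.numeric(config[[key]]) || length(config[[key]]) != 1L)
      npa_stop(sprintf("config key '%s' must be a single number", key),
               "nanopost_config_error")
  if (!config$blocks %in% c("flexible", "semiflexible", "diblock"))
    npa_stop("config key 'blocks' must be flexible, semiflexible or diblock",
             "nanopost_config_error")
  if (!config$thermostat %in% c("langevin", "nose_hoover", "none"))
    npa_stop("config key 'thermostat' must be langevin, nose_hoover or none",
             "nanopost_config_error")
  if (!config$orientation %in% c("parallel", "perpendicular"))
    npa_stop("config key 'orientation' must be parallel or perpendicular",
             "nanopost_config_error")
  for (key in c("N", "n_y", "n_z", "n_equil", "n_prod", "sample_interval",
                "seed", "replicas"))
    config[[key]] <- as.integer(config[[key]])
  for (key in c("b", "S_p", "dt", "T", "gamma_or_tau", "d_p", "D_p"))
    if (!is.null(config[[key]])) config[[key]] <- as.numeric(config[[key]])
  config
}

#' Read / write a configuration file (JSON)
#'
#' @param path file path
#' @return `read_config` returns the validated configuration list
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param config a configuration list
#' @export
write_config <- function(config, path) {
  config <- validate_config(config[!vapply(config, is.null, logical(1))])
  jsonlite::write_json(config, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read trajectories in extended-XYZ format
#'
#' One block per frame: a bead count line, a comment line carrying
#' `Time=`, the array metadata (`Sp=`, `Dp=` when present) and a
#' `Properties=species:S:1:pos:R:3` declaration, then one line per bead
#' with the block species (`F` flexible / `S` semi-flexible) and the
#' position at full double precision (hex-exact round-trip is not
#' attempted; `%.17g` reproduces doubles exactly on read).
#'
#' @param traj a `trajectory`
#' @param path output file
#' @return the path, invisibly
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  N <- dim(traj$positions)[1L]
  species <- if (!is.null(traj$topology))
    ifelse(traj$topology$block == "semiflexible", "S", "F")
  else if (!is.null(traj$species)) traj$species else rep("F", N)
  arr_meta <- if (!is.null(traj$array))
    sprintf(" Sp=%.17g Dp=%.17g", traj$array$S_p, traj$array$D_p) else ""
  for (k in seq_len(nf)) {
    writeLines(sprintf("%d", N), con)
    writeLines(sprintf(
      'Properties=species:S:1:pos:R:3 Time=%.17g%s', traj$times[k], arr_meta),
      con)
    p <- matrix(traj$positions[, , k], ncol = 3L)
    writeLines(sprintf("%s %.17g %.17g %.17g", species, p[, 1], p[, 2], p[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz` returns a `trajectory`-like object with `positions`,
#'   `times`, `species` and (when the file carries `Sp=`/`Dp=`) the array
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); species <- NULL; array <- NULL
  i <- 1L; nline <- length(lines)
  while (i <= nline) {
    if (!grepl("^[0-9]+$", lines[i]))
      npa_stop(sprintf("malformed XYZ at line %d: expected bead count", i),
               "nanopost_parse_error")
    N <- as.integer(lines[i])
    if (i + 1L + N > nline)
      npa_stop(sprintf("malformed XYZ at line %d: truncated frame", i),
               "nanopost_parse_error")
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("Time=([-+0-9.eE]+)", comment))[[1L]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_)
    sp <- regmatches(comment, regexec("Sp=([-+0-9.eE]+) Dp=([-+0-9.eE]+)",
                                      comment))[[1L]]
    if (length(sp) == 3L && is.null(array))
      array <- nanopost_array(as.numeric(sp[2L]), D_p = as.numeric(sp[3L]))
    body <- lines[(i + 2L):(i + 1L + N)]
    parts <- strsplit(body, "[ \t]+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad))
      npa_stop(sprintf("malformed XYZ at line %d: expected 'species x y z'",
                       i + 1L + bad[1L]), "nanopost_parse_error")
    species <- vapply(parts, `[`, "", 1L)
    pos <- t(vapply(parts, function(v) as.numeric(v[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- pos
    i <- i + 2L + N
  }
  nf <- length(frames)
  N <- if (nf) nrow(frames[[1L]]) else 0L
  positions <- array(if (nf) unlist(frames) else numeric(0),
                     dim = c(N, 3L, nf),
                     dimnames = list(NULL, c("x", "y", "z"), NULL))
  traj <- list(positions = positions, times = times, species = species,
               topology = NULL, array = array)
  class(traj) <- "trajectory"
  traj
}

#' Deterministic test fixtures with analytically known observables
#'
#' Builds small configurations whose observables are known in closed form,
#' as single-frame (or multi-frame) `trajectory` objects with the expected
#' values attached in `$expected`:
#' \describe{
#'   \item{rod}{`N` beads spaced `l` along x: span `(N-1)*l`, `Rg_perp = 0`.}
#'   \item{two_bead}{two beads `r` apart: `S(q) = (1 + sin(q r)/(q r))/2`.}
#'   \item{cell_filling}{one bead at the centre of each requested cell:
#'     occupation number is the number of distinct cells.}
#'   \item{wlc_correlated_bonds}{unit bond vectors with exact Markov
#'     correlation `<u_i . u_{i+k}> = exp(-k l / P)` (each bond tilted from
#'     its predecessor by the fixed angle `acos(exp(-l/P))` at a uniform
#'     azimuth), integrated to positions: the persistence-length estimator
#'     must recover `P`.}
#' }
#'
#' @param kind fixture type
#' @param N beads (rod) or bonds + 1 (wlc)
#' @param l bond spacing
#' @param r pair distance (two_bead)
#' @param cells integer matrix / data.frame of cell labels (cell_filling)
#' @param array a [nanopost_array()] (cell_filling)
#' @param P target persistence length (wlc)
#' @param n_frames frames to generate (wlc)
#' @return a `trajectory` with an `$expected` list attached
#' @export
make_fixture <- function(kind = c("rod", "two_bead", "cell_filling",
                                  "wlc_correlated_bonds"),
                         N = 11L, l = 0.97, r = 1, cells = NULL,
                         array = NULL, P = 19, n_frames = 50L) {
  kind <- match.arg(kind)
  as_traj <- function(pos, expected, arr = NULL, nfr = 1L) {
    positions <- if (length(dim(pos)) == 3L) pos else
      array(pos, dim = c(nrow(pos), 3L, 1L))
    dimnames(positions) <- list(NULL, c("x", "y", "z"), NULL)
    tr <- list(positions = positions, times = seq_len(dim(positions)[3L]) - 1,
               topology = NULL, array = arr, expected = expected)
    class(tr) <- "trajectory"
    tr
  }
  switch(kind,
    rod = {
      pos <- cbind((seq_len(N) - 1) * l, 0, 0)
      as_traj(pos, list(span = (N - 1) * l,
                        Rg_par = sqrt(mean((pos[, 1] - mean(pos[, 1]))^2)),
                        Rg_perp = 0))
    },
    two_bead = {
      pos <- rbind(c(0, 0, 0), c(r, 0, 0))
      as_traj(pos, list(S = function(q) (1 + sin(q * r) / (q * r)) / 2))
    },
    cell_filling = {
      if (is.null(array)) array <- nanopost_array(12, d_p = 6.9)
      cl <- as.matrix(cells)
      pos <- cbind(0, (cl[, 1] + 0.5) * array$S_p, (cl[, 2] + 0.5) * array$S_p)
      as_traj(pos, list(n = nrow(unique(cl))), arr = array)
    },
    wlc_correlated_bonds = {
      nb <- N - 1L
      ct <- exp(-l / P)
      st <- sqrt(1 - ct^2)
      frames <- array(NA_real_, dim = c(N, 3L, n_frames))
      for (f in seq_len(n_frames)) {
        u <- matrix(NA_real_, nb, 3L)
        u[1L, ] <- c(0, 0, 1)
        for (k in seq_len(nb - 1L)) {
          phi <- stats::runif(1, 0, 2 * pi)
          # orthonormal frame around the previous bond direction
          e3 <- u[k, ]
          ref <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- ref - sum(ref * e3) * e3
          e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(e3[2L] * e1[3L] - e3[3L] * e1[2L],
                  e3[3L] * e1[1L] - e3[1L] * e1[3L],
                  e3[1L] * e1[2L] - e3[2L] * e1[1L])
          u[k + 1L, ] <- ct * e3 + st * (cos(phi) * e1 + sin(phi) * e2)
        }
        frames[, , f] <- rbind(c(0, 0, 0), apply(u * l, 2L, cumsum))
      }
      dimnames(frames) <- list(NULL, c("x", "y", "z"), NULL)
      as_traj(frames, list(P = P, cos_step = ct))
    })
}

#' Geometry sweep reproducing the two array-variation protocols
#'
#' Runs one experiment per geometry and tabulates the derived confinement
#' parameters together with the measured observables:
#' \describe{
#'   \item{constant_Sp}{`S_p` fixed at the base configuration's value, the
#'     effective post diameter `d_p` taken from `grid`;}
#'   \item{constant_w}{the passage width `w = S_p - d_p` of the base
#'     configuration held fixed, `S_p` taken from `grid` (so
#'     `d_p = S_p - w` per row).}
#' }
#' Infeasible rows (closed passage) are skipped with a logged reason.
#' Rows are independent: each row's seed is derived from the master seed
#' and the row's geometry as
#' `(seed + round(1009*d_p) + round(9973*S_p)) mod 2^31 - 1`, so permuting
#' the grid does not change any row's result.
#'
#' @param protocol `"constant_Sp"` or `"constant_w"`
#' @param grid vector of `d_p` (constant_Sp) or `S_p` (constant_w) values
#' @param config base configuration (see [default_config()])
#' @param run `FALSE` tabulates the geometry columns only (no simulation)
#' @return a data.frame, one row per feasible geometry
#' @export
run_sweep <- function(protocol = c("constant_Sp", "constant_w"), grid,
                      config = default_config(), run = TRUE) {
  protocol <- match.arg(protocol)
  config <- validate_config(config)
  base_dp <- if (!is.null(config$d_p)) config$d_p else config$D_p + 0.9
  if (protocol == "constant_Sp") {
    S_p <- rep(config$S_p, length(grid)); d_p <- grid
  } else {
    w <- config$S_p - base_dp
    S_p <- grid; d_p <- grid - w
  }
  rows <- lapply(seq_along(grid), function(k) {
    a <- tryCatch(nanopost_array(S_p[k], d_p = d_p[k]),
                  nanopost_geometry_error = function(e) NULL)
    if (is.null(a) || (run && a$D_p <= 0)) {
      message(sprintf("skipping infeasible geometry S_p = %g, d_p = %g",
                      S_p[k], d_p[k]))
      return(NULL)
    }
    geo <- data.frame(S_p = a$S_p, d_p = a$d_p, w = a$w, d_c = a$d_c,
                      F = a$F, dc_over_w = a$d_c / a$w)
    if (!run) return(geo)
    cfg <- config
    cfg$S_p <- S_p[k]; cfg$d_p <- d_p[k]; cfg$D_p <- NULL
    cfg$seed <- as.integer((config$seed + round(1009 * d_p[k]) +
                              round(9973 * S_p[k])) %%
                             (.Machine$integer.max))
    res <- run_experiment(cfg)
    obs <- lapply(res$trajectories, function(tr) {
      g <- gyration_components(tr)
      out <- c(R_s = axial_span(tr)$mean, Rg = g$Rg, Rg_par = g$Rg_par,
               Rg_perp = g$Rg_perp, n = occupation_number(tr)$mean)
      if (cfg$blocks == "diblock")
        out <- c(out,
                 R_s_flex = axial_span(tr, "flexible")$mean,
                 R_s_semi = axial_span(tr, "semiflexible")$mean,
                 n_flex = occupation_number(tr, "flexible")$mean,
                 n_semi = occupation_number(tr, "semiflexible")$mean)
      out
    })
    m <- do.call(rbind, obs)
    means <- colMeans(m)
    ses <- apply(m, 2L, stats::sd) / sqrt(nrow(m))
    cbind(geo, as.data.frame(as.list(means)),
          as.data.frame(as.list(setNames(ses, paste0(names(ses), "_se")))))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Command-line interface
#'
#' Subcommands:
#' \preformatted{
#' nanopost simulate <config.json> [--out DIR]
#' nanopost analyze <traj.xyz> --observables span,rg,occupation,sq,persistence
#' nanopost theory transition --P 19.23 --w 2 --a 0.97
#' nanopost theory geometry --Sp 12 --dp 1.9,6.9,11.1
#' nanopost sweep --config <config.json> --protocol constant_Sp --grid 1.9,6.9 [--no-run]
#' }
#' Tables are written as CSV on stdout.
#'
#' @param args character vector of command-line arguments
#' @return invisibly, the computed object
#' @export
npa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  flag <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0L) return(default)
    args[i[1L] + 1L]
  }
  emit <- function(df) { write.csv(df, stdout(), row.names = FALSE); invisible(df) }
  if (length(args) == 0L)
    npa_stop("usage: nanopost <simulate|analyze|theory|sweep> ...",
             "nanopost_cli_error")
  cmd <- args[1L]
  if (cmd == "simulate") {
    res <- run_experiment(args[2L], out_dir = flag("out", "."))
    return(invisible(res))
  }
  if (cmd == "theory") {
    sub <- args[2L]
    if (sub == "transition") {
      P <- as.numeric(flag("P", 19.23)); w <- as.numeric(flag("w", 2))
      a <- as.numeric(flag("a", 0.97))
      return(emit(data.frame(
        flexible = flexible_transition_ratio(),
        semiflexible = semiflexible_transition_ratio(P, w, a))))
    }
    if (sub == "geometry") {
      Sp <- as.numeric(strsplit(flag("Sp", "12"), ",")[[1L]])
      dp <- as.numeric(strsplit(flag("dp", "6.9"), ",")[[1L]])
      return(emit(geometry_table(Sp, dp)))
    }
    npa_stop("theory subcommand must be 'transition' or 'geometry'",
             "nanopost_cli_error")
  }
  if (cmd == "sweep") {
    cfg <- read_config(flag("config"))
    grid <- as.numeric(strsplit(flag("grid"), ",")[[1L]])
    return(emit(run_sweep(flag("protocol", "constant_Sp"), grid, cfg,
                          run = !("--no-run" %in% args))))
  }
  if (cmd == "analyze") {
    tr <- read_xyz(args[2L])
    obs <- strsplit(flag("observables", "span,rg"), ",")[[1L]]
    out <- list()
    if ("span" %in% obs) out$span <- axial_span(tr)$mean
    if ("rg" %in% obs) {
      g <- gyration_components(tr)
      out$Rg <- g$Rg; out$Rg_par <- g$Rg_par; out$Rg_perp <- g$Rg_perp
    }
    if ("occupation" %in% obs) out$n <- occupation_number(tr)$mean
    if ("persistence" %in% obs) out$P <- persistence_length(tr)$P
    res <- as.data.frame(out)
    if ("sq" %in% obs) {
      sq <- structure_factor(tr)
      res <- data.frame(q = sq$q, S = sq$S)
    }
    return(emit(res))
  }
  npa_stop(sprintf("unknown subcommand '%s'", cmd), "nanopost_cli_error")
}
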