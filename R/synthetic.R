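# Synthetic generators with analytic ground truth.  Every analysis stage in
# the package is exercised against these instead of real MD output: modes
# with known wavenumbers for the spectral path, two-state Markov chains with
# known rates for the H-bond path, Gaussian fields with a prescribed
# cross-correlation for the network/PCA path, and exact toy geometries for
# the H-bond detector.

# Speed of light in cm/ps: converts frequency (ps^-1) to wavenumber (cm^-1).
C_CM_PER_PS <- 2.99792458e-2

#' Specification of a harmonic test trajectory
#'
#' @param modes data.frame with columns \code{wavenumber} (cm^-1, > 0),
#'   \code{amplitude} (Angstrom) and optionally \code{phase} (rad, default 0).
#' @param noise_sigma standard deviation of positional white noise
#'   (Angstrom); the stored velocities are the analytic mode derivatives
#'   and exclude this noise.
#' @param dt frame spacing (ps).
#' @param n_frames number of frames, at least 64.
#' @param n_atoms number of atoms.
#' @param seed RNG seed (explicit, never global state).
#' @return object of class \code{harmonic_spec}.
#' @export
harmonic_spec <- function(modes, noise_sigma = 0, dt = 0.05,
                          n_frames = 4096L, n_atoms = 4L, seed = 1L) {
  if (!is.data.frame(modes)) {
    modes <- data.frame(wavenumber = modes, amplitude = 1)
  }
  if (is.null(modes$phase)) modes$phase <- 0
  stopifnot(all(modes$wavenumber > 0), all(modes$amplitude > 0),
            noise_sigma >= 0, dt > 0, n_frames >= 64L, n_atoms >= 1L)
  nyquist_cm1 <- 1 / (2 * dt) / C_CM_PER_PS
  if (any(modes$wavenumber >= nyquist_cm1)) {
    stop("mode wavenumber exceeds the Nyquist limit of ",
         round(nyquist_cm1, 1), " cm^-1 at dt = ", dt, " ps")
  }
  structure(list(modes = modes, noise_sigma = noise_sigma, dt = dt,
                 n_frames = as.integer(n_frames),
                 n_atoms = as.integer(n_atoms), seed = as.integer(seed)),
            class = "harmonic_spec")
}

#' Generate a trajectory of superposed cosine modes
#'
#' Each atom oscillates along x as a sum of cosine modes (with a
#' reproducible per-atom phase offset so atoms are not in lock-step) plus
#' optional positional white noise; y and z hold the atom at its rest
#' position.  Velocities are stored analytically as the sum of the
#' corresponding \eqn{-A\omega\sin} terms, so the velocity autocorrelation
#' of a noise-free single mode is exactly \eqn{\cos(\omega\tau)}.
#'
#' @param spec a \code{\link{harmonic_spec}}.
#' @return a \code{\link{trajectory}} of pseudo-atoms (CA atoms of a
#'   poly-glycine stand-in) with stored velocities.
#' @export
make_harmonic_trajectory <- function(spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)
  nf <- spec$n_frames; na <- spec$n_atoms
  t <- (seq_len(nf) - 1) * spec$dt
  omega <- 2 * pi * spec$modes$wavenumber * C_CM_PER_PS   # rad/ps
  amp <- spec$modes$amplitude
  ph0 <- spec$modes$phase
  # scattered rest positions so the geometry is never degenerate
  rest <- matrix(runif(na * 3, -5 * na, 5 * na), ncol = 3)
  coords <- array(0, dim = c(nf, na, 3L))
  vels <- array(0, dim = c(nf, na, 3L))
  phase_offset <- matrix(runif(na * length(omega), 0, 2 * pi),
                         nrow = na)
  for (a in seq_len(na)) {
    x <- 0; v <- 0
    for (m in seq_along(omega)) {
      arg <- omega[m] * t + ph0[m] + phase_offset[a, m]
      x <- x + amp[m] * cos(arg)
      v <- v - amp[m] * omega[m] * sin(arg)
    }
    coords[, a, 1] <- rest[a, 1] + x
    coords[, a, 2] <- rest[a, 2]
    coords[, a, 3] <- rest[a, 3]
    vels[, a, 1] <- v
  }
  if (spec$noise_sigma > 0) {
    coords <- coords + array(rnorm(length(coords), 0, spec$noise_sigma),
                             dim = dim(coords))
  }
  atoms <- data.frame(name = "CA", element = "C",
                      resno = seq_len(na), resname = "GLY",
                      stringsAsFactors = FALSE)
  trajectory(atoms, coords, spec$dt, velocities = vels)
}

#' Generate an Ornstein-Uhlenbeck (Langevin bath) trajectory
#'
#' Each velocity component follows an exact-discretization OU process with
#' relaxation rate \code{theta} and noise intensity \code{sigma}; positions
#' are the Euler integral of the velocities.  The stationary velocity
#' variance is \eqn{\sigma^2/(2\theta)} per component and the velocity
#' autocorrelation decays as \eqn{e^{-\theta\tau}}, giving a broadband
#' (Lorentzian) spectrum that stands in for solvent-coupled relaxation.
#'
#' @param theta relaxation rate (ps^-1), > 0.
#' @param sigma noise intensity (Angstrom ps^-3/2).
#' @param dt frame spacing (ps).
#' @param n_frames,n_atoms trajectory dimensions.
#' @param seed RNG seed.
#' @param burn_in frames simulated and discarded before recording, so the
#'   recorded process is stationary from frame 1.
#' @return a \code{\link{trajectory}} with stored velocities.
#' @export
make_langevin_trajectory <- function(theta, sigma = 1, dt = 0.01,
                                     n_frames = 8192L, n_atoms = 4L,
                                     seed = 1L, burn_in = NULL) {
  stopifnot(theta > 0, sigma > 0, dt > 0, n_frames >= 2L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (is.null(burn_in)) burn_in <- ceiling(5 / (theta * dt))
  nf <- as.integer(n_frames)
  ntot <- nf + burn_in
  a <- exp(-theta * dt)
  s_stat <- sigma / sqrt(2 * theta)
  s_step <- s_stat * sqrt(1 - a^2)
  nchan <- n_atoms * 3L
  v <- matrix(NA_real_, nrow = ntot, ncol = nchan)
  v[1, ] <- rnorm(nchan, 0, s_stat)
  innov <- matrix(rnorm((ntot - 1) * nchan, 0, s_step), ncol = nchan)
  for (i in 2:ntot) v[i, ] <- a * v[i - 1, ] + innov[i - 1, ]
  v <- v[(burn_in + 1):ntot, , drop = FALSE]
  x <- apply(v, 2, function(col) cumsum(c(0, col[-nf] * dt)))
  coords <- array(x, dim = c(nf, n_atoms, 3L))
  vels <- array(v, dim = c(nf, n_atoms, 3L))
  rest <- matrix(runif(n_atoms * 3, -5 * n_atoms, 5 * n_atoms), ncol = 3)
  for (at in seq_len(n_atoms)) {
    for (k in 1:3) coords[, at, k] <- coords[, at, k] + rest[at, k]
  }
  atoms <- data.frame(name = "CA", element = "C",
                      resno = seq_len(n_atoms), resname = "GLY",
                      stringsAsFactors = FALSE)
  trajectory(atoms, coords, dt, velocities = vels)
}

# ---------------------------------------------------------------------------
# Two-state Markov hydrogen-bond timelines

#' Specification of a two-state Markov hydrogen-bond ensemble
#'
#' Bonds switch between broken (0) and formed (1) with per-step
#' probabilities \eqn{1 - e^{-k\,dt}}; the intermittent autocorrelation of
#' such a chain is the closed form
#' \eqn{C(\tau) = p + (1-p)\,e^{-(k_{on}+k_{off})\tau}} with stationary
#' occupancy \eqn{p = k_{on}/(k_{on}+k_{off})}, so the fitted lifetime has
#' the analytic truth \eqn{\tau = 1/(k_{on}+k_{off})}.
#'
#' @param k_on,k_off formation / rupture rates (ps^-1), > 0.
#' @param dt frame spacing (ps); \code{dt * (k_on + k_off)} must be below
#'   0.5 for the discretization to track the continuous-time chain.
#' @param n_frames,n_bonds timeline dimensions.
#' @param seed RNG seed.
#' @return object of class \code{markov_hbond_spec}.
#' @export
markov_hbond_spec <- function(k_on, k_off, dt = 0.01, n_frames = 1e5,
                              n_bonds = 100L, seed = 1L) {
  stopifnot(k_on > 0, k_off > 0, dt > 0, n_frames >= 2, n_bonds >= 1)
  if (dt * (k_on + k_off) >= 0.5) {
    stop("dt * (k_on + k_off) = ", dt * (k_on + k_off),
         " >= 0.5: timestep too coarse for the rates")
  }
  structure(list(k_on = k_on, k_off = k_off, dt = dt,
                 n_frames = as.integer(n_frames),
                 n_bonds = as.integer(n_bonds), seed = as.integer(seed)),
            class = "markov_hbond_spec")
}

#' Simulate a Markov hydrogen-bond occupancy timeline
#'
#' Initial states are drawn from the stationary distribution; dwell times
#' in each state are geometric with the per-step switching probability
#' \eqn{1 - e^{-k\,dt}} (run-length simulation, exactly equivalent to the
#' frame-by-frame chain).  Bonds that never form within the window are
#' dropped, since an all-zero row carries no kinetic information.
#'
#' @param spec a \code{\link{markov_hbond_spec}}.
#' @return an \code{\link{hbond_timeline}} whose \code{bonds} table carries
#'   synthetic identities.
#' @export
make_markov_hbond_timeline <- function(spec) {
  stopifnot(inherits(spec, "markov_hbond_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)
  nf <- spec$n_frames
  p_stat <- spec$k_on / (spec$k_on + spec$k_off)
  # per-step switch probabilities out of each state
  p_switch <- c(`0` = 1 - exp(-spec$k_on * spec$dt),
                `1` = 1 - exp(-spec$k_off * spec$dt))
  occ <- matrix(0L, nrow = spec$n_bonds, ncol = nf)
  for (b in seq_len(spec$n_bonds)) {
    state <- rbinom(1, 1, p_stat)
    pos <- 1L
    while (pos <= nf) {
      # dwell = frames spent in `state` before switching (>= 1); rgeom
      # overflows to NA for near-zero switch rates, i.e. a dwell beyond
      # the window
      dwell <- 1L + rgeom(1, p_switch[[as.character(state)]])
      if (is.na(dwell) || dwell > nf) dwell <- nf
      end <- min(nf, pos + dwell - 1L)
      if (state == 1L) occ[b, pos:end] <- 1L
      pos <- end + 1L
      state <- 1L - state
    }
  }
  formed <- rowSums(occ) > 0
  if (!all(formed)) occ <- occ[formed, , drop = FALSE]
  bonds <- data.frame(donor_heavy = NA_integer_, hydrogen = NA_integer_,
                      acceptor_heavy = NA_integer_,
                      class = "synthetic",
                      id = paste0("markov_", seq_len(nrow(occ))),
                      stringsAsFactors = FALSE)
  hbond_timeline_obj(bonds, occ, spec$dt)
}

# ---------------------------------------------------------------------------
# Correlated displacement fields

#' Specification of a Gaussian displacement field with planted correlations
#'
#' @param target_C symmetric positive-semidefinite matrix with unit
#'   diagonal: the cross-correlation the sample matrix should converge to.
#' @param n_frames number of frames.
#' @param amplitudes optional per-residue RMS displacement (Angstrom,
#'   default 1); scales rows without changing correlations.
#' @param seed RNG seed.
#' @return object of class \code{correlated_field_spec}.
#' @export
correlated_field_spec <- function(target_C, n_frames = 1000L,
                                  amplitudes = NULL, seed = 1L) {
  target_C <- as.matrix(target_C)
  if (!isSymmetric(target_C, tol = 1e-10)) stop("target_C must be symmetric")
  if (any(abs(diag(target_C) - 1) > 1e-10)) {
    stop("target_C must have a unit diagonal")
  }
  if (any(abs(target_C) > 1 + 1e-10)) stop("target_C entries must lie in [-1, 1]")
  ev <- eigen(target_C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target_C is not positive semidefinite (most negative eigenvalue ",
         format(min(ev), digits = 4), ")")
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, nrow(target_C))
  stopifnot(length(amplitudes) == nrow(target_C), all(amplitudes > 0))
  structure(list(target_C = target_C, n_frames = as.integer(n_frames),
                 amplitudes = amplitudes, seed = as.integer(seed)),
            class = "correlated_field_spec")
}

#' Generate Gaussian residue displacements with a prescribed correlation
#'
#' White Gaussian noise is coloured by the symmetric matrix square root of
#' \code{target_C}; the same factor is applied independently to the x, y
#' and z components, so the 3-vector dot-product correlation of the field
#' converges to \code{target_C} as frames accumulate (and equals it exactly
#' for \eqn{\pm 1} entries).
#'
#' @param spec a \code{\link{correlated_field_spec}}.
#' @return object of class \code{displacement_field} (see
#'   \code{\link{displacement_field}}), with residue ids \code{1..N}.
#' @export
make_correlated_displacements <- function(spec) {
  stopifnot(inherits(spec, "correlated_field_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)
  n <- nrow(spec$target_C)
  nf <- spec$n_frames
  e <- eigen(spec$target_C, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n) %*% t(e$vectors)
  disp <- array(NA_real_, dim = c(n, nf, 3L))
  for (k in 1:3) {
    z <- matrix(rnorm(n * nf), nrow = n)
    disp[, , k] <- spec$amplitudes * (L %*% z)
  }
  # centre per residue/component so the field is a genuine displacement
  for (k in 1:3) disp[, , k] <- disp[, , k] - rowMeans(disp[, , k])
  displacement_field_obj(residue_ids = seq_len(n), displacements = disp,
                         superposed = FALSE)
}

# ---------------------------------------------------------------------------
# Toy hydrogen-bond geometries

#' Build a single-frame donor/hydrogen/acceptor toy geometry
#'
#' Places a water-like donor (O with two H) at the origin and an acceptor
#' oxygen at distance \code{d_da} from the donor, at angle
#' \code{angle_deg} (measured at the donor between the donor-hydrogen and
#' donor-acceptor directions).  The hydrogen sits \code{r_dh} from the
#' donor along x.  The truth flag is computed from the layout parameters
#' against the geometric criterion - never from the detector - so detector
#' tests have constructive ground truth.
#'
#' @param d_da donor-acceptor heavy-atom distance (Angstrom).
#' @param angle_deg donor angle between the O-H direction and the
#'   donor-acceptor direction (degrees).
#' @param r_dh covalent O-H bond length (Angstrom, default 1.0).
#' @param criteria an \code{\link{hbond_criteria}} used only to evaluate
#'   the truth flag.
#' @return list with the single-frame \code{trajectory} (\code{traj}), the
#'   implied hydrogen-acceptor distance \code{r_ha}, the donor / hydrogen /
#'   acceptor atom indices, and \code{is_hbond}, the constructive truth.
#' @export
make_toy_hbond_frame <- function(d_da = 2.8, angle_deg = 0, r_dh = 1.0,
                                 criteria = hbond_criteria()) {
  stopifnot(d_da > 0, r_dh > 0, angle_deg >= 0, angle_deg <= 180)
  if (d_da <= r_dh && angle_deg == 0) {
    # acceptor would sit inside the covalent bond
    if (d_da <= r_dh) stop("impossible geometry: d_da <= r_dh on the bond axis")
  }
  th <- angle_deg * pi / 180
  donor <- c(0, 0, 0)
  hyd <- c(r_dh, 0, 0)
  acc <- d_da * c(cos(th), sin(th), 0)
  # spectator hydrogen pointing away so the donor looks like water
  h2 <- r_dh * c(cos(115 * pi / 180), -sin(115 * pi / 180), 0)
  coords <- rbind(donor, hyd, h2, acc)
  atoms <- data.frame(name = c("OW", "HW1", "HW2", "OW"),
                      element = c("O", "H", "H", "O"),
                      resno = c(1L, 1L, 1L, 2L),
                      resname = "HOH", stringsAsFactors = FALSE)
  traj <- trajectory(atoms, coords, dt = 1)
  r_ha <- sqrt(sum((hyd - acc)^2))
  truth <- (d_da < criteria$max_heavy_distance) &&
           (r_ha < criteria$max_oh_distance) &&
           (angle_deg < criteria$max_angle)
  list(traj = traj, donor = 1L, hydrogen = 2L, acceptor = 4L,
       r_ha = r_ha, d_da = d_da, angle_deg = angle_deg,
       is_hbond = truth)
}

#' Scatter water molecules around a small rigid solute
#'
#' Random test system for shell selection and detector/oracle comparisons:
#' a compact cluster of protein-like atoms surrounded by rigid SPC-like
#' waters at random positions and orientations.
#'
#' @param n_waters number of water molecules.
#' @param n_protein_atoms number of solute atoms (alanine-like names).
#' @param radius waters are placed uniformly within this radius (Angstrom)
#'   of the origin.
#' @param seed RNG seed.
#' @return a single-frame \code{\link{trajectory}}.
#' @export
make_random_water_frame <- function(n_waters = 30L, n_protein_atoms = 10L,
                                    radius = 12, seed = 1L) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  coords <- list(); atoms <- list()
  if (n_protein_atoms > 0) {
    pr_names <- rep(c("N", "CA", "C", "O", "CB"),
                    length.out = n_protein_atoms)
    pr_elem <- .element_from_name(pr_names)
    coords[[1]] <- matrix(rnorm(n_protein_atoms * 3, 0, 1.5), ncol = 3)
    atoms[[1]] <- data.frame(name = pr_names, element = pr_elem,
                             resno = rep(seq_len(ceiling(n_protein_atoms / 5)),
                                         each = 5)[seq_len(n_protein_atoms)],
                             resname = "ALA", stringsAsFactors = FALSE)
  }
  for (w in seq_len(n_waters)) {
    centre <- runif(3, -radius, radius)
    # random orthonormal frame for the two O-H vectors (104.5 deg apart)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    perp <- rnorm(3); perp <- perp - sum(perp * ax) * ax
    perp <- perp / sqrt(sum(perp^2))
    half <- 104.5 / 2 * pi / 180
    h1 <- centre + 0.9572 * (cos(half) * ax + sin(half) * perp)
    h2 <- centre + 0.9572 * (cos(half) * ax - sin(half) * perp)
    coords[[length(coords) + 1]] <- rbind(centre, h1, h2)
    atoms[[length(atoms) + 1]] <-
      data.frame(name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
                 resno = 1000L + w, resname = "HOH",
                 stringsAsFactors = FALSE)
  }
  trajectory(do.call(rbind, atoms), do.call(rbind, coords), dt = 1)
}

# ---------------------------------------------------------------------------
# RNG hygiene: generators take explicit seeds but must not clobber the
# caller's RNG stream.

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
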