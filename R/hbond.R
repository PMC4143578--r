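# Geometric hydrogen-bond detection and kinetics.  A bond D-H...A is
# counted when, simultaneously, the donor-acceptor heavy-atom distance is
# below 3.5 A, the hydrogen-acceptor distance is below 2.6 A, and the angle
# at the donor between the D->H and D->A directions is below 30 degrees
# (all strict inequalities).  The intermittent occupancy autocorrelation
# C(tau) = <hb(t+tau) hb(t)> / <hb^2> decays with the bond lifetime.

#' Geometric hydrogen-bond criterion
#'
#' @param max_heavy_distance donor-acceptor heavy-atom cutoff (Angstrom).
#' @param max_oh_distance hydrogen-acceptor cutoff (Angstrom).
#' @param max_angle donor-angle cutoff in degrees (angle at the donor
#'   between the donor-hydrogen and donor-acceptor directions; the
#'   acceptance cone convention).  \code{angle_at = "hydrogen"} switches to
#'   the supplement-style angle at the hydrogen between H->D and H->A.
#' @param angle_at vertex of the angular criterion.
#' @param heavy_mode \code{"atom"} measures the heavy-atom pair distance
#'   (default); \code{"water-com"} uses molecular centres of mass when both
#'   partners are water.
#' @return object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.5, max_oh_distance = 2.6,
                           max_angle = 30,
                           angle_at = c("donor", "hydrogen"),
                           heavy_mode = c("atom", "water-com")) {
  angle_at <- match.arg(angle_at)
  heavy_mode <- match.arg(heavy_mode)
  stopifnot(max_heavy_distance > 0, max_oh_distance > 0,
            max_angle > 0, max_angle < 90)
  structure(list(max_heavy_distance = max_heavy_distance,
                 max_oh_distance = max_oh_distance,
                 max_angle = max_angle, angle_at = angle_at,
                 heavy_mode = heavy_mode),
            class = "hbond_criteria")
}

#' Assign donors, acceptors and their hydrogens
#'
#' Donors are N/O heavy atoms carrying at least one hydrogen within the
#' covalent cutoff (1.2 Angstrom) in the reference frame; acceptors are
#' all N/O atoms.  Each hydrogen is attached to its nearest heavy atom;
#' hydrogens with no heavy atom within the cutoff are excluded with a
#' warning.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param frame reference frame for the covalent assignment (bond
#'   topology is assumed constant, as under bond constraints).
#' @param covalent_cutoff H-to-heavy-atom attachment distance (Angstrom).
#' @return list with \code{donors}, \code{acceptors}, and a data.frame
#'   \code{hydrogens} mapping each hydrogen to its \code{donor}.
#' @export
assign_donors_acceptors <- function(traj, frame = 1L,
                                    covalent_cutoff = 1.2) {
  at <- traj$atoms
  heavy_no <- which(at$element %in% c("N", "O"))
  hyd <- which(at$element == "H")
  if (length(heavy_no) == 0L) stop("no N/O atoms in the system")
  co <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(co))) co <- matrix(co, ncol = 3)
  hmap <- data.frame(hydrogen = integer(0), donor = integer(0))
  orphans <- 0L
  if (length(hyd) > 0L) {
    heavy_all <- which(at$element != "H")
    d <- .pair_dist(co[hyd, , drop = FALSE],
                    co[heavy_all, , drop = FALSE], traj$box)
    nearest <- apply(d, 1, which.min)
    mind <- d[cbind(seq_along(hyd), nearest)]
    ok <- mind <= covalent_cutoff
    orphans <- sum(!ok)
    hmap <- data.frame(hydrogen = hyd[ok], donor = heavy_all[nearest[ok]])
  }
  if (orphans > 0L) {
    warning(orphans, " hydrogen(s) with no heavy atom within ",
            covalent_cutoff, " A excluded")
  }
  donors <- sort(unique(hmap$donor[hmap$donor %in% heavy_no]))
  hmap <- hmap[hmap$donor %in% donors, , drop = FALSE]
  list(donors = donors, acceptors = heavy_no, hydrogens = hmap)
}

.bond_class <- function(cat_d, cat_a) {
  ifelse(cat_d == "protein" & cat_a == "protein", "protein-protein",
  ifelse(cat_d == "water" & cat_a == "water", "water-water",
  ifelse((cat_d == "protein" & cat_a == "water") |
         (cat_d == "water" & cat_a == "protein"), "protein-water",
         "other")))
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the three-part geometric criterion to every
#' donor-hydrogen / acceptor pair; the acceptor may not be the donor's own
#' heavy atom.  Bonds are classified by the partner categories
#' (protein-protein, protein-water, water-water, other).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param frame frame index.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param scope optional class filter, any subset of
#'   \code{c("protein-protein", "protein-water", "water-water")}.
#' @param assignment optional precomputed
#'   \code{\link{assign_donors_acceptors}} result (reused across frames).
#' @return data.frame with one row per bond: \code{donor_heavy},
#'   \code{hydrogen}, \code{acceptor_heavy}, the three geometric values,
#'   and \code{class}.
#' @export
detect_hbonds_frame <- function(traj, frame = 1L,
                                criteria = hbond_criteria(),
                                scope = NULL, assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_donors_acceptors(traj)
  hm <- assignment$hydrogens
  acc <- assignment$acceptors
  empty <- data.frame(donor_heavy = integer(0), hydrogen = integer(0),
                      acceptor_heavy = integer(0), r_da = numeric(0),
                      r_ha = numeric(0), angle = numeric(0),
                      class = character(0))
  if (nrow(hm) == 0L || length(acc) == 0L) {
    warning("no donors or acceptors available")
    return(empty)
  }
  co <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(co))) co <- matrix(co, ncol = 3)
  at <- traj$atoms
  # pairwise distances donor-heavy -> acceptors and hydrogen -> acceptors
  d_da <- .pair_dist(co[hm$donor, , drop = FALSE],
                     co[acc, , drop = FALSE], traj$box)
  d_ha <- .pair_dist(co[hm$hydrogen, , drop = FALSE],
                     co[acc, , drop = FALSE], traj$box)
  heavy_dist <- d_da
  if (criteria$heavy_mode == "water-com") {
    heavy_dist <- .water_com_dist(traj, frame, hm$donor, acc, d_da)
  }
  cand <- which(heavy_dist < criteria$max_heavy_distance &
                d_ha < criteria$max_oh_distance, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    # drop self pairs (acceptor is the donor's own heavy atom)
    self <- acc[cand[, 2]] == hm$donor[cand[, 1]]
    cand <- cand[!self, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty)
  di <- hm$donor[cand[, 1]]
  hi <- hm$hydrogen[cand[, 1]]
  ai <- acc[cand[, 2]]
  ang <- .hbond_angle(co, di, hi, ai, criteria$angle_at, traj$box)
  keep <- ang < criteria$max_angle
  res <- data.frame(donor_heavy = di[keep], hydrogen = hi[keep],
                    acceptor_heavy = ai[keep],
                    r_da = d_da[cand[keep, , drop = FALSE]],
                    r_ha = d_ha[cand[keep, , drop = FALSE]],
                    angle = ang[keep],
                    class = .bond_class(at$category[di[keep]],
                                        at$category[ai[keep]]),
                    stringsAsFactors = FALSE)
  if (!is.null(scope)) res <- res[res$class %in% scope, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Angle (degrees) at the donor between D->H and D->A, or at the hydrogen
# between H->D and H->A.
.hbond_angle <- function(co, di, hi, ai, angle_at, box = NULL) {
  mi <- function(v) {
    if (!is.null(box)) {
      for (k in 1:3) v[, k] <- v[, k] - box[k] * round(v[, k] / box[k])
    }
    v
  }
  if (angle_at == "donor") {
    v1 <- mi(co[hi, , drop = FALSE] - co[di, , drop = FALSE])
    v2 <- mi(co[ai, , drop = FALSE] - co[di, , drop = FALSE])
  } else {
    v1 <- mi(co[di, , drop = FALSE] - co[hi, , drop = FALSE])
    v2 <- mi(co[ai, , drop = FALSE] - co[hi, , drop = FALSE])
  }
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# Replace the heavy-pair distance by the molecular centre-of-mass distance
# for water-water pairs (masses: O 15.999, H 1.008).
.water_com_dist <- function(traj, frame, donors, acceptors, d_da) {
  at <- traj$atoms
  co <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(co))) co <- matrix(co, ncol = 3)
  mass <- ifelse(at$element == "H", 1.008,
          ifelse(at$element == "O", 15.999,
          ifelse(at$element == "N", 14.007, 12.011)))
  com_of <- function(idx) {
    resno <- at$resno[idx]
    mol <- which(at$resno == resno & at$category == "water")
    colSums(co[mol, , drop = FALSE] * mass[mol]) / sum(mass[mol])
  }
  out <- d_da
  dw <- at$category[donors] == "water"
  aw <- at$category[acceptors] == "water"
  for (i in which(dw)) {
    cd <- com_of(donors[i])
    for (j in which(aw)) {
      if (at$resno[acceptors[j]] == at$resno[donors[i]]) next
      ca <- com_of(acceptors[j])
      d <- cd - ca
      if (!is.null(traj$box)) {
        d <- d - traj$box * round(d / traj$box)
      }
      out[i, j] <- sqrt(sum(d * d))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Timelines

# internal constructor shared with the Markov generator
hbond_timeline_obj <- function(bonds, occupancy, dt) {
  stopifnot(nrow(bonds) == nrow(occupancy), dt > 0,
            all(occupancy %in% c(0L, 1L)))
  if (nrow(occupancy) > 0 && any(rowSums(occupancy) == 0)) {
    stop("timeline contains a bond never present in any frame")
  }
  structure(list(bonds = bonds, occupancy = occupancy, dt = dt),
            class = "hbond_timeline")
}

#' @export
print.hbond_timeline <- function(x, ...) {
  cat("hbond timeline:", nrow(x$occupancy), "bonds x",
      ncol(x$occupancy), "frames, dt =", x$dt, "ps\n")
  if (nrow(x$bonds) > 0) {
    cat("  mean occupancy:", signif(mean(x$occupancy), 4), "\n")
  }
  invisible(x)
}

#' Track hydrogen-bond occupancy across frames
#'
#' Runs the detector on every frame and unions the bond identities (keyed
#' by donor-heavy, hydrogen, acceptor-heavy); occupancy is 1 in the frames
#' where the bond is detected.  For the interfacial water-water scope with
#' a \code{shell_cutoff}, the hydration shell is evaluated per frame and
#' both partner waters must be members.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param scope class filter as in \code{\link{detect_hbonds_frame}}
#'   (NULL keeps every class).
#' @param shell_cutoff optional hydration-shell radius (Angstrom) applied
#'   to water-water bonds.
#' @return an \code{hbond_timeline}.
#' @export
hbond_timeline <- function(traj, criteria = hbond_criteria(), scope = NULL,
                           shell_cutoff = NULL) {
  nf <- n_frames(traj)
  assignment <- assign_donors_acceptors(traj)
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    det <- detect_hbonds_frame(traj, f, criteria, scope, assignment)
    if (!is.null(shell_cutoff) && nrow(det) > 0) {
      sh <- shell_waters(traj, f, shell_cutoff)
      if (sh$n_waters == 0L) {
        warning("hydration shell empty at frame ", f)
      }
      member_res <- sh$water_resno
      at <- traj$atoms
      ww <- det$class == "water-water"
      ok <- !ww | (at$resno[det$donor_heavy] %in% member_res &
                   at$resno[det$acceptor_heavy] %in% member_res)
      det <- det[ok, , drop = FALSE]
    }
    per_frame[[f]] <- det
  }
  keys <- lapply(per_frame, function(d) {
    if (nrow(d) == 0) character(0)
    else paste(d$donor_heavy, d$hydrogen, d$acceptor_heavy, sep = "_")
  })
  all_keys <- unique(unlist(keys))
  if (length(all_keys) == 0L) {
    warning("no hydrogen bonds detected in any frame")
    return(hbond_timeline_obj(
      data.frame(donor_heavy = integer(0), hydrogen = integer(0),
                 acceptor_heavy = integer(0), class = character(0),
                 id = character(0)),
      matrix(0L, 0, nf), traj$dt))
  }
  occ <- matrix(0L, nrow = length(all_keys), ncol = nf,
                dimnames = list(all_keys, NULL))
  for (f in seq_len(nf)) occ[keys[[f]], f] <- 1L
  first <- match(all_keys, unlist(keys))
  flat <- do.call(rbind, per_frame)
  bonds <- data.frame(donor_heavy = flat$donor_heavy[first],
                      hydrogen = flat$hydrogen[first],
                      acceptor_heavy = flat$acceptor_heavy[first],
                      class = flat$class[first],
                      id = all_keys, stringsAsFactors = FALSE)
  hbond_timeline_obj(bonds, occ, traj$dt)
}

#' Hydrogen-bond occupancy autocorrelation function
#'
#' Intermittent definition (default): \eqn{C(\tau) = \langle
#' hb_i(t+\tau)\,hb_i(t)\rangle / \langle hb_i^2\rangle}, time-origin
#' averaged per bond, normalized per bond so that \eqn{C_i(0) = 1}, then
#' averaged over bonds (\code{pooled = TRUE} instead sums numerators and
#' denominators across bonds before dividing).  A broken-then-reformed
#' bond contributes again at later times; the \code{"continuous"} variant
#' treats the first rupture as absorbing, counting only unbroken
#' stretches.
#'
#' @param timeline an \code{hbond_timeline}.
#' @param max_lag maximum lag (ps), below the timeline duration.
#' @param type \code{"intermittent"} or \code{"continuous"}.
#' @param pooled pool numerators/denominators across bonds instead of
#'   averaging per-bond-normalized curves.
#' @param estimator lag normalization, as in \code{\link{autocorrelation}}.
#' @return a \code{\link{correlation_series}}.
#' @export
hbacf <- function(timeline, max_lag, type = c("intermittent", "continuous"),
                  pooled = FALSE, estimator = c("unbiased", "biased")) {
  type <- match.arg(type)
  estimator <- match.arg(estimator)
  stopifnot(inherits(timeline, "hbond_timeline"))
  occ <- timeline$occupancy
  dt <- timeline$dt
  nf <- ncol(occ)
  L <- as.integer(round(max_lag / dt))
  if (L >= nf) stop("max_lag exceeds timeline duration")
  if (nrow(occ) == 0L || sum(occ) == 0L) {
    stop("timeline has no occupied frames")
  }
  num <- matrix(NA_real_, nrow(occ), L + 1L)
  if (type == "intermittent") {
    for (b in seq_len(nrow(occ))) {
      num[b, ] <- .acov_fft(as.numeric(occ[b, ]), L, estimator)
    }
  } else {
    # survival counting over uninterrupted runs: a run of r frames offers
    # max(0, r - k) origins still intact after k steps
    denom_origin <- if (estimator == "unbiased") nf - 0:L else rep(nf, L + 1L)
    for (b in seq_len(nrow(occ))) {
      r <- rle(as.integer(occ[b, ]))
      runs <- r$lengths[r$values == 1L]
      cnt <- numeric(L + 1L)
      for (rl in runs) {
        k <- 0:min(L, rl - 1L)
        cnt[k + 1L] <- cnt[k + 1L] + (rl - k)
      }
      num[b, ] <- cnt / denom_origin
    }
  }
  if (pooled) {
    vals <- colSums(num) / sum(num[, 1])
  } else {
    vals <- colMeans(num / num[, 1])
  }
  correlation_series(lags = (0:L) * dt, values = vals, normalized = TRUE,
                     n_samples = nf - (0:L), dt = dt)
}

#' Fit an exponential hydrogen-bond lifetime
#'
#' Least-squares fit of \eqn{C(\tau) = c_\infty + (1 - c_\infty)
#' e^{-\tau/\tau_{hb}}} over a lag window; the plateau \eqn{c_\infty}
#' absorbs the stationary occupancy a two-state process relaxes to, or can
#' be pinned to zero.
#'
#' @param acf a normalized \code{\link{correlation_series}}.
#' @param fit_window \code{c(lo, hi)} lag window in ps.
#' @param fix_plateau NULL to fit the plateau freely, or a value in
#'   [0, 1) to pin it (0 gives the plateau-free pure exponential).
#' @return object of class \code{lifetime_fit}: \code{tau} (ps),
#'   \code{plateau}, \code{fit_window}, \code{residual_rms}.
#' @export
fit_hbond_lifetime <- function(acf, fit_window = c(0.5, 8),
                               fix_plateau = NULL) {
  stopifnot(inherits(acf, "correlation_series"), acf$normalized)
  keep <- acf$lags >= fit_window[1] & acf$lags <= fit_window[2]
  if (sum(keep) < 4L) stop("fit window contains fewer than 4 lags")
  x <- acf$lags[keep]
  y <- acf$values[keep]
  if (diff(range(y)) < 1e-10) {
    stop("correlation function shows no decay over the fit window")
  }
  # starting values from a log-linear pass above a provisional plateau
  p0 <- if (is.null(fix_plateau)) max(0, min(y) - 0.05 * diff(range(y)))
        else fix_plateau
  ypos <- pmax(y - p0, 1e-8)
  lf <- lm(log(ypos) ~ x)
  tau0 <- -1 / unname(coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(fit_window) / 2
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  if (is.null(fix_plateau)) {
    fit <- minpack.lm::nls.lm(
      par = c(p = max(p0, 1e-4), tau = tau0),
      lower = c(0, 1e-6), upper = c(0.999, Inf),
      fn = function(par) par[1] + (1 - par[1]) * exp(-x / par[2]) - y,
      control = ctrl)
    plateau <- unname(fit$par["p"])
  } else {
    fit <- minpack.lm::nls.lm(
      par = c(tau = tau0), lower = 1e-6, upper = Inf,
      fn = function(par) {
        fix_plateau + (1 - fix_plateau) * exp(-x / par[1]) - y
      },
      control = ctrl)
    plateau <- fix_plateau
  }
  if (fit$info %in% c(0, 9) || !is.finite(fit$par[["tau"]])) {
    stop("lifetime fit did not converge (", fit$message,
         "); residual rms ", signif(sqrt(fit$deviance / length(y)), 3))
  }
  structure(list(tau = unname(fit$par[["tau"]]), plateau = plateau,
                 fit_window = fit_window,
                 residual_rms = sqrt(mean(fit$fvec^2)),
                 fit = fit),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("H-bond lifetime fit: tau = ", signif(x$tau, 4), " ps, plateau = ",
      signif(x$plateau, 4), " (window ", x$fit_window[1], "-",
      x$fit_window[2], " ps, residual rms ",
      signif(x$residual_rms, 3), ")\n", sep = "")
  invisible(x)
}

#' @importFrom stats residuals
NULL
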