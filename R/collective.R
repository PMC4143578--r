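# Correlated residue fluctuations: rigid-body superposition, displacement
# fields, the residue cross-correlation matrix
# C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), its thresholded
# network, and essential-dynamics PCA of C-alpha motion.

#' Rigid-body superposition of trajectory frames
#'
#' Each frame is least-squares fitted (optimal rotation + translation,
#' Kabsch/SVD) onto the reference over the fit selection; the transform is
#' applied to all atoms.  With \code{reference = "mean"} the frames are
#' first fitted to frame 1, then refitted once to the resulting mean
#' structure.  Removing global rotation and translation before computing
#' displacement correlations or PCA keeps rigid-body motion from
#' masquerading as internal correlation.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selection fit atoms (default all); at least 3, non-collinear.
#' @param reference \code{"mean"} or \code{"frame0"} (frame 1).
#' @return the superposed trajectory (velocities, if any, are dropped:
#'   they are no longer consistent with the rotated coordinates).
#' @export
superpose <- function(traj, selection = NULL,
                      reference = c("mean", "frame0")) {
  reference <- match.arg(reference)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (length(selection) < 3L) stop("need at least 3 fit atoms")
  ref_xyz <- traj$coords[1, selection, , drop = TRUE]
  if (.collinear(ref_xyz)) stop("fit selection is (near-)collinear")
  out <- .fit_all(traj$coords, selection, ref_xyz)
  if (reference == "mean") {
    mean_ref <- apply(out[, selection, , drop = FALSE], c(2, 3), mean)
    out <- .fit_all(out, selection, mean_ref)
  }
  traj$coords <- out
  traj$velocities <- NULL
  traj$derived_velocities <- FALSE
  traj
}

.collinear <- function(x, tol = 1e-8) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)$d
  sv[2] < tol * max(sv[1], 1)
}

.fit_all <- function(coords, selection, ref_sel) {
  nf <- dim(coords)[1]
  out <- coords
  ref_cen <- colMeans(ref_sel)
  ref0 <- sweep(ref_sel, 2, ref_cen)
  for (f in seq_len(nf)) {
    mob <- coords[f, selection, , drop = TRUE]
    mob_cen <- colMeans(mob)
    R <- .kabsch(sweep(mob, 2, mob_cen), ref0)
    frame <- sweep(coords[f, , , drop = TRUE], 2, mob_cen)
    out[f, , ] <- sweep(frame %*% R, 2, ref_cen, "+")
  }
  out
}

# Optimal rotation matrix R (applied as x %*% R) minimizing |x R - y|^2
# for centred coordinate sets, with proper-rotation (det +1) correction.
.kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# ---------------------------------------------------------------------------
# Displacement fields and cross-correlation

# internal constructor shared with the synthetic generator
displacement_field_obj <- function(residue_ids, displacements, superposed) {
  stopifnot(length(dim(displacements)) == 3L, dim(displacements)[3] == 3L,
            length(residue_ids) == dim(displacements)[1])
  structure(list(residue_ids = residue_ids, displacements = displacements,
                 superposed = isTRUE(superposed)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$displacements)
  cat("displacement field:", d[1], "residues x", d[2], "frames",
      if (x$superposed) "(superposed)", "\n")
  invisible(x)
}

#' Per-residue displacement field
#'
#' \eqn{\Delta r_i(t) = r_i(t) - \langle r_i\rangle_t} for each selected
#' atom (one per residue for the default C-alpha selection), after
#' optional rigid-body superposition.
#'
#' @param traj a \code{\link{trajectory}} with at least 2 frames.
#' @param selection atom indices, one per residue (default: C-alpha).
#' @param superpose_first remove global rotation/translation first.
#' @return object of class \code{displacement_field}.
#' @export
displacement_field <- function(traj, selection = NULL,
                               superpose_first = TRUE) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(traj, "calpha")
  if (superpose_first) traj <- superpose(traj, selection, "mean")
  x <- traj$coords[, selection, , drop = FALSE]
  mean_pos <- apply(x, c(2, 3), mean)
  nf <- dim(x)[1]
  disp <- array(NA_real_, dim = c(length(selection), nf, 3L))
  for (k in 1:3) {
    disp[, , k] <- t(x[, , k]) - mean_pos[, k]
  }
  displacement_field_obj(residue_ids = traj$atoms$resno[selection],
                         displacements = disp,
                         superposed = superpose_first)
}

#' Residue cross-correlation matrix
#'
#' \eqn{C_{ij} = \langle\Delta r_i\cdot\Delta r_j\rangle /
#' (\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle)^{1/2}} with
#' full 3-vector dot products in the numerator.  +1 marks completely
#' correlated, -1 completely anti-correlated, 0 uncorrelated motion.
#' Residues with zero displacement variance get zeroed off-diagonal rows
#' (diagonal kept at 1) and a warning, keeping the matrix usable for
#' network construction.
#'
#' @param field a \code{displacement_field}.
#' @return object of class \code{crosscorr_matrix} with the matrix
#'   \code{C}, \code{residue_ids}, and per-residue mean square amplitudes
#'   \code{amplitude} (Angstrom^2).
#' @export
cross_correlation_matrix <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  d <- field$displacements
  nf <- dim(d)[2]
  if (nf < 2L) stop("need at least 2 frames")
  num <- matrix(0, dim(d)[1], dim(d)[1])
  for (k in 1:3) num <- num + tcrossprod(d[, , k]) / nf
  amp <- diag(num)
  zero <- amp <= 1e-300
  if (any(zero)) {
    warning(sum(zero), " residue(s) with zero displacement variance; ",
            "their correlations set to 0")
  }
  scale <- sqrt(ifelse(zero, 1, amp))
  C <- num / outer(scale, scale)
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  structure(list(C = C, residue_ids = field$residue_ids, amplitude = amp),
            class = "crosscorr_matrix")
}

#' @export
print.crosscorr_matrix <- function(x, ...) {
  n <- nrow(x$C)
  off <- x$C[upper.tri(x$C)]
  cat("cross-correlation matrix:", n, "residues; |C_ij| range ",
      signif(min(abs(off)), 3), "..", signif(max(abs(off)), 3), "\n")
  invisible(x)
}

#' Thresholded residue correlation network
#'
#' Nodes are residues sized by their mean square fluctuation; edges join
#' pairs whose correlation magnitude reaches the threshold (0.35 for the
#' stricter network view, 0.25 for the permissive one).  Edge weight is
#' \eqn{|C_{ij}|}; the sign is kept as an edge attribute.
#'
#' @param ccm a \code{crosscorr_matrix}.
#' @param threshold correlation magnitude cutoff in (0, 1].
#' @param keep_isolated retain residues with no edge as isolated nodes.
#' @param signed_weight use the signed \eqn{C_{ij}} as weight instead of
#'   the magnitude.
#' @return an \pkg{igraph} graph with vertex attributes \code{residue}
#'   and \code{amplitude}, edge attributes \code{weight} and \code{sign},
#'   and graph attribute \code{threshold}.
#' @export
build_network <- function(ccm, threshold = 0.35, keep_isolated = FALSE,
                          signed_weight = FALSE) {
  stopifnot(inherits(ccm, "crosscorr_matrix"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  C <- ccm$C
  n <- nrow(C)
  sel <- which(abs(C) >= threshold & upper.tri(C), arr.ind = TRUE)
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      weight = abs(C[sel]), sign = sign(C[sel]))
  if (!signed_weight) {
    g_edges <- edges
  } else {
    g_edges <- edges
    g_edges$weight <- g_edges$weight * g_edges$sign
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "residue", value = ccm$residue_ids)
  g <- igraph::set_vertex_attr(g, "amplitude", value = ccm$amplitude)
  g <- igraph::set_vertex_attr(g, "name",
                               value = as.character(ccm$residue_ids))
  if (nrow(g_edges) > 0) {
    g <- igraph::add_edges(g, t(as.matrix(g_edges[, c("i", "j")])),
                           weight = g_edges$weight, sign = g_edges$sign)
  }
  if (!keep_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Write a correlation network as GraphML or edge-list TSV
#'
#' @param g graph from \code{\link{build_network}}.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(g, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# PCA of C-alpha motion

#' Essential-dynamics PCA of selected-atom coordinates
#'
#' Eigendecomposition of the 3N x 3N covariance of (optionally superposed)
#' coordinates, unweighted.  Square fluctuations of mode k are the
#' per-residue sums of the squared mode components scaled by the
#' eigenvalue, so they sum to that mode's variance; over all modes they
#' recover the per-residue variance (trace identity).
#'
#' @param traj a \code{\link{trajectory}} with at least 2 frames.
#' @param selection atom indices (default C-alpha).
#' @param superpose_first remove rigid-body motion first.
#' @return object of class \code{pca_result}: \code{eigenvalues}
#'   (descending, Angstrom^2), orthonormal \code{modes} (3N x 3N),
#'   \code{mean_structure}, \code{projections} (frames x modes),
#'   \code{residue_ids}.
#' @export
pca_modes <- function(traj, selection = NULL, superpose_first = TRUE) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(traj, "calpha")
  if (superpose_first) traj <- superpose(traj, selection, "mean")
  nf <- n_frames(traj)
  n <- length(selection)
  if (nf <= 3 * n) {
    warning("fewer frames (", nf, ") than coordinate dimensions (", 3 * n,
            "): covariance is rank-deficient")
  }
  X <- matrix(NA_real_, nrow = nf, ncol = 3L * n)
  for (k in 1:3) X[, seq(k, 3L * n, by = 3L)] <- traj$coords[, selection, k]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / nf
  e <- eigen(S, symmetric = TRUE)
  structure(list(eigenvalues = e$values, modes = e$vectors,
                 mean_structure = mu,
                 projections = Xc %*% e$vectors,
                 residue_ids = traj$atoms$resno[selection],
                 selection = selection),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$eigenvalues
  cat("PCA:", length(ev), "modes;",
      "PC1 explains", signif(100 * ev[1] / sum(pmax(ev, 0)), 3), "% of",
      signif(sum(pmax(ev, 0)), 4), "A^2 total variance\n")
  invisible(x)
}

#' Per-residue square fluctuations of a principal mode
#'
#' @param pca a \code{pca_result}.
#' @param mode mode index (1 = PC1).
#' @return data.frame with \code{residue} and \code{square_fluctuation}
#'   (Angstrom^2).
#' @export
square_fluctuations <- function(pca, mode = 1L) {
  stopifnot(inherits(pca, "pca_result"),
            mode >= 1L, mode <= ncol(pca$modes))
  v <- pca$modes[, mode]
  n <- length(v) / 3L
  per_res <- rowSums(matrix(v^2, nrow = n, byrow = TRUE))
  data.frame(residue = pca$residue_ids,
             square_fluctuation = pca$eigenvalues[mode] * per_res)
}

#' Project a trajectory onto a principal mode
#'
#' Centres the trajectory's selected coordinates with the PCA's stored
#' mean and projects onto the requested mode; for the trajectory the PCA
#' was built from, the projection variance equals the eigenvalue.
#'
#' @param traj a \code{\link{trajectory}} (already superposed consistently
#'   with the PCA), or NULL to use the PCA's stored projections.
#' @param pca a \code{pca_result}.
#' @param mode mode index.
#' @return numeric time series of projections (Angstrom).
#' @export
project_trajectory <- function(traj = NULL, pca, mode = 1L) {
  stopifnot(inherits(pca, "pca_result"),
            mode >= 1L, mode <= ncol(pca$modes))
  if (is.null(traj)) return(pca$projections[, mode])
  selection <- pca$selection
  if (max(selection) > n_atoms(traj)) {
    stop("trajectory does not contain the atoms the PCA was built on")
  }
  n <- length(selection)
  X <- matrix(NA_real_, nrow = n_frames(traj), ncol = 3L * n)
  for (k in 1:3) X[, seq(k, 3L * n, by = 3L)] <- traj$coords[, selection, k]
  if (ncol(X) != length(pca$mean_structure)) {
    stop("selection size does not match the PCA input")
  }
  sweep(X, 2, pca$mean_structure) %*% pca$modes[, mode]
}

#' Write a cross-correlation matrix as TSV with residue-id headers
#'
#' @param ccm a \code{crosscorr_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_crosscorr_tsv <- function(ccm, path) {
  m <- as.data.frame(ccm$C)
  names(m) <- ccm$residue_ids
  m <- cbind(residue = ccm$residue_ids, m)
  write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
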