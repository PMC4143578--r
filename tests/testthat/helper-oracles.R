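# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain double loops and explicit trigonometry.

# O(n^2) autocorrelation of a vector, averaging over valid time origins.
oracle_autocorrelation <- function(x, max_lag_frames) {
  n <- length(x)
  sapply(0:max_lag_frames, function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k)
  })
}

# All-triples hydrogen-bond scan: for every hydrogen, attach it to the
# nearest non-hydrogen atom (within the covalent cutoff), then test every
# N/O acceptor against the three geometric criteria.
oracle_detect_hbonds <- function(traj, frame = 1, max_da = 3.5,
                                 max_ha = 2.6, max_angle = 30,
                                 covalent = 1.2) {
  at <- traj$atoms
  co <- traj$coords[frame, , ]
  if (is.null(dim(co))) co <- matrix(co, ncol = 3)
  dist3 <- function(i, j) sqrt(sum((co[i, ] - co[j, ])^2))
  hyd <- which(at$element == "H")
  heavy <- which(at$element != "H")
  no <- which(at$element %in% c("N", "O"))
  out <- NULL
  for (h in hyd) {
    dd <- sapply(heavy, function(j) dist3(h, j))
    if (min(dd) > covalent) next
    d <- heavy[which.min(dd)]
    if (!(at$element[d] %in% c("N", "O"))) next
    for (a in no) {
      if (a == d) next
      if (!(dist3(d, a) < max_da)) next
      if (!(dist3(h, a) < max_ha)) next
      v1 <- co[h, ] - co[d, ]
      v2 <- co[a, ] - co[d, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (!(ang < max_angle)) next
      out <- rbind(out, c(d, h, a))
    }
  }
  if (is.null(out)) {
    matrix(integer(0), ncol = 3,
           dimnames = list(NULL, c("donor", "hydrogen", "acceptor")))
  } else {
    colnames(out) <- c("donor", "hydrogen", "acceptor")
    out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  }
}

# Brute-force shell membership: min over all protein atoms of the
# water-oxygen distance, no vectorization tricks.
oracle_shell_members <- function(traj, frame, cutoff) {
  at <- traj$atoms
  co <- traj$coords[frame, , ]
  prot <- which(at$category == "protein")
  wox <- which(at$category == "water" & at$element == "O")
  keep <- sapply(wox, function(w) {
    dmin <- min(sapply(prot, function(p) sqrt(sum((co[w, ] - co[p, ])^2))))
    dmin <= cutoff
  })
  wox[keep]
}

# Two-atom trajectory whose inter-atom vector is fixed by the caller.
make_vector_traj <- function(u, dt) {
  nf <- nrow(u)
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, ] <- u
  trajectory(data.frame(name = c("CA", "CA"), element = c("C", "C"),
                        resno = 1:2, resname = "GLY"),
             coords, dt)
}

# Trajectory with caller-supplied per-atom coordinate matrices.
make_coord_traj <- function(coords, dt = 1, resname = "GLY",
                            name = "CA", element = "C") {
  na <- dim(coords)[2]
  trajectory(data.frame(name = name, element = element,
                        resno = seq_len(na), resname = resname),
             coords, dt)
}
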