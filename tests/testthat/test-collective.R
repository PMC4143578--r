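rotation_about_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

test_that("superposition removes pure rigid-body motion", {
  set.seed(12)
  base <- matrix(rnorm(15, sd = 3), ncol = 3)
  nf <- 20
  coords <- array(NA_real_, c(nf, 5, 3))
  for (f in seq_len(nf)) {
    R <- rotation_about_z(0.3 * f) %*% rotation_about_z(0)  # rotation
    shift <- c(f, -2 * f, 0.5 * f)                          # translation
    coords[f, , ] <- sweep(base %*% t(R), 2, shift, "+")
  }
  tr <- make_coord_traj(coords, dt = 1)
  fitted <- superpose(tr, reference = "mean")
  disp <- displacement_field(fitted, selection = 1:5,
                             superpose_first = FALSE)
  expect_lt(max(abs(disp$displacements)), 1e-6)
})

test_that("superposition is idempotent and matches the bio3d reference fit", {
  set.seed(4)
  coords <- array(rnorm(30 * 5 * 3, sd = 2), c(30, 5, 3))
  tr <- make_coord_traj(coords, dt = 1)
  once <- superpose(tr, reference = "frame0")
  twice <- superpose(once, reference = "frame0")
  expect_lt(max(abs(once$coords - twice$coords)), 1e-10)

  # independent oracle: bio3d's least-squares fit, frame by frame
  xyz <- matrix(NA_real_, 30, 15)
  for (k in 1:3) xyz[, seq(k, 15, by = 3)] <- coords[, , k]
  ref <- xyz[1, ]
  for (f in 2:30) {
    oracle <- suppressWarnings(bio3d::fit.xyz(fixed = ref, mobile = xyz[f, ]))
    mine <- as.numeric(t(once$coords[f, , ]))
    expect_lt(max(abs(mine - as.numeric(oracle))), 1e-8)
  }
})

test_that("fitting can only reduce the RMSD to the reference", {
  set.seed(77)
  coords <- array(rnorm(10 * 6 * 3, sd = 2), c(10, 6, 3))
  tr <- make_coord_traj(coords, dt = 1)
  fitted <- superpose(tr, reference = "frame0")
  for (f in 2:10) {
    raw <- sqrt(mean((coords[f, , ] - coords[1, , ])^2))
    fit <- sqrt(mean((fitted$coords[f, , ] - fitted$coords[1, , ])^2))
    expect_lte(fit, raw + 1e-12)
  }
  expect_error(superpose(tr, selection = 1:2), "at least 3")
})

test_that("displacement fields are centred and localize injected motion", {
  nf <- 50
  coords <- array(0, c(nf, 3, 3))
  coords[, 1, ] <- matrix(rep(c(0, 0, 0), nf), ncol = 3, byrow = TRUE)
  coords[, 2, ] <- matrix(rep(c(10, 0, 0), nf), ncol = 3, byrow = TRUE)
  coords[, 3, ] <- matrix(rep(c(0, 10, 0), nf), ncol = 3, byrow = TRUE)
  coords[, 3, 1] <- coords[, 3, 1] + sin(seq_len(nf))
  tr <- make_coord_traj(coords, dt = 1)
  f <- displacement_field(tr, selection = 1:3, superpose_first = FALSE)
  means <- apply(f$displacements, 1, mean)
  expect_lt(max(abs(means)), 1e-10)
  amp <- apply(f$displacements, 1, function(m) mean(m^2))
  expect_equal(which.max(amp), 3)
  expect_lt(max(amp[1:2]), 1e-20)
  expect_error(displacement_field(make_coord_traj(coords[1, , , drop = FALSE]),
                                  selection = 1:3), "2 frames")
})

test_that("cross-correlation identities: copied, negated, independent fields", {
  set.seed(9)
  nf <- 400
  base <- matrix(rnorm(nf * 3), ncol = 3)
  disp <- array(NA_real_, c(3, nf, 3))
  disp[1, , ] <- base
  disp[2, , ] <- base            # identical motion
  disp[3, , ] <- -base           # mirrored motion
  disp <- sweep(disp, c(1, 3), apply(disp, c(1, 3), mean))
  f <- thzdyn:::displacement_field_obj(1:3, disp, FALSE)
  C <- cross_correlation_matrix(f)$C
  expect_equal(C[1, 2], 1, tolerance = 1e-10)
  expect_equal(C[1, 3], -1, tolerance = 1e-10)
  expect_true(isSymmetric(C, tol = 1e-12))
  expect_equal(diag(C), rep(1, 3), tolerance = 1e-10)
})

test_that("the sample correlation matrix converges to planted PSD targets", {
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    A <- matrix(rnorm(n * n), n)
    S <- tcrossprod(A) + diag(n) * 0.1
    target <- cov2cor(S)
    nf <- 2000
    f <- make_correlated_displacements(
      correlated_field_spec(target, n_frames = nf, seed = rep))
    C <- cross_correlation_matrix(f)$C
    worst <- max(worst, max(abs(C - target)))
  }
  expect_lt(worst, 5 / sqrt(2000))
})

test_that("the in-package correlation matrix agrees with the bio3d DCCM", {
  spec <- harmonic_spec(data.frame(wavenumber = c(30, 80),
                                   amplitude = c(1, 0.5)),
                        noise_sigma = 0.3, n_frames = 256, n_atoms = 6,
                        seed = 14)
  tr <- make_harmonic_trajectory(spec)
  f <- displacement_field(tr, selection = 1:6, superpose_first = FALSE)
  C <- cross_correlation_matrix(f)$C
  xyz <- matrix(NA_real_, 256, 18)
  for (k in 1:3) xyz[, seq(k, 18, by = 3)] <- tr$coords[, , k]
  ref <- suppressWarnings(bio3d::dccm.xyz(xyz))
  expect_lt(max(abs(C - unclass(ref))), 1e-8)
})

test_that("zero-variance residues yield zeroed correlations, not NaN", {
  nf <- 100
  disp <- array(rnorm(3 * nf * 3), c(3, nf, 3))
  disp[2, , ] <- 0
  disp <- sweep(disp, c(1, 3), apply(disp, c(1, 3), mean))
  f <- thzdyn:::displacement_field_obj(1:3, disp, FALSE)
  expect_warning(ccm <- cross_correlation_matrix(f), "zero")
  expect_false(any(is.na(ccm$C)))
  expect_equal(ccm$C[2, 1], 0)
  expect_equal(ccm$C[2, 2], 1)
})

test_that("network construction thresholds edges and keeps amplitudes", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.5
  C[3, 4] <- C[4, 3] <- -0.3
  ccm <- structure(list(C = C, residue_ids = 1:4,
                        amplitude = c(1, 2, 3, 4)),
                   class = "crosscorr_matrix")
  g35 <- build_network(ccm, 0.35)
  expect_equal(igraph::ecount(g35), 1)
  g25 <- build_network(ccm, 0.25)
  expect_equal(igraph::ecount(g25), 2)
  # the permissive network contains the strict one
  e35 <- apply(igraph::as_edgelist(g35), 1, paste, collapse = "-")
  e25 <- apply(igraph::as_edgelist(g25), 1, paste, collapse = "-")
  expect_true(all(e35 %in% e25))
  # anti-correlated pair enters by magnitude with its sign kept
  s <- igraph::E(g25)$sign[e25 == "3-4"]
  expect_equal(s, -1)
  expect_error(build_network(ccm, 1.01), "0, 1")

  # identity matrix: no edges at all
  ccm0 <- structure(list(C = diag(4), residue_ids = 1:4,
                         amplitude = rep(1, 4)),
                    class = "crosscorr_matrix")
  expect_equal(igraph::ecount(build_network(ccm0, 0.25)), 0)
})

test_that("edge counts are monotone non-increasing in the threshold", {
  set.seed(6)
  A <- matrix(rnorm(100), 10)
  C <- cov2cor(tcrossprod(A) + diag(10) * 0.01)
  ccm <- structure(list(C = C, residue_ids = 1:10, amplitude = rep(1, 10)),
                   class = "crosscorr_matrix")
  counts <- sapply(seq(0.05, 1, by = 0.05), function(th) {
    igraph::ecount(build_network(ccm, th))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("a planted correlated block is recovered exactly by the network", {
  n <- 12
  target <- diag(n)
  block <- 1:4
  target[block, block] <- 0.8
  diag(target) <- 1
  f <- make_correlated_displacements(
    correlated_field_spec(target, n_frames = 20000, seed = 11))
  ccm <- cross_correlation_matrix(f)
  g <- build_network(ccm, 0.35, keep_isolated = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  got <- sort(apply(el, 1, paste, collapse = "-"))
  want <- sort(apply(t(combn(block, 2)), 1, paste, collapse = "-"))
  expect_identical(got, want)
})

test_that("PCA satisfies the trace and projection-variance identities", {
  set.seed(30)
  nf <- 10000; n <- 10
  sds <- sqrt(c(4, rep(1, 3 * n - 1)))   # leading planted variance 4
  X <- sweep(matrix(rnorm(nf * 3 * n), nf), 2, sds, "*")
  coords <- array(NA_real_, c(nf, n, 3))
  for (k in 1:3) coords[, , k] <- X[, seq(k, 3 * n, by = 3)]
  tr <- make_coord_traj(coords, dt = 1)
  p <- pca_modes(tr, selection = 1:n, superpose_first = FALSE)

  S_trace <- sum(apply(X, 2, function(col) mean((col - mean(col))^2)))
  expect_equal(sum(p$eigenvalues), S_trace, tolerance = 1e-6)
  expect_equal(p$eigenvalues[1], 4, tolerance = 0.1)

  for (m in c(1, 2, 5)) {
    pv <- mean(p$projections[, m]^2)
    expect_equal(pv, p$eigenvalues[m], tolerance = 1e-6)
  }
  # orthogonal projections
  expect_lt(abs(mean(p$projections[, 1] * p$projections[, 2])), 0.05)
  # modes orthonormal
  G <- crossprod(p$modes)
  expect_lt(max(abs(G - diag(3 * n))), 1e-8)
})

test_that("PCA recovers a known covariance spectrum within 5%", {
  set.seed(55)
  n <- 10; nf <- 10000
  evals <- sort(runif(3 * n, 0.5, 5), decreasing = TRUE)
  Q <- qr.Q(qr(matrix(rnorm((3 * n)^2), 3 * n)))
  Shalf <- Q %*% diag(sqrt(evals)) %*% t(Q)
  X <- matrix(rnorm(nf * 3 * n), nf) %*% Shalf
  coords <- array(NA_real_, c(nf, n, 3))
  for (k in 1:3) coords[, , k] <- X[, seq(k, 3 * n, by = 3)]
  p <- pca_modes(make_coord_traj(coords, dt = 1), selection = 1:n,
                 superpose_first = FALSE)
  expect_lt(max(abs(p$eigenvalues - evals) / evals), 0.05)
})

test_that("square fluctuations localize planted variance and conserve totals", {
  set.seed(2)
  nf <- 5000; n <- 8
  coords <- array(rnorm(nf * n * 3, sd = 0.3), c(nf, n, 3))
  coords[, 5, ] <- array(rnorm(nf * 3, sd = sqrt(10) * 0.3), c(nf, 3))
  tr <- make_coord_traj(coords, dt = 1)
  p <- pca_modes(tr, selection = 1:n, superpose_first = FALSE)
  sf1 <- square_fluctuations(p, 1)
  expect_equal(which.max(sf1$square_fluctuation), 5)
  expect_gt(sf1$square_fluctuation[5], 0.5 * sum(sf1$square_fluctuation))

  # summed over all modes, per-residue square fluctuations equal variances
  total <- Reduce(`+`, lapply(seq_len(3 * n), function(m) {
    square_fluctuations(p, m)$square_fluctuation
  }))
  per_res_var <- sapply(1:n, function(a) {
    sum(apply(coords[, a, ], 2, function(c) mean((c - mean(c))^2)))
  })
  expect_equal(total, per_res_var, tolerance = 1e-6)
})

test_that("trajectory reconstruction from all modes is complete", {
  set.seed(8)
  coords <- array(rnorm(200 * 4 * 3), c(200, 4, 3))
  tr <- make_coord_traj(coords, dt = 1)
  p <- pca_modes(tr, selection = 1:4, superpose_first = FALSE)
  recon <- p$projections %*% t(p$modes)
  X <- matrix(NA_real_, 200, 12)
  for (k in 1:3) X[, seq(k, 12, by = 3)] <- coords[, , k]
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(recon - Xc)), 1e-8)

  # projecting the same trajectory reproduces the stored projections
  pr <- project_trajectory(tr, p, 1)
  expect_equal(as.numeric(pr), as.numeric(p$projections[, 1]),
               tolerance = 1e-10)
  expect_error(project_trajectory(make_coord_traj(coords[, 1:2, , drop = FALSE]),
                                  p, 1), "atoms")
})
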