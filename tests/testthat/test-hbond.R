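test_that("donor/acceptor assignment reflects the local chemistry", {
  # a single water: O is both donor (2 H) and acceptor
  w <- make_random_water_frame(n_waters = 1, n_protein_atoms = 0, seed = 1)
  da <- assign_donors_acceptors(w)
  o_idx <- which(w$atoms$element == "O")
  expect_equal(da$donors, o_idx)
  expect_equal(da$acceptors, o_idx)
  expect_equal(sort(da$hydrogens$hydrogen), which(w$atoms$element == "H"))
  expect_equal(da$hydrogens$donor, rep(o_idx, 2))

  # carbonyl-style O with no hydrogen: acceptor only
  atoms <- data.frame(name = c("C", "O"), element = c("C", "O"),
                      resno = 1, resname = "ALA")
  co <- rbind(c(0, 0, 0), c(1.23, 0, 0))
  tr <- trajectory(atoms, co, dt = 1)
  da2 <- assign_donors_acceptors(tr)
  expect_length(da2$donors, 0)
  expect_equal(da2$acceptors, 2)

  # an orphan hydrogen is excluded with a warning
  atoms3 <- rbind(atoms, data.frame(name = "HX", element = "H",
                                    resno = 2, resname = "ALA"))
  tr3 <- trajectory(atoms3, rbind(co, c(9, 9, 9)), dt = 1)
  expect_warning(assign_donors_acceptors(tr3), "no heavy atom")
})

test_that("the detector honors each geometric criterion separately", {
  crit <- hbond_criteria()
  # all three satisfied
  toy <- make_toy_hbond_frame(d_da = 2.8, angle_deg = 0)
  expect_equal(nrow(detect_hbonds_frame(toy$traj, criteria = crit)), 1)
  # H...A pushed past 2.6 A while donors stay close: lengthen the O-H bond
  # geometry where r_ha breaks the rule alone
  toy2 <- make_toy_hbond_frame(d_da = 3.4, angle_deg = 25, r_dh = 0.5)
  if (toy2$r_ha >= 2.6) {
    expect_equal(nrow(detect_hbonds_frame(toy2$traj, criteria = crit)), 0)
  }
  # angle violation alone
  toy3 <- make_toy_hbond_frame(d_da = 2.5, angle_deg = 35)
  expect_equal(nrow(detect_hbonds_frame(toy3$traj, criteria = crit)), 0)
  # heavy-distance violation alone
  toy4 <- make_toy_hbond_frame(d_da = 3.6, angle_deg = 0, r_dh = 1.2)
  expect_equal(nrow(detect_hbonds_frame(toy4$traj, criteria = crit)), 0)
})

test_that("a boundary grid around 3.5 A / 2.6 A / 30 deg matches constructive truth", {
  crit <- hbond_criteria()
  grid <- expand.grid(d_da = c(2.6, 3.45, 3.55),
                      angle = c(5, 29, 31),
                      r_dh = c(0.75, 1.0, 1.05))
  for (i in seq_len(nrow(grid))) {
    toy <- make_toy_hbond_frame(grid$d_da[i], grid$angle[i], grid$r_dh[i])
    det <- detect_hbonds_frame(toy$traj, criteria = crit)
    found <- any(det$donor_heavy == toy$donor &
                 det$hydrogen == toy$hydrogen &
                 det$acceptor_heavy == toy$acceptor)
    expect_identical(found, toy$is_hbond,
                     label = sprintf("d_da=%g angle=%g r_dh=%g",
                                     grid$d_da[i], grid$angle[i],
                                     grid$r_dh[i]))
  }
})

test_that("the detector agrees with the all-triples oracle on random frames", {
  for (seed in 1:25) {
    tr <- make_random_water_frame(n_waters = 40, n_protein_atoms = 0,
                                  radius = 8, seed = seed)
    det <- detect_hbonds_frame(tr)
    got <- sort(sprintf("%d_%d_%d", det$donor_heavy, det$hydrogen,
                        det$acceptor_heavy))
    want <- oracle_detect_hbonds(tr)
    want <- sort(sprintf("%d_%d_%d", want[, 1], want[, 2], want[, 3]))
    expect_identical(got, want, label = paste("seed", seed))
  }
})

test_that("scope classes partition the unfiltered detections", {
  tr <- make_random_water_frame(n_waters = 25, n_protein_atoms = 8,
                                radius = 7, seed = 99)
  # give the solute a donor so protein classes can occur
  tr$atoms$name[1] <- "N"; tr$atoms$element[1] <- "N"
  hpos <- tr$coords[1, 1, ] + c(1.0, 0, 0)
  tr$atoms <- rbind(tr$atoms,
                    data.frame(name = "H", element = "H", resno = 1,
                               resname = "ALA", chain = "A",
                               category = "protein"))
  tr$coords <- array(rbind(tr$coords[1, , ], hpos),
                     c(1, n_atoms(tr) + 1, 3))
  all_det <- detect_hbonds_frame(tr)
  classes <- c("protein-protein", "protein-water", "water-water")
  parts <- lapply(classes, function(cl) detect_hbonds_frame(tr, scope = cl))
  expect_equal(sum(sapply(parts, nrow)) +
                 sum(!(all_det$class %in% classes)),
               nrow(all_det))
  for (k in seq_along(classes)) {
    if (nrow(parts[[k]]) > 0) {
      expect_true(all(parts[[k]]$class == classes[k]))
    }
  }
  # protein-water scope excludes water-water bonds entirely
  pw <- detect_hbonds_frame(tr, scope = "protein-water")
  ww_keys <- with(all_det[all_det$class == "water-water", ],
                  paste(donor_heavy, hydrogen, acceptor_heavy))
  pw_keys <- with(pw, paste(donor_heavy, hydrogen, acceptor_heavy))
  expect_length(intersect(pw_keys, ww_keys), 0)
})

test_that("timelines track constructed occupancy patterns", {
  toy <- make_toy_hbond_frame(d_da = 2.8, angle_deg = 0)
  co1 <- toy$traj$coords[1, , ]

  # static geometry replicated: occupancy all ones
  coords <- array(NA_real_, c(10, nrow(co1), 3))
  for (f in 1:10) coords[f, , ] <- co1
  tr <- trajectory(toy$traj$atoms, coords, dt = 0.1)
  tl <- hbond_timeline(tr)
  expect_equal(nrow(tl$occupancy), 1)
  expect_true(all(tl$occupancy == 1L))

  # acceptor displaced on odd frames: occupancy alternates
  coords2 <- coords
  for (f in seq(1, 10, by = 2)) coords2[f, 4, 1] <- coords2[f, 4, 1] + 5
  tr2 <- trajectory(toy$traj$atoms, coords2, dt = 0.1)
  tl2 <- hbond_timeline(tr2)
  expect_equal(as.integer(tl2$occupancy[1, ]), rep(c(0L, 1L), 5))
})

test_that("interfacial water-water timelines respect the hydration shell", {
  # protein atom at origin; two waters H-bonded to each other far away
  base <- make_toy_hbond_frame(d_da = 2.8, angle_deg = 0)
  atoms <- rbind(data.frame(name = "CA", element = "C", resno = 1,
                            resname = "ALA", chain = "A",
                            category = "protein"),
                 base$traj$atoms)
  atoms$resno[-1] <- atoms$resno[-1] + 1
  # protein CA above the water pair: both oxygens inside / outside the shell
  near <- rbind(c(1.4, 2.5, 0), base$traj$coords[1, , ])
  far <- rbind(c(1.4, 30, 0), base$traj$coords[1, , ])
  co <- array(NA_real_, c(2, nrow(atoms), 3))
  co[1, , ] <- near; co[2, , ] <- near
  tr_near <- trajectory(atoms, co, dt = 1)
  co[1, , ] <- far; co[2, , ] <- far
  tr_far <- trajectory(atoms, co, dt = 1)

  tl_near <- hbond_timeline(tr_near, scope = "water-water",
                            shell_cutoff = 3.8)
  expect_equal(nrow(tl_near$occupancy), 1)
  tl_far <- suppressWarnings(
    hbond_timeline(tr_far, scope = "water-water", shell_cutoff = 3.8))
  expect_equal(nrow(tl_far$occupancy), 0)
})

test_that("HBACF handles degenerate and constructed timelines exactly", {
  bonds <- data.frame(donor_heavy = 1L, hydrogen = 2L, acceptor_heavy = 3L,
                      class = "water-water", id = "b1")
  # occupied only at t = 0: C(0) = 1 and zero afterwards
  occ <- matrix(c(1L, rep(0L, 49)), nrow = 1)
  tl <- thzdyn:::hbond_timeline_obj(bonds, occ, dt = 0.1)
  ch <- hbacf(tl, max_lag = 2)
  expect_equal(ch$values[1], 1)
  expect_equal(ch$values[-1], rep(0, length(ch$values) - 1))

  # all-ones: constant 1, and the lifetime fit refuses it
  tl2 <- thzdyn:::hbond_timeline_obj(bonds, matrix(1L, 1, 50), dt = 0.1)
  ch2 <- hbacf(tl2, max_lag = 2)
  expect_equal(ch2$values, rep(1, 21))
  expect_error(fit_hbond_lifetime(ch2, fit_window = c(0.1, 2)), "decay")
})

test_that("Markov timelines reproduce the two-state closed form ACF", {
  spec <- markov_hbond_spec(k_on = 0.25, k_off = 0.25, dt = 0.01,
                            n_frames = 1e5, n_bonds = 100, seed = 21)
  tl <- make_markov_hbond_timeline(spec)
  ch <- hbacf(tl, max_lag = 10)
  p <- 0.5; k <- 0.5
  closed <- p + (1 - p) * exp(-k * ch$lags)
  expect_lt(max(abs(ch$values - closed)), 0.02)

  # fitted relaxation rate within 10%
  fit <- fit_hbond_lifetime(ch)
  expect_equal(fit$tau, 2.0, tolerance = 0.1)
  expect_equal(fit$plateau, 0.5, tolerance = 0.1)
})

test_that("the continuous variant decays at least as fast as the intermittent one", {
  spec <- markov_hbond_spec(k_on = 0.5, k_off = 0.5, dt = 0.01,
                            n_frames = 2e4, n_bonds = 50, seed = 5)
  tl <- make_markov_hbond_timeline(spec)
  ci <- hbacf(tl, max_lag = 5, type = "intermittent")
  cc <- hbacf(tl, max_lag = 5, type = "continuous")
  expect_true(all(cc$values <= ci$values + 1e-12))
  # continuous survival of a Markov bond is exp(-k_off tau)
  expect_lt(max(abs(cc$values - exp(-0.5 * cc$lags))), 0.05)
})

test_that("lifetime fits recover exact exponentials to machine precision", {
  lags <- seq(0, 10, by = 0.02)
  acf <- correlation_series(lags, exp(-lags / 2))
  fit <- fit_hbond_lifetime(acf, fit_window = c(0.5, 8), fix_plateau = 0)
  expect_equal(fit$tau, 2.0, tolerance = 1e-6)
  fit2 <- fit_hbond_lifetime(acf, fit_window = c(0.5, 8))
  expect_equal(fit2$tau, 2.0, tolerance = 1e-4)
  expect_lt(fit2$plateau, 1e-4)

  acf3 <- correlation_series(lags, 0.3 + 0.7 * exp(-lags / 2.9))
  fit3 <- fit_hbond_lifetime(acf3, fit_window = c(0.5, 8))
  expect_equal(fit3$tau, 2.9, tolerance = 1e-4)
  expect_equal(fit3$plateau, 0.3, tolerance = 1e-4)
})

test_that("lifetime recovery holds across a grid of two-state rates", {
  taus <- c(1, 2.5, 5, 10)
  errs <- sapply(seq_along(taus), function(i) {
    k <- 1 / taus[i]
    spec <- markov_hbond_spec(k_on = k / 2, k_off = k / 2, dt = 0.01,
                              n_frames = 1e5, n_bonds = 100,
                              seed = 300 + i)
    tl <- make_markov_hbond_timeline(spec)
    win <- c(0.5, min(4 * taus[i], 20))
    fit <- fit_hbond_lifetime(hbacf(tl, max_lag = min(5 * taus[i], 25)),
                              fit_window = win)
    abs(fit$tau - taus[i]) / taus[i]
  })
  expect_lt(median(errs), 0.10)
})
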