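# hinge angle, per-subunit distances, hydrogen bonds, moving average, RMSF

make_three_bead_dimer <- function(pa, pv, pb) {
  top <- topology(data.frame(
    name = "CA", resid = c(182, 29, 182), resname = "LYS",
    subunit = c("A", "A", "B"), mass = 12, species = "protein",
    headgroup = FALSE))
  list(top = top, xyz = rbind(pa, pv, pb))
}

test_that("hinge angle reproduces planar geometry", {
  d <- make_three_bead_dimer(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  traj <- make_traj(d$top, list(d$xyz))
  expect_equal(hinge_angle_series(traj)$theta, 180)
  d90 <- make_three_bead_dimer(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(hinge_angle_series(make_traj(d90$top, list(d90$xyz)))$theta, 90)
  dco <- make_three_bead_dimer(c(1, 1, 1), c(1, 1, 1), c(2, 0, 0))
  expect_warning(out <- hinge_angle_series(make_traj(dco$top, list(dco$xyz))),
                 "coincident")
  expect_true(is.na(out$theta))
})

test_that("hinge angle is invariant under global rotation and translation", {
  set.seed(41)
  d <- make_three_bead_dimer(c(0, 1, 0.3), c(0.5, 0, 0), c(1.5, 0.2, -0.4))
  base <- hinge_angle_series(make_traj(d$top, list(d$xyz)))$theta
  for (i in 1:10) {
    R <- random_rotation_matrix()
    shift <- runif(3, -2, 2)
    moved <- sweep(d$xyz %*% t(R), 2, shift, "+") + 5
    th <- hinge_angle_series(make_traj(d$top, list(moved)))$theta
    expect_equal(th, base, tolerance = 1e-9)
  }
})

test_that("the synthetic crystallographic-pose dimer starts at 180 degrees", {
  dim <- build_dimer_model(seed = 2)
  traj <- make_traj(dim$topology, list(dim$frame$coords), box = dim$frame$box)
  th <- hinge_angle_series(traj)$theta
  expect_equal(th, 180, tolerance = 1)
  # bending subunit B about the interface reduces the angle
  bsel <- select_particles(dim$topology, "subunit B")
  vsel <- select_particles(dim$topology, "subunit A and resid 29")
  bent <- dim$frame$coords
  pivot <- bent[vsel[1], ]
  Rb <- rotation_axis_angle(c(0, 1, 0), -40 * pi / 180)
  bent[bsel, ] <- sweep(sweep(bent[bsel, ], 2, pivot) %*% t(Rb), 2, pivot, "+")
  th2 <- hinge_angle_series(make_traj(dim$topology, list(bent),
                                      box = dim$frame$box))$theta
  expect_equal(th2, 140, tolerance = 2)
})

test_that("per-subunit distances separate a bound from an unbound subunit", {
  # symmetric dimer above/below membrane plane gives equal series
  top <- make_mixed_topology(nres = 2, nlip = 2)
  top$particles$subunit[1:2] <- c("A", "B")
  xyz_sym <- rbind(c(5, 5, 13), c(5, 5, 7),
                   c(4, 4, 10.2), c(4, 4, 10), c(4, 4, 9.8),
                   c(6, 6, 9.8), c(6, 6, 10), c(6, 6, 10.2))
  traj <- make_traj(top, list(xyz_sym), box = c(10, 10, 20))
  dA <- subunit_distance_series(traj, "subunit A", "lipid")
  dB <- subunit_distance_series(traj, "subunit B", "lipid")
  expect_equal(dA$values, dB$values)
  expect_equal(dA$values, 3)
  # one-subunit-bound synthetic trajectory: bound plateau below unbound
  frames <- lapply(seq(0, 1, length.out = 11), function(f) {
    x <- xyz_sym
    x[1, 3] <- 13 - 1.5 * f   # subunit A approaches to 1.5 nm
    x[2, 3] <- 16             # subunit B stays away (above the membrane)
    x
  })
  tr2 <- make_traj(top, frames, box = c(10, 10, 30))
  dA2 <- subunit_distance_series(tr2, "subunit A", "lipid")
  dB2 <- subunit_distance_series(tr2, "subunit B", "lipid")
  expect_lt(tail(dA2$values, 1), tail(dB2$values, 1))
  expect_equal(tail(dB2$values, 1), 6)
})

test_that("hydrogen-bond counting honours both geometric cutoffs", {
  top <- topology(data.frame(
    name = c("N", "H", "O"), resid = c(1, 1, 2), resname = c("LYS", "LYS", "PI4P"),
    subunit = c("A", "A", "M"), mass = c(14, 1, 16),
    species = c("protein", "protein", "PI4P"),
    headgroup = c(FALSE, FALSE, TRUE)))
  hmap <- list("1" = 2L)
  # D-A at 0.30 nm with H on the D->A axis: counts
  xyz1 <- rbind(c(5, 5, 5), c(5, 5, 5.1), c(5, 5, 5.3))
  tr1 <- make_traj(top, list(xyz1))
  expect_equal(count_hbonds(tr1, 1L, hmap, 3L), 1L)
  # D-A at 0.40 nm: outside the 0.35 nm default
  xyz2 <- rbind(c(5, 5, 5), c(5, 5, 5.1), c(5, 5, 5.4))
  expect_equal(count_hbonds(make_traj(top, list(xyz2)), 1L, hmap, 3L), 0L)
  # H-D-A angle of 45 degrees: outside the 30 degree default
  xyz3 <- rbind(c(5, 5, 5), c(5, 5.0707, 5.0707), c(5, 5, 5.3))
  expect_equal(count_hbonds(make_traj(top, list(xyz3)), 1L, hmap, 3L), 0L)
  expect_error(count_hbonds(tr1, 1L, list("1" = integer(0)), 3L),
               "without a mapped hydrogen")
})

test_that("hydrogen-bond counts match the naive triple loop on random systems", {
  set.seed(43)
  for (i in 1:8) {
    n_d <- 4; n_a <- 6
    nm <- c(rep(c("N", "H1"), n_d), rep("O", n_a))
    top <- topology(data.frame(
      name = nm, resid = seq_along(nm), resname = "X",
      subunit = "A", mass = 10,
      species = "protein", headgroup = FALSE))
    box <- c(4, 4, 4)
    xyz <- cbind(runif(length(nm), 0, 4), runif(length(nm), 0, 4),
                 runif(length(nm), 0, 4))
    donors <- seq(1, 2 * n_d, by = 2)
    hmap <- setNames(lapply(donors, function(d) d + 1L), as.character(donors))
    acceptors <- 2 * n_d + seq_len(n_a)
    # place each hydrogen near its donor so the geometry is realistic
    for (d in donors) xyz[d + 1, ] <- xyz[d, ] + rnorm(3, 0, 0.07)
    traj <- make_traj(top, list(xyz), box = box)
    crit <- hbond_criterion(d_max = 1.2, a_max = 60)
    got <- count_hbonds(traj, donors, hmap, acceptors, crit)
    want <- oracle_hbonds_frame(xyz, box, donors, hmap, acceptors, 1.2, 60)
    expect_identical(got, want)
  }
})

test_that("hydrogen-bond counts are monotone in both cutoffs", {
  set.seed(47)
  nm <- c(rep(c("N", "H1"), 5), rep("O", 8))
  top <- topology(data.frame(name = nm, resid = seq_along(nm), resname = "X",
                             subunit = "A", mass = 10, species = "protein",
                             headgroup = FALSE))
  xyz <- cbind(runif(18, 0, 3), runif(18, 0, 3), runif(18, 0, 3))
  donors <- seq(1, 10, by = 2)
  for (d in donors) xyz[d + 1, ] <- xyz[d, ] + rnorm(3, 0, 0.07)
  hmap <- setNames(lapply(donors, function(d) d + 1L), as.character(donors))
  traj <- make_traj(top, list(xyz), box = c(3, 3, 3))
  acceptors <- 11:18
  counts_d <- vapply(c(0.2, 0.4, 0.8, 1.2), function(dm)
    count_hbonds(traj, donors, hmap, acceptors, hbond_criterion(dm, 45)),
    integer(1))
  expect_true(all(diff(counts_d) >= 0))
  counts_a <- vapply(c(10, 30, 60, 120), function(am)
    count_hbonds(traj, donors, hmap, acceptors, hbond_criterion(0.8, am)),
    integer(1))
  expect_true(all(diff(counts_a) >= 0))
})

test_that("infer_hydrogens maps hydrogens to their nearest donor", {
  top <- topology(data.frame(
    name = c("N", "H1", "H2", "O"), resid = c(1, 1, 1, 2), resname = "X",
    subunit = "A", mass = c(14, 1, 1, 16), species = "protein",
    headgroup = FALSE))
  xyz <- rbind(c(1, 1, 1), c(1, 1, 1.1), c(1, 1.1, 1), c(3, 3, 3))
  fr <- frame(0, xyz, c(10, 10, 10))
  hmap <- infer_hydrogens(top, fr, donors = 1L)
  expect_setequal(hmap[["1"]], c(2L, 3L))
})

test_that("moving average: constants, alternation and length preservation", {
  expect_equal(moving_average(rep(3, 10), window = 4, dt = 1), rep(3, 10))
  alt <- rep(c(0, 2), 50)
  sm <- moving_average(alt, window = 21, dt = 1)
  expect_equal(sm[30:70], rep(1, 41), tolerance = 0.05)
  expect_length(moving_average(1:7, 100, dt = 1), 7)
  expect_error(moving_average(1:5, 0), "window")
})

test_that("RMSF: static zero, two-point alternation amplitude, rigid motion", {
  set.seed(53)
  n <- 60
  base <- matrix(rnorm(3 * n, sd = 1.5), n, 3)
  top <- topology(data.frame(name = "CA", resid = 1:n, resname = "GLY",
                             subunit = "A", mass = 12, species = "protein",
                             headgroup = FALSE))
  static <- make_traj(top, list(base, base, base))
  expect_lt(max(rmsf(static, "name CA")$rmsf), 1e-10)
  # residue 10 alternates +/- a along x: RMSF = a (two-point alternation)
  a <- 0.4
  up <- base; up[10, 1] <- base[10, 1] + a
  dn <- base; dn[10, 1] <- base[10, 1] - a
  osc <- make_traj(top, rep(list(up, dn), 10))
  out <- rmsf(osc, "name CA")
  # superposition absorbs a small share of a single residue's motion into
  # the global fit, so the recovered amplitude sits slightly below a
  expect_equal(out$rmsf[out$residue == 10], a, tolerance = 0.05)
  expect_lt(max(out$rmsf[out$residue != 10]), 0.05)
  # rigid-body tumbling of the whole structure is removed by superposition
  frames <- lapply(1:8, function(i) {
    sweep(base %*% t(random_rotation_matrix()), 2, runif(3, -3, 3), "+")
  })
  rigid <- make_traj(top, frames)
  expect_lt(max(rmsf(rigid, "name CA")$rmsf), 1e-8)
  expect_error(rmsf(static, "name CB"), "empty selection")
  expect_error(rmsf(make_traj(top, list(base)), "name CA"), ">= 2 frames")
})
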