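# reference picking, orientation series, density map and mode detection

test_that("user-supplied references pass through with provenance", {
  ref <- matrix(rnorm(9), 3, 3)
  out <- pick_reference(list(), reference = ref)
  expect_equal(out$coords, ref)
  expect_equal(out$provenance, "user")
})

test_that("reference search picks a post-binding productive frame", {
  s <- small_encounter(n_frames = 600, noise_sigma = 0.1, tau = 50,
                       hotspots = c(180:184, 187:197))
  ref <- pick_reference(list(s$run$trajectory), site_residues = 180:184,
                        lipid_target_sel = "headgroup")
  expect_equal(ref$provenance, "search")
  expect_gt(ref$frame_index, s$run$truth$binding_frame)
  expect_equal(nrow(ref$coords), 324)
})

test_that("an all-unbound ensemble yields an informative error", {
  # frames fixed far above the membrane: no catalytic-site contacts anywhere
  top <- make_mixed_topology(nres = 200, nlip = 4)
  xyz <- cbind(runif(212, 0, 5), runif(212, 0, 5),
               c(runif(200, 15, 18), runif(12, 0, 2)))
  traj <- make_traj(top, list(xyz, xyz), box = c(20, 20, 20))
  expect_error(pick_reference(list(traj), site_residues = 1:5,
                              lipid_target_sel = "headgroup"),
               "supply a reference")
})

test_that("orientation series anchors: identity, flip, size mismatch", {
  s <- small_encounter(n_frames = 5, noise_sigma = 0)
  traj <- s$run$trajectory
  sel <- select_particles(traj$topology, "protein")
  ref <- traj$coords[sel, , 3]
  os <- orientation_series(traj, "protein", ref)
  expect_equal(os$rzz[3], 1, tolerance = 1e-9)
  expect_true(all(abs(os$rzz) <= 1))
  flipped <- ref %*% t(rotation_axis_angle(c(1, 0, 0), pi))
  osf <- orientation_series(traj, "protein", flipped)
  expect_equal(osf$rzz[3], -1, tolerance = 1e-9)
  expect_error(orientation_series(traj, "protein", ref[1:10, ]),
               "does not match")
})

test_that("density map puts all mass where the data are and sums to 1", {
  one_d <- membind:::distance_series(1:100, rep(4, 100))
  one_r <- structure(list(times = 1:100, rzz = rep(1, 100)),
                     class = "orientation_series")
  map <- distance_orientation_map(list(one_d), list(one_r), 10, 10)
  expect_equal(sum(map$prob), 1)
  expect_equal(max(map$prob), 1)  # single bin holds everything
  # two equal constant clusters -> two bins of mass 0.5
  two_d <- membind:::distance_series(1:100, rep(c(3, 6), each = 50))
  two_r <- structure(list(times = 1:100, rzz = rep(c(0.2, 0.9), each = 50)),
                     class = "orientation_series")
  map2 <- distance_orientation_map(list(two_d), list(two_r), 10, 10)
  expect_equal(sort(map2$prob[map2$prob > 0]), c(0.5, 0.5))
  # random input still sums to 1 and is replicate-order invariant
  set.seed(37)
  ds <- lapply(1:3, function(i)
    membind:::distance_series(1:50, runif(50, 2, 8)))
  rs <- lapply(1:3, function(i)
    structure(list(times = 1:50, rzz = runif(50, -1, 1)),
              class = "orientation_series"))
  m1 <- distance_orientation_map(ds, rs)
  m2 <- distance_orientation_map(rev(ds), rev(rs))
  expect_equal(sum(m1$prob), 1, tolerance = 1e-12)
  expect_equal(m1$prob, m2$prob)
  expect_error(distance_orientation_map(list(), list()), "empty")
})

test_that("mode detection: single cluster has mass 1; ties break low", {
  set.seed(61)
  one_d <- membind:::distance_series(1:50, rnorm(50, 4, 0.05))
  one_r <- structure(list(times = 1:50, rzz = rnorm(50, 0.8, 0.01)),
                     class = "orientation_series")
  # fixed wide axes so the cluster is compact relative to the bins
  map <- distance_orientation_map(list(one_d), list(one_r), 20, 20,
                                  d_range = c(0, 10), r_range = c(-1, 1))
  expect_warning(modes <- find_modes(map, k = 2), "separated maxima")
  expect_equal(length(modes), 1)
  expect_equal(modes[[1]]$mass, 1)
  expect_equal(modes[[1]]$d, 4, tolerance = 0.2)
  # perfectly uniform map: the kept peak is the lowest distance/rzz bin
  u <- map
  u$prob <- matrix(1 / 400, 20, 20)
  um <- find_modes(u, k = 1)
  expect_equal(um[[1]]$d_bin, 1L)
  expect_equal(um[[1]]$r_bin, 1L)
})

test_that("planted two-mode ensembles are recovered within one bin", {
  bil <- build_bilayer(bilayer_spec(grid_nx = 6, grid_ny = 6), seed = 1)
  prot <- build_protein_model(seed = 1)
  params <- encounter_params(n_frames = 1200, dt = 0.5, noise_sigma = 0.3,
                             bound_distance = c(4.5, 3.6),
                             bound_rzz = c(0.4, 0.9),
                             mode_weights = c(0.5, 0.5), tau = 60, seed = 501L)
  runs <- simulate_ensemble(prot, bil, params, n_replicates = 6)
  trajs <- lapply(runs, `[[`, "trajectory")
  dists <- lapply(trajs, com_distance_series)
  ors <- lapply(trajs, orientation_series,
                reference = runs[[1]]$truth$reference)
  map <- distance_orientation_map(dists, ors)
  modes <- find_modes(map, k = 2)
  expect_equal(length(modes), 2)
  dw <- diff(map$d_edges[1:2]); rw <- diff(map$r_edges[1:2])
  planted <- list(c(4.5, 0.4), c(3.6, 0.9))
  for (pl in planted) {
    hit <- vapply(modes, function(m)
      abs(m$d - pl[1]) <= 1.5 * dw && abs(m$rzz - pl[2]) <= 1.5 * rw,
      logical(1))
    expect_true(any(hit))
  }
  expect_equal(sum(vapply(modes, `[[`, numeric(1), "mass")), 1,
               tolerance = 1e-9)
})

test_that("density map CSV export is long-format with matching totals", {
  one_d <- membind:::distance_series(1:20, runif(20, 2, 8))
  one_r <- structure(list(times = 1:20, rzz = runif(20, -1, 1)),
                     class = "orientation_series")
  map <- distance_orientation_map(list(one_d), list(one_r), 5, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_density_map(map, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 25)
  expect_equal(sum(out$probability), 1, tolerance = 1e-12)
})
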