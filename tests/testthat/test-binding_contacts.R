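# distance series, exponential fits and contact profiling

test_that("COM distance series reproduces static geometries", {
  top <- make_mixed_topology(nres = 1, nlip = 1)
  # protein bead at z = 8 above a lipid centred at z = 0 (through its COM)
  xyz <- rbind(c(5, 5, 18),                      # protein
               c(2, 1, 10.5), c(2, 1, 10), c(2, 1, 9.5))  # lipid, COM z = 10
  traj <- make_traj(top, list(xyz, xyz), box = c(20, 20, 40))
  dz <- com_distance_series(traj, "protein", "lipid", "z_component")
  expect_equal(dz$values, c(8, 8))
  d3 <- com_distance_series(traj, "protein", "lipid", "euclidean3d")
  expect_equal(d3$values, rep(sqrt(9 + 16 + 64), 2))
  expect_error(com_distance_series(traj, "species PIP2", "lipid"), "empty")
})

test_that("ensemble mean averages pointwise and validates grids", {
  a <- membind:::distance_series(0:4, rep(4, 5))
  b <- membind:::distance_series(0:4, rep(6, 5))
  m <- ensemble_mean(list(a, b))
  expect_equal(m$values, rep(5, 5))
  expect_equal(ensemble_mean(list(a))$values, a$values)
  c <- membind:::distance_series(seq(0, 2, 0.5), rep(6, 5))
  expect_error(ensemble_mean(list(a, c)), "time grids differ")
  m2 <- ensemble_mean(list(a, c), resample = TRUE)
  expect_equal(m2$times, a$times)
})

test_that("exponential fit inverts a noiseless curve to 1e-6", {
  t <- seq(0, 500, by = 0.5)
  d <- 4 + (8 - 4) * exp(-t / 50)
  fit <- fit_binding_curve(membind:::distance_series(t, d))
  expect_true(fit$converged)
  expect_equal(fit$d0, 8, tolerance = 1e-6)
  expect_equal(fit$d_inf, 4, tolerance = 1e-6)
  expect_equal(fit$tau, 50, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("constant or short series are rejected before fitting", {
  expect_error(fit_binding_curve(membind:::distance_series(0:9, rep(5, 10))),
               "constant")
  expect_error(fit_binding_curve(membind:::distance_series(0:2, c(1, 2, 3))),
               ">= 4 points")
})

test_that("fitted tau scales with time units (scale equivariance)", {
  set.seed(23)
  t <- seq(0, 400, by = 0.5)
  d <- 4.5 + 3.5 * exp(-t / 80) + rnorm(length(t), 0, 0.2)
  f1 <- fit_binding_curve(membind:::distance_series(t, d))
  for (c_scale in c(0.1, 3)) {
    f2 <- fit_binding_curve(membind:::distance_series(t * c_scale, d))
    expect_equal(f2$tau, f1$tau * c_scale, tolerance = 1e-4)
  }
})

test_that("contact cutoff is a strict inequality", {
  top <- make_mixed_topology(nres = 1, nlip = 1)
  place <- function(gap) {
    rbind(c(5, 5, 5), c(5, 5, 5 + gap), c(5, 5, 3), c(5, 5, 2.8))
  }
  tr_in <- make_traj(top, list(place(0.65)))
  tr_at <- make_traj(top, list(place(0.70)))
  p_in <- residue_contact_profile(tr_in, cutoff = 0.7)
  p_at <- residue_contact_profile(tr_at, cutoff = 0.7)
  expect_equal(p_in$raw, 1L)   # 0.65 < 0.7 counts
  expect_equal(p_at$raw, 0L)   # exactly 0.70 does not
  expect_true(attr(p_at, "all_zero"))
})

test_that("contact counts match the naive oracle on random frames (both modes)", {
  set.seed(29)
  for (i in 1:10) {
    rf <- random_contact_frame(nres = 12, nlip = 8)
    traj <- make_traj(rf$top, list(rf$xyz), box = rf$box)
    tgt <- select_particles(rf$top, "headgroup")
    for (mode in c("min_particle", "com")) {
      for (plc in c(FALSE, TRUE)) {
        prof <- residue_contact_profile(traj, lipid_target_sel = "headgroup",
                                        cutoff = 0.9, mode = mode,
                                        per_lipid_count = plc)
        oracle <- oracle_contacts_frame(rf$top, rf$xyz, rf$box, 1:12, tgt,
                                        0.9, mode, plc)
        expect_identical(prof$raw, as.integer(oracle))
      }
    }
  }
})

test_that("profile normalisation follows the max-residue rule", {
  prof <- structure(data.frame(residue = 1:3, raw = c(2L, 8L, 4L),
                               normalized = 0),
                    class = c("contact_profile", "data.frame"))
  out <- normalize_profile(prof)
  expect_equal(out$normalized, c(0.25, 1, 0.5))
  zero <- normalize_profile(structure(
    data.frame(residue = 1:3, raw = c(0L, 0L, 0L), normalized = 0),
    class = c("contact_profile", "data.frame")))
  expect_equal(zero$normalized, rep(0, 3))
  expect_true(attr(zero, "all_zero"))
})

test_that("contact time series row sums equal the profile raw counts", {
  s <- small_encounter(n_frames = 120, noise_sigma = 0.2)
  traj <- s$run$trajectory
  prof <- residue_contact_profile(traj, lipid_target_sel = "headgroup",
                                  cutoff = 0.7)
  cs <- contact_timeseries(traj, lipid_target_sel = "headgroup", cutoff = 0.7)
  expect_identical(as.integer(rowSums(cs)), prof$raw)
  expect_equal(dim(cs), c(324, 120))
})

test_that("hotspot rows become persistently occupied after binding", {
  s <- small_encounter(n_frames = 600, noise_sigma = 0.1, tau = 50)
  traj <- s$run$trajectory
  bf <- s$run$truth$binding_frame
  expect_false(is.na(bf))
  cs <- contact_timeseries(traj, protein_residues = c(182, 50),
                           lipid_target_sel = "headgroup", cutoff = 0.7)
  post <- seq(bf + 50, n_frames(traj))
  pre <- seq_len(max(1, bf - 50))
  expect_gt(mean(cs["182", post]), 0.8)   # planted hotspot occupied when bound
  expect_lt(mean(cs["182", pre]), 0.2)    # and not during the approach
})

test_that("no lipid targets yields an all-zero profile with a warning", {
  top <- make_mixed_topology(nres = 3, nlip = 2, lipid_species = "PC")
  xyz <- matrix(runif(9 * 3, 0, 5), ncol = 3)
  traj <- make_traj(top, list(xyz), box = c(6, 6, 6))
  expect_warning(prof <- residue_contact_profile(traj), "empty lipid target")
  expect_true(all(prof$raw == 0))
})

test_that("proximal-lipid counts match distances and the naive oracle", {
  top <- make_mixed_topology(nres = 1, nlip = 3)
  # lipid headgroup COMs at 1, 3 and 4 nm from the site bead (tails collapsed
  # onto the head position so the per-lipid COM is the head position)
  xyz <- rbind(c(5, 5, 5),
               c(6, 5, 5), c(6, 5, 5), c(6, 5, 5),
               c(8, 5, 5), c(8, 5, 5), c(8, 5, 5),
               c(9, 5, 5), c(9, 5, 5), c(9, 5, 5))
  traj <- make_traj(top, list(xyz), box = c(20, 20, 20))
  expect_equal(count_proximal_lipids(traj, "protein", "headgroup", 3.5), 2L)
  expect_equal(count_proximal_lipids(traj, "protein", "headgroup", 0.5), 0L)
  expect_error(count_proximal_lipids(traj, "species PIP2", "headgroup", 3.5),
               "empty site")
  set.seed(31)
  for (i in 1:10) {
    rf <- random_contact_frame(nres = 1, nlip = 10)
    tr <- make_traj(rf$top, list(rf$xyz), box = rf$box)
    hg <- select_particles(rf$top, "headgroup")
    scom <- rf$xyz[1, ]
    oracle <- sum(vapply(hg, function(j)
      oracle_min_image(scom, rf$xyz[j, ], rf$box) <= 2.5, logical(1)))
    expect_equal(count_proximal_lipids(tr, 1L, hg, 2.5), oracle)
  }
})

test_that("contact profile CSV carries PDB renumbering", {
  s <- small_encounter(n_frames = 5)
  prof <- residue_contact_profile(s$run$trajectory,
                                  protein_residues = c(182, 254),
                                  lipid_target_sel = "headgroup")
  path <- withr::local_tempfile(fileext = ".csv")
  write_contact_profile(prof, path)
  out <- read.csv(path)
  expect_equal(out$pdb_residue, c(238, 356))
})
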