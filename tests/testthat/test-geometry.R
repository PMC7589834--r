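# Superposition, RMSD/RMSF/Rg and the analysis window.

# one-frame view of a trajectory through the exported constructor
subset_frames_export <- function(traj, i) {
  trajectory(traj$atoms, traj$xyz[i, , drop = FALSE])
}

test_that("Kabsch superposition nulls rigid transforms and matches a
           brute-force rotation search", {
  ref <- frame_coords(build_ideal_helix(4), 1)

  same <- kabsch_superpose(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  shifted <- kabsch_superpose(sweep(ref, 2, c(5, 0, 0), "+"), ref)
  expect_equal(shifted$rmsd, 0, tolerance = 1e-10)

  R <- rot_about(c(1, 2, 3), 73)
  rotated <- kabsch_superpose(ref %*% t(R), ref)
  expect_equal(rotated$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(rotated$rotation), 1, tolerance = 1e-8)

  # tetrahedron with one vertex displaced: SVD answer = grid-search answer
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  moved <- tet; moved[4, ] <- moved[4, ] + c(0.6, -0.5, 0.62)
  fit <- kabsch_superpose(moved, tet)
  expect_equal(fit$rmsd, grid_rmsd_oracle(moved, tet), tolerance = 1e-4)

  expect_error(kabsch_superpose(ref[1:3, ], ref), "atom count")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 atoms")
})

test_that("RMSD series is zero on rigid motion and matches an independent
           refit of the same frames", {
  h <- build_ideal_helix(6)
  still <- trajectory(h$atoms, h$xyz[rep(1, 4), ])
  expect_equal(rmsd_series(still)$values, rep(0, 4), tolerance = 1e-10)

  two <- trajectory(h$atoms, h$xyz[c(1, 1), ])
  two <- transform_frame(two, 2, rot_about(c(0, 0, 1), 40), c(3, -1, 2))
  expect_equal(rmsd_series(two)$values, c(0, 0), tolerance = 1e-8)

  # independent oracle: bio3d's fitter on the identical frames
  tr <- sample_harmonic_ensemble(h, diag(1, 6), n_frames = 40, seed = 11)
  sel <- select_atoms(tr, "backbone")
  ours <- rmsd_series(tr, "first_frame", "backbone")$values
  fitted <- bio3d::fit.xyz(sel$xyz[1, ], sel$xyz,
                           fixed.inds = seq_len(ncol(sel$xyz)),
                           mobile.inds = seq_len(ncol(sel$xyz)))
  theirs <- vapply(seq_len(nrow(fitted)), function(i)
    sqrt(mean(colSums(matrix((fitted[i, ] - sel$xyz[1, ])^2, nrow = 3)))),
    numeric(1))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("RMSF matches the isotropic closed form and scales linearly", {
  h <- build_ideal_helix(30)
  frozen <- trajectory(h$atoms, h$xyz[rep(1, 3), ])
  expect_equal(as.numeric(rmsf_per_residue(frozen)), rep(0, 30),
               tolerance = 1e-10)

  # unit per-axis variance => RMSF ~ sqrt(3)
  tr <- sample_harmonic_ensemble(h, diag(1, 30), n_frames = 5000, seed = 12)
  rf <- rmsf_per_residue(tr)
  expect_equal(mean(as.numeric(rf)), sqrt(3), tolerance = 0.05 * sqrt(3))

  # doubling the displacements doubles the profile (same seed, 4x cov)
  tr2 <- sample_harmonic_ensemble(h, diag(4, 30), n_frames = 500, seed = 13)
  tr1 <- sample_harmonic_ensemble(h, diag(1, 30), n_frames = 500, seed = 13)
  # linear up to the (nonlinear) refit onto each ensemble's own mean
  expect_equal(as.numeric(rmsf_per_residue(tr2)),
               2 * as.numeric(rmsf_per_residue(tr1)), tolerance = 1e-3)

  expect_error(rmsf_per_residue(subset_frames_export(h, 1)), "2 frames")
})

test_that("B-factor conversion follows B = (8 pi^2 / 3) RMSF^2", {
  prof <- structure(setNames(c(0, 1, 0.5), c("1", "2", "3")),
                    label = "RMSF", class = "residue_profile")
  b <- bfactor_from_rmsf(prof)
  expect_equal(as.numeric(b), c(0, 8 * pi^2 / 3, 8 * pi^2 / 12),
               tolerance = 1e-10)
  expect_equal(as.numeric(b)[2], 26.319, tolerance = 1e-3)
  expect_equal(as.numeric(b)[3], 6.580, tolerance = 1e-3)
})

test_that("radius of gyration matches closed forms and rigid invariance", {
  two <- ca_traj(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(rg_series(two, "all")$values, 1)

  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  cube <- ca_traj(corners)
  expect_equal(rg_series(cube, "all", mass_weighted = FALSE)$values,
               sqrt(3), tolerance = 1e-10)

  moved <- transform_frame(cube, 1, rot_about(c(1, 1, 0), 35), c(10, -4, 2))
  expect_equal(rg_series(moved, "all")$values, rg_series(cube, "all")$values,
               tolerance = 1e-8)
})

test_that("equilibration window drops the configured leading fraction", {
  w <- equilibration_window(300, 0.4)
  expect_equal(range(w), c(121, 300))
  expect_length(w, 180)
  expect_equal(equilibration_window(10, 0), 1:10)
  expect_warning(w1 <- equilibration_window(10, 0.99), "clamped")
  expect_equal(w1, 10L)
  expect_error(equilibration_window(10, 1), "config error")
})
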