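# Dynamic cross-correlation maps and essential-dynamics PCA.

test_that("DCCM extremes: rigid co-motion gives +1, antiphase gives -1", {
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  frames <- lapply(c(0, 1, -2, 3, 0.5), function(s) sweep(base, 2,
                                                          c(s, 0, 0), "+"))
  co <- compute_dccm(ca_traj(frames), superpose = FALSE)
  expect_true(all(abs(co - 1) < 1e-10))

  anti <- lapply(c(-1, 0.5, 2, -2), function(s)
    rbind(c(s, 0, 0), c(10 - s, 0, 0)))
  m <- compute_dccm(ca_traj(anti), superpose = FALSE)
  expect_equal(m[1, 2], -1, tolerance = 1e-10)
})

test_that("planted correlation blocks are recovered within 0.05", {
  ref <- build_ideal_helix(8)
  C <- diag(8)
  C[1:4, 1:4] <- 0.9; diag(C) <- 1
  tr <- sample_harmonic_ensemble(ref, C, n_frames = 5000, seed = 21)
  D <- compute_dccm(tr, superpose = FALSE)
  block <- D[1:4, 1:4][upper.tri(diag(4))]
  expect_equal(mean(block), 0.9, tolerance = 0.05)
  expect_lt(max(abs(D[5:8, 1:4])), 0.1)

  # structural invariants of the map
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(diag(D)), rep(1, 8), tolerance = 1e-10)
  expect_true(all(D >= -1 - 1e-10 & D <= 1 + 1e-10))

  # time reversal leaves the map unchanged
  rev_tr <- trajectory(tr$atoms, tr$xyz[rev(seq_len(n_frames(tr))), ])
  expect_equal(unclass(compute_dccm(rev_tr, superpose = FALSE)),
               unclass(D), tolerance = 1e-10)
})

test_that("zero-variance residues are flagged NA, not zero", {
  frames <- lapply(c(-1, 0, 1, 2), function(s)
    rbind(c(s, 0, 0), c(10, 0, 0), c(s, 10, 0)))
  D <- compute_dccm(ca_traj(frames), superpose = FALSE)
  expect_true(all(is.na(D[2, ])))
  expect_true(all(is.na(D[, 2])))
  expect_equal(D[1, 3], 1, tolerance = 1e-10)
})

test_that("DCCM agrees with bio3d's implementation on shared input", {
  ref <- build_ideal_helix(6)
  C <- 0.5 * diag(6) + 0.5
  tr <- sample_harmonic_ensemble(ref, C, n_frames = 300, seed = 22)
  ca <- select_atoms(tr, "CA")
  ours <- compute_dccm(tr, superpose = FALSE)
  theirs <- bio3d::dccm(ca$xyz)
  expect_equal(unclass(ours), unclass(theirs), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PCA recovers planted eigen-structure", {
  ref <- build_ideal_helix(4)
  # rank-1 motion concentrated on residue 1
  frames <- lapply(c(-2, -1, 1, 2), function(s) {
    m <- frame_coords(ref, 1)
    ca1 <- which(ref$atoms$name == "CA")[1]
    rows <- which(ref$atoms$resno == 1)
    m[rows, 1] <- m[rows, 1] + s
    m
  })
  p1 <- compute_pca(trajectory(ref$atoms,
                               do.call(rbind, lapply(frames, function(m)
                                 as.numeric(t(m))))),
                    superpose = FALSE)
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-10)
  mob <- p1$pc1_residue_mobility
  expect_gt(mob[1], 100 * max(mob[-1], 0))
  expect_equal(cumulative_variance(p1, 1), 1, tolerance = 1e-10)

  # planted spectrum (9, 3, 1, 0): fractions 9/13, 3/13, 1/13
  V <- qr.Q(qr(matrix(c(1, 1, 1, 1, 1, -1, 1, -1,
                        1, 1, -1, -1, 1, -1, -1, 1), 4, 4)))
  C <- V %*% diag(c(9, 3, 1, 0)) %*% t(V)
  tr <- sample_harmonic_ensemble(ref, C, n_frames = 5000, seed = 23)
  p <- compute_pca(tr, superpose = FALSE)
  expect_equal(p$variance_fractions[1:3], c(9, 3, 1) / 13, tolerance = 0.03)
  expect_equal(cumulative_variance(p, 3), 1, tolerance = 1e-6)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-8)
  expect_equal(crossprod(p$eigenvectors), diag(ncol(p$eigenvectors)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(cumulative_variance(p, 0), "out of range")
})

test_that("eigenvalue sum equals summed squared RMSF on the same frames", {
  tr <- sample_harmonic_ensemble(build_ideal_helix(10), diag(0.8, 10),
                                 n_frames = 200, seed = 24)
  p <- compute_pca(tr, "CA")
  rf <- rmsf_per_residue(tr, "CA")
  expect_equal(sum(p$eigenvalues), sum(as.numeric(rf)^2),
               tolerance = 1e-6 * sum(p$eigenvalues))
})

test_that("two-state projections separate into clusters along PC1", {
  a <- build_ideal_helix(8)
  b <- build_extended_strand(8)
  ts <- sample_two_state(a, b, occupancy_a = 0.5, jitter_sd = 0.3,
                         n_frames = 400, seed = 25)
  p <- compute_pca(ts)
  sil <- silhouette_1d(p$projections[, 1], attr(ts, "state"))
  expect_gt(sil, 0.5)
})
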