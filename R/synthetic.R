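# Synthetic ensembles and score tables with known ground truth.
#
# These generators define the validation conditions for every analysis
# stage: near-harmonic fluctuation ensembles with a prescribed
# residue-residue covariance (DCCM/PCA/RMSF ground truth), two-state
# ensembles with prescribed occupancies (FEL/PCA-cluster ground truth),
# ideal backbone geometries (SSE / H-bond / network ground truth), and
# predictor score tables with planted deleterious variants.

#' Sample a near-harmonic fluctuation ensemble
#'
#' Each frame adds to the reference conformation a Gaussian per-residue
#' scalar displacement with the prescribed residue-residue covariance.
#' The same displacement is added to the x, y and z coordinate of every
#' atom of the residue, so the residue-level displacement covariance --
#' the ground truth recovered by DCCM, PCA and RMSF -- is exactly
#' `residue_covariance` per axis.
#'
#' @param reference a one-frame [trajectory()] (the mean structure).
#' @param residue_covariance symmetric positive-semidefinite `N x N`
#'   matrix (Angstrom^2), N = number of residues of `reference`.
#' @param n_frames number of frames to draw.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return a [trajectory()] with `n_frames` frames.
#' @export
sample_harmonic_ensemble <- function(reference, residue_covariance,
                                     n_frames, seed = 1) {
  stopifnot(inherits(reference, "trajectory"))
  if (n_frames(reference) != 1) stop("reference must have exactly one frame")
  N <- n_residues(reference)
  C <- as.matrix(residue_covariance)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("spec error: residue_covariance must be symmetric")
  if (nrow(C) != N)
    stop("spec error: covariance is ", nrow(C), "x", ncol(C),
         " but reference has ", N, " residues")
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
    stop("spec error: residue_covariance is not positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), N)
  rid <- residue_ids(reference)
  res_of_atom <- match(rid, unique(rid))
  ref <- frame_coords(reference, 1)
  xyz <- with_seed(seed, {
    z <- matrix(rnorm(n_frames * N), nrow = N)       # N x n_frames
    d <- L %*% z                                     # residue displacements
    t(vapply(seq_len(n_frames), function(f) {
      as.numeric(t(ref + d[res_of_atom, f]))         # same shift on x,y,z
    }, numeric(3 * n_atoms(reference))))
  })
  trajectory(reference$atoms, xyz, frame_interval = reference$frame_interval)
}

#' Sample a two-state conformational ensemble
#'
#' Each frame is `state_a` with probability `occupancy_a`, otherwise
#' `state_b`, plus isotropic Gaussian jitter on every coordinate.
#'
#' @param state_a,state_b one-frame trajectories sharing a topology.
#' @param occupancy_a fraction of frames in state A, in `[0, 1]`.
#' @param jitter_sd standard deviation (Angstrom) of the added noise.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @return a [trajectory()]; attribute `"state"` holds the ground-truth
#'   state label ("A"/"B") of each frame.
#' @export
sample_two_state <- function(state_a, state_b, occupancy_a = 0.5,
                             jitter_sd = 0.1, n_frames = 1000, seed = 1) {
  stopifnot(inherits(state_a, "trajectory"), inherits(state_b, "trajectory"))
  same <- identical(state_a$atoms[c("name", "resname", "resno", "chain")],
                    state_b$atoms[c("name", "resname", "resno", "chain")])
  if (!same) stop("spec error: states do not share a topology")
  if (occupancy_a < 0 || occupancy_a > 1)
    stop("spec error: occupancy_a must be in [0, 1]")
  na <- n_atoms(state_a)
  a <- state_a$xyz[1, ]; b <- state_b$xyz[1, ]
  out <- with_seed(seed, {
    in_a <- runif(n_frames) < occupancy_a
    base <- matrix(ifelse(rep(in_a, each = 3 * na), rep(a, n_frames),
                          rep(b, n_frames)),
                   nrow = n_frames, byrow = TRUE)
    noise <- matrix(rnorm(n_frames * 3 * na, sd = jitter_sd),
                    nrow = n_frames)
    list(xyz = base + if (jitter_sd > 0) noise else 0, in_a = in_a)
  })
  traj <- trajectory(state_a$atoms, out$xyz,
                     frame_interval = state_a$frame_interval)
  attr(traj, "state") <- ifelse(out$in_a, "A", "B")
  traj
}

# ---- ideal backbone construction ------------------------------------------

# Place atom D given A, B, C using bond length |C-D|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg). Natural-extension-reference-frame construction.
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an all-alanine chain with uniform backbone dihedrals.
# Atoms per residue: N, CA, C, O, CB. Ideal bond lengths/angles.
build_chain <- function(n_residues, phi, psi, omega = 180) {
  if (n_residues < 2) stop("spec error: need at least 2 residues")
  coords <- matrix(NA_real_, nrow = 5 * n_residues, ncol = 3)
  at <- function(i, k) (i - 1) * 5 + k   # k: 1 N, 2 CA, 3 C, 4 O, 5 CB
  # seed residue 1 in the xy-plane
  coords[at(1, 1), ] <- c(0, 0, 0)
  coords[at(1, 2), ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  coords[at(1, 3), ] <- coords[at(1, 2), ] +
    1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues)) {
    N <- coords[at(i, 1), ]; CA <- coords[at(i, 2), ]; C <- coords[at(i, 3), ]
    coords[at(i, 5), ] <- place_atom(N, C, CA, 1.521, 110.5, 122.5)  # CB
    coords[at(i, 4), ] <- place_atom(N, CA, C, 1.231, 120.8, psi + 180)  # O
    if (i < n_residues) {
      Nn <- place_atom(N, CA, C, 1.329, 116.2, psi)
      CAn <- place_atom(CA, C, Nn, 1.458, 121.7, omega)
      Cn <- place_atom(C, Nn, CAn, 1.525, 111.2, phi)
      coords[at(i + 1, 1), ] <- Nn
      coords[at(i + 1, 2), ] <- CAn
      coords[at(i + 1, 3), ] <- Cn
    }
  }
  atoms <- data.frame(
    serial = seq_len(5 * n_residues),
    name = rep(c("N", "CA", "C", "O", "CB"), n_residues),
    resname = "ALA",
    chain = "A",
    resno = rep(seq_len(n_residues), each = 5),
    stringsAsFactors = FALSE)
  trajectory(atoms, coords)
}

#' Build an ideal alpha-helix
#'
#' A poly-alanine backbone (N, CA, C, O, CB per residue) with uniform
#' dihedrals phi = -57, psi = -47 degrees and ideal bond geometry;
#' consecutive C-alpha atoms are ~3.8 Angstrom apart and the O(i)...N(i+4)
#' helical hydrogen-bond register is in place.
#'
#' @param n_residues number of residues (>= 4).
#' @return a one-frame [trajectory()].
#' @export
build_ideal_helix <- function(n_residues) {
  if (n_residues < 4) stop("spec error: an ideal helix needs >= 4 residues")
  build_chain(n_residues, phi = -57, psi = -47)
}

#' Build a fully extended chain
#'
#' Poly-alanine with phi = psi = 180 degrees; useful as a strand/coil
#' fixture for secondary-structure tests.
#'
#' @param n_residues number of residues (>= 2).
#' @return a one-frame [trajectory()].
#' @export
build_extended_strand <- function(n_residues) {
  build_chain(n_residues, phi = 180, psi = 180)
}

# ---- predictor score tables ------------------------------------------------

# Tool metadata shared with the screen: sampling ranges on the deleterious
# and neutral side of each cutoff (kept clear of the boundary).
.tool_sampler <- list(
  SIFT            = list(pass = c(0, 0.05),    fail = c(0.10, 1)),
  PolyPhen2       = list(pass = c(0.905, 1),   fail = c(0, 0.85)),
  MAPP            = list(pass = c(0.55, 1),    fail = c(0, 0.45)),
  PANTHER         = list(pass = c(0.5, 1),     fail = c(0, 0.45)),
  SNP_GO          = list(pass = c(0.55, 1),    fail = c(0, 0.45)),
  PhD_SNP         = list(pass = c(0.55, 1),    fail = c(0, 0.45)),
  PredictSNP      = "categorical",
  PROVEAN         = list(pass = c(-8, -2.5),   fail = c(-2, 2)),
  I_Mutant        = list(pass = c(-2, -0.55),  fail = c(-0.4, 1)))

#' Generate a synthetic predictor score table
#'
#' Emulates a multi-tool nsSNP screening input: each of the nine tools
#' draws a score past its deleteriousness cutoff with probability
#' `pass_prob_deleterious` for planted deleterious rows and
#' `pass_prob_neutral` for neutral rows; cells are then blanked at
#' `missing_rate`. PolyPhen-2 contributes its HumDiv and HumVar columns
#' jointly (one tool).
#'
#' @param n_variants number of rows.
#' @param planted_deleterious integer row indices of the planted
#'   deleterious variants.
#' @param missing_rate fraction of score cells blanked, in `[0, 1)`.
#' @param pass_prob_deleterious,pass_prob_neutral per-tool probability of
#'   a deleterious-side score for planted / neutral rows (defaults 0.95 /
#'   0.05).
#' @param seed integer RNG seed.
#' @return data.frame in the screen's input layout (`rs_id`,
#'   `substitution`, one column per score); attribute `"planted"` holds
#'   the ground-truth indices.
#' @export
generate_score_table <- function(n_variants, planted_deleterious = integer(),
                                 missing_rate = 0,
                                 pass_prob_deleterious = 0.95,
                                 pass_prob_neutral = 0.05, seed = 1) {
  if (length(planted_deleterious) &&
      (max(planted_deleterious) > n_variants || min(planted_deleterious) < 1))
    stop("spec error: planted indices out of range")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("spec error: missing_rate must be in [0, 1)")
  with_seed(seed, {
    wild <- sample(.aa_one, n_variants, replace = TRUE)
    mut <- vapply(wild, function(w) sample(setdiff(.aa_one, w), 1), "")
    pos <- sample(903:1147, n_variants, replace = TRUE)
    tab <- data.frame(
      rs_id = sprintf("rs%09d", sample.int(1e9 - 1, n_variants)),
      substitution = paste0(wild, pos, mut),
      stringsAsFactors = FALSE)
    is_del <- seq_len(n_variants) %in% planted_deleterious
    p_pass <- ifelse(is_del, pass_prob_deleterious, pass_prob_neutral)
    draw <- function(rng, n) runif(n, rng[1], rng[2])
    for (tool in names(.tool_sampler)) {
      pass <- runif(n_variants) < p_pass
      s <- .tool_sampler[[tool]]
      if (identical(s, "categorical")) {
        tab[[tool]] <- ifelse(pass, "D", "N")
      } else if (tool == "PolyPhen2") {
        hd <- ifelse(pass, draw(s$pass, n_variants), draw(s$fail, n_variants))
        hv <- ifelse(pass, draw(s$pass, n_variants), draw(s$fail, n_variants))
        tab$PolyPhen2_HumDiv <- round(hd, 3)
        tab$PolyPhen2_HumVar <- round(hv, 3)
      } else {
        tab[[tool]] <- round(ifelse(pass, draw(s$pass, n_variants),
                                    draw(s$fail, n_variants)), 3)
      }
    }
    if (missing_rate > 0) {
      score_cols <- setdiff(names(tab), c("rs_id", "substitution"))
      for (cc in score_cols) {
        gone <- runif(n_variants) < missing_rate
        tab[[cc]][gone] <- NA
      }
    }
    attr(tab, "planted") <- sort(planted_deleterious)
    tab
  })
}
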