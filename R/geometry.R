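# Superposition and scalar conformational descriptors.

#' Least-squares (Kabsch) superposition of two conformations
#'
#' Finds the rigid rotation and translation minimizing the mass-unweighted
#' sum of squared deviations between paired atoms, via SVD of the
#' covariance of the centered coordinate sets. The returned transform maps
#' a mobile point x to `rotation %*% x + translation`.
#'
#' @param mobile,reference numeric `n x 3` coordinate matrices with equal
#'   atom counts (n >= 3, not all collinear).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom, the minimized value).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("shape error: mobile and reference differ in atom count")
  if (nrow(mobile) < 3)
    stop("degenerate input: need at least 3 atoms for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)                       # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

# apply a kabsch_superpose() transform to an n x 3 matrix
apply_transform <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

# Superpose every frame of a (selected) trajectory onto reference coords.
superpose_frames <- function(traj, ref) {
  for (i in seq_len(n_frames(traj))) {
    fit <- kabsch_superpose(frame_coords(traj, i), ref)
    traj <- set_frame_coords(traj, i, apply_transform(frame_coords(traj, i), fit))
  }
  traj
}

# Two-pass fit onto the mean structure: fit to frame 1, take the mean,
# refit to that mean. Returns the superposed trajectory and the final mean
# (n_atoms x 3). Shared by RMSF, DCCM and PCA so their covariances agree.
superpose_to_mean <- function(traj) {
  if (n_frames(traj) < 2)
    stop("insufficient frames: need at least 2 for a mean-structure fit")
  traj <- superpose_frames(traj, frame_coords(traj, 1))
  m <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
  traj <- superpose_frames(traj, m)
  m <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
  list(traj = traj, mean = m)
}

# ---- series / profile containers ------------------------------------------

scalar_series <- function(values, label, frame_interval = NA_real_) {
  structure(list(values = as.numeric(values), label = label,
                 frame_interval = frame_interval),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("%s series: %d frames (mean %.3f, sd %.3f)\n", x$label,
              length(x$values), mean(x$values), stats::sd(x$values)))
  invisible(x)
}

residue_profile <- function(values, resno, label) {
  structure(setNames(as.numeric(values), as.character(resno)),
            label = label, class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("%s profile over %d residues (range %.3f .. %.3f)\n",
              attr(x, "label"), length(x), min(x), max(x)))
  invisible(x)
}

# one representative resno vector for a selected trajectory (order kept)
profile_resno <- function(traj) {
  rid <- residue_ids(traj)
  traj$atoms$resno[!duplicated(rid)]
}

# ---- descriptors ----------------------------------------------------------

#' Per-frame RMSD series after optimal superposition
#'
#' Every frame is superposed onto the reference before the deviation is
#' measured, so rigid-body motion contributes nothing.
#'
#' @param traj a [trajectory()].
#' @param reference `"first_frame"` or `"mean_structure"` (mean of the
#'   frames after a first-frame fit).
#' @param selection atom selection passed to [select_atoms()]; backbone by
#'   default.
#' @return a `scalar_series` of RMSD values (Angstrom), one per frame.
#' @export
rmsd_series <- function(traj, reference = c("first_frame", "mean_structure"),
                        selection = "backbone") {
  reference <- match.arg(reference)
  sel <- select_atoms(traj, selection)
  ref <- if (reference == "first_frame") frame_coords(sel, 1)
         else superpose_to_mean(sel)$mean
  vals <- vapply(seq_len(n_frames(sel)), function(i)
    kabsch_superpose(frame_coords(sel, i), ref)$rmsd, numeric(1))
  scalar_series(vals, "RMSD", sel$frame_interval)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are fitted to the mean structure (two-pass) and
#' `RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2)` is computed per
#' selected atom, then averaged (as root mean square) over the atoms of
#' each residue.
#'
#' @param traj a [trajectory()] with at least two frames.
#' @param selection atom selection; `"CA"` (one atom per residue) by
#'   default.
#' @return a `residue_profile` of RMSF values (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = "CA") {
  sel <- select_atoms(traj, selection)
  if (n_frames(sel) < 2)
    stop("insufficient frames: RMSF needs at least 2 frames")
  sp <- superpose_to_mean(sel)
  dev2 <- sweep(sp$traj$xyz, 2, as.numeric(t(sp$mean)))^2
  msf_axis <- colMeans(dev2)                       # 3 per atom
  msf_atom <- msf_axis[c(TRUE, FALSE, FALSE)] +
              msf_axis[c(FALSE, TRUE, FALSE)] +
              msf_axis[c(FALSE, FALSE, TRUE)]
  rid <- residue_ids(sel)
  msf_res <- vapply(split(msf_atom, factor(rid, levels = unique(rid))),
                    mean, numeric(1))
  residue_profile(sqrt(msf_res), profile_resno(sel), "RMSF")
}

#' Crystallographic B-factor implied by an RMSF profile
#'
#' `B_i = (8 pi^2 / 3) RMSF_i^2`, in Angstrom^2.
#'
#' @param profile a `residue_profile` of RMSF values (Angstrom, >= 0).
#' @return a `residue_profile` of B-factors (Angstrom^2).
#' @export
bfactor_from_rmsf <- function(profile) {
  if (any(profile < 0)) stop("RMSF values must be non-negative")
  residue_profile((8 * pi^2 / 3) * as.numeric(profile)^2,
                  names(profile), "B-factor")
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt( sum m_i |r_i - r_com|^2 / sum m_i )`, mass-weighted by
#' default with standard atomic masses (element inferred from the atom
#' name when absent).
#'
#' @param traj a [trajectory()].
#' @param selection atom selection; `"heavy"` by default.
#' @param mass_weighted logical; unit masses when `FALSE`.
#' @return a `scalar_series` of Rg values (Angstrom).
#' @export
rg_series <- function(traj, selection = "heavy", mass_weighted = TRUE) {
  sel <- select_atoms(traj, selection)
  m <- if (mass_weighted) element_mass(sel$atoms$element)
       else rep(1, n_atoms(sel))
  if (sum(m) <= 0) stop("mass-table error: zero total mass")
  vals <- vapply(seq_len(n_frames(sel)), function(i) {
    x <- frame_coords(sel, i)
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, numeric(1))
  scalar_series(vals, "Rg", sel$frame_interval)
}

#' Post-equilibration analysis window
#'
#' Discards the leading `cutoff_fraction` of the frames (the
#' pre-equilibration part of the trajectory) and returns the indices of
#' the retained frames. With 300 frames and the default fraction 0.4 the
#' window is frames 121..300 (the last 180).
#'
#' @param x a `scalar_series`, a [trajectory()], or an integer frame
#'   count.
#' @param cutoff_fraction fraction in `[0, 1)` of leading frames to drop.
#' @return integer vector of retained (1-based) frame indices.
#' @export
equilibration_window <- function(x, cutoff_fraction = 0.4) {
  n <- if (inherits(x, "scalar_series")) length(x$values)
       else if (inherits(x, "trajectory")) n_frames(x)
       else as.integer(x)
  if (cutoff_fraction < 0 || cutoff_fraction >= 1)
    stop("config error: cutoff_fraction must be in [0, 1)")
  start <- ceiling(cutoff_fraction * n) + 1L
  if (start > n) {
    warning("equilibration window clamped to the final frame")
    start <- n
  }
  seq.int(start, n)
}
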