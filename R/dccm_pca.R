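# Dynamic cross-correlation map and essential-dynamics PCA of the
# positional fluctuation covariance.

#' Residue-level dynamic cross-correlation map
#'
#' Computes `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, where
#' `dr_i` is the displacement vector of residue i from its time-averaged
#' position, over the analysis window. Entries lie in `[-1, 1]`: +1 is
#' fully correlated motion, -1 antiphase motion. Frames are superposed on
#' the window's mean structure first unless `superpose = FALSE` (useful
#' for rigid-motion checks, where superposition would remove the signal).
#'
#' Residues with zero positional variance have no defined correlation;
#' their rows/columns are returned as `NA` rather than 0.
#'
#' @param traj a [trajectory()].
#' @param selection one-atom-per-residue selection (default `"CA"`).
#' @param window integer frame indices (default all; >= 2 required).
#' @param superpose fit frames to the mean structure first (default TRUE).
#' @return an object of class `"correlation_map"`: the `N x N` matrix
#'   with residue numbers as dimnames.
#' @export
compute_dccm <- function(traj, selection = "CA",
                         window = seq_len(n_frames(traj)), superpose = TRUE) {
  sel <- subset_frames(select_atoms(traj, selection), window)
  if (n_frames(sel) < 2)
    stop("insufficient frames: DCCM needs at least 2 frames")
  if (superpose) sel <- superpose_to_mean(sel)$traj
  dev <- sweep(sel$xyz, 2, colMeans(sel$xyz))       # frames x 3N
  nres <- n_atoms(sel)                              # one atom per residue
  # <dr_i . dr_j> = (1/T) sum_t sum_axis dev_i,ax dev_j,ax
  Tn <- nrow(dev)
  cij <- matrix(0, nres, nres)
  for (ax in 1:3) {
    d <- dev[, seq(ax, 3 * nres, by = 3), drop = FALSE]
    cij <- cij + crossprod(d) / Tn
  }
  v <- diag(cij)
  denom <- sqrt(outer(v, v))
  C <- cij / denom
  C[denom == 0] <- NA_real_
  resno <- profile_resno(sel)
  dimnames(C) <- list(resno, resno)
  structure(C, class = c("correlation_map", "matrix"))
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation map: %d x %d residues, range [%.3f, %.3f]%s\n",
              nrow(x), ncol(x), min(x, na.rm = TRUE), max(x, na.rm = TRUE),
              if (anyNA(x)) " (zero-variance residues flagged NA)" else ""))
  invisible(x)
}

#' Principal component analysis of the fluctuation covariance
#'
#' Eigendecomposition of the `3N x 3N` covariance (denominator `T`, so
#' the eigenvalue sum equals the summed squared RMSF on the same
#' selection) of the superposed coordinates. Projections are the centered
#' coordinates on the eigenvectors; the PC1 residue mobility is the
#' per-residue displacement magnitude of the first eigenvector scaled by
#' `sqrt(lambda_1)`. Eigenvector signs are fixed by making each vector's
#' largest-magnitude component positive.
#'
#' @inheritParams compute_dccm
#' @return list of class `"pca_result"` with `eigenvalues` (descending,
#'   Angstrom^2), `eigenvectors` (columns, orthonormal),
#'   `variance_fractions`, `projections` (frames x 3N, Angstrom) and
#'   `pc1_residue_mobility` (a `residue_profile`).
#' @export
compute_pca <- function(traj, selection = "CA",
                        window = seq_len(n_frames(traj)), superpose = TRUE) {
  sel <- subset_frames(select_atoms(traj, selection), window)
  if (n_frames(sel) < 2)
    stop("insufficient frames: PCA needs at least 2 frames")
  if (superpose) sel <- superpose_to_mean(sel)$traj
  dev <- sweep(sel$xyz, 2, colMeans(sel$xyz))
  covm <- crossprod(dev) / nrow(dev)
  ed <- eigen(covm, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  vec <- ed$vectors
  for (k in seq_len(ncol(vec))) {          # reproducible sign convention
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  fractions <- if (sum(lam) > 0) lam / sum(lam) else lam
  proj <- dev %*% vec
  v1 <- matrix(vec[, 1], ncol = 3, byrow = TRUE)
  mob <- sqrt(rowSums(v1^2)) * sqrt(lam[1])
  structure(list(eigenvalues = lam, eigenvectors = vec,
                 variance_fractions = fractions, projections = proj,
                 pc1_residue_mobility =
                   residue_profile(mob, profile_resno(sel), "PC1 mobility")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$variance_fractions))
  cat(sprintf("PCA: %d modes; top-%d variance fractions: %s\n",
              length(x$eigenvalues), k,
              paste(sprintf("%.1f%%", 100 * x$variance_fractions[1:k]),
                    collapse = ", ")))
  invisible(x)
}

#' Cumulative explained variance of the leading components
#'
#' @param pca a [compute_pca()] result.
#' @param k number of leading components.
#' @return fraction in `[0, 1]`.
#' @export
cumulative_variance <- function(pca, k) {
  if (k < 1 || k > length(pca$variance_fractions))
    stop("index error: k out of range")
  sum(pca$variance_fractions[seq_len(k)])
}
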