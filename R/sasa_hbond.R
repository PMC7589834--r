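# Solvent-accessible surface area (Shrake-Rupley) and intramolecular
# hydrogen-bond counting.

#' Default van der Waals radius table
#'
#' @return named numeric vector of radii (Angstrom) per element symbol
#'   (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80).
#' @export
default_vdw_radii <- function() .vdw_radii

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' Each atom is covered with `n_sphere_points` quasi-uniform test points
#' on a sphere of radius `r_vdw + probe_radius`; the accessible area is
#' `4 pi (r + probe)^2` times the fraction of points not inside any
#' neighbor's expanded sphere.
#'
#' @param traj a [trajectory()].
#' @param frame frame index to analyze (default 1).
#' @param radii named radius table (Angstrom per element), see
#'   [default_vdw_radii()].
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, a
#'   water molecule).
#' @param n_sphere_points number of quadrature points per atom (>= 24;
#'   default 960).
#' @return list with `total` (Angstrom^2), `per_residue` (named by
#'   residue number) and `per_atom`.
#' @export
shrake_rupley_sasa <- function(traj, frame = 1, radii = default_vdw_radii(),
                               probe_radius = 1.4, n_sphere_points = 960) {
  if (n_sphere_points < 24) stop("n_sphere_points must be >= 24")
  x <- frame_coords(traj, frame)
  el <- traj$atoms$element
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("radius-table error: no radius for element(s): ",
         paste(unknown, collapse = ", "))
  R <- unname(radii[el]) + probe_radius
  n <- nrow(x)
  pts <- sphere_points(n_sphere_points)
  per_atom <- numeric(n)
  # pairwise neighbor lists on expanded spheres
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, x[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(p[free, , drop = FALSE], 2, x[j, ])^2)
      free[free] <- dj2 >= R[j]^2
    }
    per_atom[i] <- 4 * pi * R[i]^2 * sum(free) / n_sphere_points
  }
  rid <- residue_ids(traj)
  per_res <- vapply(split(per_atom, factor(rid, levels = unique(rid))),
                    sum, numeric(1))
  names(per_res) <- profile_resno(traj)
  list(total = sum(per_atom), per_residue = per_res, per_atom = per_atom)
}

#' Total SASA per frame
#'
#' Convenience wrapper applying [shrake_rupley_sasa()] to each frame of a
#' window.
#'
#' @inheritParams shrake_rupley_sasa
#' @param window integer frame indices (default all frames).
#' @return a `scalar_series` of total SASA (Angstrom^2).
#' @export
sasa_series <- function(traj, window = seq_len(n_frames(traj)),
                        radii = default_vdw_radii(), probe_radius = 1.4,
                        n_sphere_points = 960) {
  vals <- vapply(window, function(f)
    shrake_rupley_sasa(traj, f, radii, probe_radius, n_sphere_points)$total,
    numeric(1))
  scalar_series(vals, "SASA", traj$frame_interval)
}

# ---- hydrogen bonds -------------------------------------------------------

.donor_names <- c("N", "NE", "NH1", "NH2", "ND1", "NE2", "ND2",
                  "NZ", "NE1", "OG", "OG1", "OH", "SG")
.acceptor_names <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2",
                     "OG", "OG1", "OH", "ND1", "NE2", "SD")

# Reconstruct backbone amide hydrogens: H = N + 1.01 * unit(C_prev - O_prev)
# (N-H anti to the preceding carbonyl). Returns an n_atoms x 3 matrix with
# NA rows for atoms that are not reconstructable backbone N donors.
reconstruct_amide_h <- function(traj, x) {
  a <- traj$atoms
  H <- matrix(NA_real_, nrow(a), 3)
  rid <- residue_ids(traj)
  ures <- unique(rid)
  for (k in seq_along(ures)[-1]) {
    cur <- which(rid == ures[k]); prev <- which(rid == ures[k - 1])
    if (a$chain[cur[1]] != a$chain[prev[1]]) next
    iN <- cur[a$name[cur] == "N"]
    iC <- prev[a$name[prev] == "C"]
    iO <- prev[a$name[prev] == "O"]
    if (length(iN) != 1 || length(iC) != 1 || length(iO) != 1) next
    if (a$resname[cur[1]] == "PRO") next
    u <- x[iC, ] - x[iO, ]
    H[iN, ] <- x[iN, ] + 1.01 * u / sqrt(sum(u^2))
  }
  H
}

#' Intramolecular hydrogen-bond count per frame
#'
#' Counts unique donor--acceptor pairs with heavy-atom distance
#' `D...A <= donor_acceptor_max` and (where a donor hydrogen is available)
#' `D-H...A` angle at the hydrogen of at least `angle_min_deg`. Pairs
#' within one residue and the covalent backbone N(i+1)...O(i) pair of
#' each peptide bond are excluded.
#'
#' Hydrogens are used when present in the structure; for hydrogen-free
#' structures the backbone amide H is reconstructed geometrically
#' (N-H 1.01 Angstrom, anti to the preceding carbonyl) so the angle test
#' still discriminates bonded from merely close pairs; donors with no
#' obtainable hydrogen fall back to the distance criterion alone.
#'
#' @param traj a [trajectory()].
#' @param donor_acceptor_max heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_min_deg minimum D-H...A angle, degrees (default 120).
#' @param window integer frame indices (default all).
#' @return a `scalar_series` of bond counts.
#' @export
hbond_count_series <- function(traj, donor_acceptor_max = 3.5,
                               angle_min_deg = 120,
                               window = seq_len(n_frames(traj))) {
  if (donor_acceptor_max <= 0) stop("distance cutoff must be positive")
  if (angle_min_deg <= 0 || angle_min_deg > 180)
    stop("angle_min_deg must be in (0, 180]")
  a <- traj$atoms
  rid <- residue_ids(traj)
  don <- which(a$name %in% .donor_names & a$element != "H")
  acc <- which(a$name %in% .acceptor_names & a$element != "H")
  hyd <- which(a$element == "H")
  vals <- vapply(window, function(f) {
    x <- frame_coords(traj, f)
    # explicit H: attach to nearest donor heavy atom within 1.25 A
    hmap <- vector("list", nrow(a))
    if (length(hyd)) {
      for (ih in hyd) {
        d2 <- rowSums(sweep(x[don, , drop = FALSE], 2, x[ih, ])^2)
        j <- don[which.min(d2)]
        if (min(d2) < 1.25^2) hmap[[j]] <- c(hmap[[j]], ih)
      }
    }
    recon <- reconstruct_amide_h(traj, x)
    count <- 0L
    for (i in don) {
      d <- sqrt(rowSums(sweep(x[acc, , drop = FALSE], 2, x[i, ])^2))
      cand <- acc[d <= donor_acceptor_max & acc != i]
      cand <- cand[rid[cand] != rid[i]]
      # exclude the covalent N(i+1)...O(i) pair of each peptide bond
      if (a$name[i] == "N")
        cand <- cand[!(a$name[cand] == "O" &
                       a$chain[cand] == a$chain[i] &
                       a$resno[cand] == a$resno[i] - 1L)]
      if (!length(cand)) next
      hpos <- if (length(hmap[[i]])) x[hmap[[i]], , drop = FALSE]
              else if (all(is.finite(recon[i, ]))) matrix(recon[i, ], 1)
              else NULL
      for (j in cand) {
        ok <- if (is.null(hpos)) TRUE else {
          ang <- apply(hpos, 1, function(h) {
            v1 <- x[i, ] - h; v2 <- x[j, ] - h
            acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          })
          any(ang >= angle_min_deg)
        }
        if (ok) count <- count + 1L
      }
    }
    as.numeric(count)
  }, numeric(1))
  scalar_series(vals, "H-bonds", traj$frame_interval)
}
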