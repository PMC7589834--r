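# Simplified Kabsch-Sander secondary-structure assignment. Backbone
# hydrogen bonds are detected with the Kabsch-Sander electrostatic model
# (amide H reconstructed geometrically when absent), then n-turns,
# helices, bridges/ladders, turns and bends are assigned with the class
# priority H > E > G > T > S > C. Pi-helices, chirality flags and chain
# breaks are not modelled.

# per-residue backbone atom indices; error names the offending residue
.backbone_index <- function(traj) {
  a <- traj$atoms
  rid <- residue_ids(traj)
  ures <- unique(rid)
  idx <- lapply(c("N", "CA", "C", "O"), function(nm) {
    out <- integer(length(ures))
    for (k in seq_along(ures)) {
      hit <- which(rid == ures[k] & a$name == nm)
      if (length(hit) != 1)
        stop("assignment error: residue ", a$resname[rid == ures[k]][1],
             a$resno[rid == ures[k]][1], " lacks backbone atom ", nm)
      out[k] <- hit
    }
    out
  })
  names(idx) <- c("N", "CA", "C", "O")
  idx
}

# Kabsch-Sander energy matrix for one frame: E[j, i] is the energy of the
# bond donated by NH(j) to CO(i), NA where not evaluated.
.ks_energy_matrix <- function(traj, x, bb) {
  nres <- length(bb$N)
  H <- reconstruct_amide_h(traj, x)
  E <- matrix(NA_real_, nres, nres)
  d <- function(p, q) sqrt(sum((p - q)^2))
  for (j in seq_len(nres)) {                 # donor
    hj <- H[bb$N[j], ]
    if (!all(is.finite(hj))) next            # no amide H (N-terminus, Pro)
    for (i in seq_len(nres)) {               # acceptor
      if (abs(i - j) < 2) next
      rON <- d(x[bb$O[i], ], x[bb$N[j], ])
      if (rON > 5) next                      # cannot reach bonding energy
      E[j, i] <- 0.084 * 332 *
        (1 / rON + 1 / d(x[bb$C[i], ], hj) -
         1 / d(x[bb$O[i], ], hj) - 1 / d(x[bb$C[i], ], x[bb$N[j], ]))
    }
  }
  E
}

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic bond energy between the amide group of `donor_res` and
#' the carbonyl of `acceptor_res`:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A hydrogen bond is assigned when `E < -0.5`. The amide hydrogen is
#' reconstructed (N-H 1.01 Angstrom, anti to the preceding carbonyl) when
#' absent from the structure. Adjacent residues (`|i - j| < 2`) are not
#' evaluated and return `NA`.
#'
#' @param traj a [trajectory()] with backbone N, CA, C, O atoms.
#' @param donor_res,acceptor_res residue positions (1-based along the
#'   chain, not author numbering).
#' @param frame frame index (default 1).
#' @return energy in kcal/mol, or `NA` where not evaluated.
#' @export
backbone_hbond_energy <- function(traj, donor_res, acceptor_res, frame = 1) {
  bb <- .backbone_index(traj)
  if (abs(donor_res - acceptor_res) < 2) return(NA_real_)
  x <- frame_coords(traj, frame)
  H <- reconstruct_amide_h(traj, x)
  hj <- H[bb$N[donor_res], ]
  if (!all(is.finite(hj))) return(NA_real_)
  d <- function(p, q) sqrt(sum((p - q)^2))
  i <- acceptor_res; j <- donor_res
  0.084 * 332 * (1 / d(x[bb$O[i], ], x[bb$N[j], ]) +
                 1 / d(x[bb$C[i], ], hj) -
                 1 / d(x[bb$O[i], ], hj) -
                 1 / d(x[bb$C[i], ], x[bb$N[j], ]))
}

# assign classes for one frame; returns character vector over residues
.assign_frame <- function(traj, x, bb) {
  nres <- length(bb$N)
  res_chain <- traj$atoms$chain[bb$CA]
  E <- .ks_energy_matrix(traj, x, bb)
  AC <- !is.na(E) & E < -0.5                # AC[donor j, acceptor i]
  hb <- function(acceptor, donor) {         # CO(acceptor) <- NH(donor)
    acceptor >= 1 && donor >= 1 && acceptor <= nres && donor <= nres &&
      AC[donor, acceptor]
  }
  same_chain <- function(i, j) res_chain[i] == res_chain[j]
  cls <- rep("C", nres)
  # bends: S where the CA(i-2), CA(i), CA(i+2) direction change exceeds 70 deg
  if (nres >= 5) for (i in 3:(nres - 2)) {
    if (!same_chain(i - 2, i + 2)) next
    v1 <- x[bb$CA[i], ] - x[bb$CA[i - 2], ]
    v2 <- x[bb$CA[i + 2], ] - x[bb$CA[i], ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (ang > 70) cls[i] <- "S"
  }
  # n-turns at offsets 3, 4, 5 within one chain: CO(i) <- NH(i+n)
  turn <- list()
  for (n in 3:5) {
    at <- vapply(seq_len(nres), function(i)
      i + n <= nres && same_chain(i, i + n) && hb(i, i + n), logical(1))
    turn[[as.character(n)]] <- at
    for (i in which(at)) {
      span <- seq(i + 1, min(i + n - 1, nres))
      cls[span][cls[span] %in% c("C", "S")] <- "T"
    }
  }
  # 3_10 helix: two consecutive 3-turns
  g3 <- turn[["3"]]
  for (i in which(g3[-1] & head(g3, -1)) + 1) {
    span <- seq(i, min(i + 2, nres))
    cls[span][cls[span] %in% c("C", "S", "T")] <- "G"
  }
  # beta bridges/ladders (parallel and antiparallel): nonlocal pairs,
  # i.e. sequence-distant within a chain or on different chains
  isE <- rep(FALSE, nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (j <= i || (j - i < 3 && same_chain(i, j))) next
      par <- (hb(i - 1, j) && hb(j, i + 1)) || (hb(j - 1, i) && hb(i, j + 1))
      anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (par || anti) isE[c(i, j)] <- TRUE
    }
  }
  cls[isE] <- "E"
  # alpha helix: two consecutive 4-turns -> residues i..i+3 (top priority)
  h4 <- turn[["4"]]
  for (i in which(h4[-1] & head(h4, -1)) + 1) {
    cls[seq(i, min(i + 3, nres))] <- "H"
  }
  cls
}

#' Secondary-structure timeline over a trajectory window
#'
#' Assigns each residue of each frame one of the classes `H` (alpha
#' helix), `G` (3-10 helix), `E` (strand), `T` (turn), `S` (bend) or `C`
#' (coil) by the simplified Kabsch-Sander rules (see the package
#' vignette). Terminal residues that lack the neighbors a motif needs
#' default to `C`.
#'
#' @param traj a [trajectory()] with backbone N, CA, C, O atoms.
#' @param window integer frame indices (default all).
#' @return an object of class `"sse_timeline"`: a character matrix with
#'   one row per frame and one column per residue (colnames = residue
#'   numbers).
#' @export
assign_sse <- function(traj, window = seq_len(n_frames(traj))) {
  bb <- .backbone_index(traj)
  out <- t(vapply(window, function(f)
    .assign_frame(traj, frame_coords(traj, f), bb),
    character(length(bb$N))))
  dimnames(out) <- list(window, profile_resno(traj))
  structure(out, class = c("sse_timeline", "matrix"))
}

#' @export
print.sse_timeline <- function(x, ...) {
  tab <- table(factor(x, levels = c("H", "G", "E", "T", "S", "C")))
  cat(sprintf("SSE timeline: %d frame(s) x %d residues; class content: %s\n",
              nrow(x), ncol(x),
              paste(sprintf("%s %.0f%%", names(tab),
                            100 * tab / sum(tab)), collapse = ", ")))
  invisible(x)
}

#' Per-residue secondary-structure class fractions
#'
#' @param timeline an [assign_sse()] result.
#' @return numeric matrix, residues x classes (`H G E T S C`), each row
#'   summing to 1.
#' @export
sse_fractions <- function(timeline) {
  classes <- c("H", "G", "E", "T", "S", "C")
  out <- t(apply(unclass(timeline), 2, function(col)
    table(factor(col, levels = classes)) / length(col)))
  colnames(out) <- classes
  out
}
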