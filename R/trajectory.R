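# Trajectory container: one topology shared by an ordered set of frames.
# Coordinates are stored bio3d-style as an n_frames x 3*n_atoms matrix
# (x1, y1, z1, x2, ...), in Angstrom.

#' Construct a trajectory object
#'
#' A trajectory bundles a topology (one row per atom) with an ordered set
#' of coordinate frames sharing that topology. All coordinates are in
#' Angstrom; residue numbering is the author numbering of the source file
#' and is never renumbered.
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom
#'   name, e.g. "CA"), `resname` (3-letter residue code), `chain`
#'   (single character), `resno` (author residue number, strictly
#'   increasing within a chain) and optionally `element` (inferred from
#'   `name` when absent) and `occ` (occupancy).
#' @param xyz numeric matrix with one row per frame and `3 * nrow(atoms)`
#'   columns in x,y,z atom-major order, or a single frame as an
#'   `n_atoms x 3` matrix.
#' @param frame_interval time between successive frames in picoseconds
#'   (metadata only; default 25).
#' @return an object of class `"trajectory"`.
#' @seealso [read_multimodel_pdb()], [select_atoms()]
#' @export
trajectory <- function(atoms, xyz, frame_interval = 25) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "chain", "resno")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  atoms$name <- trimws(as.character(atoms$name))
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  if (is.null(atoms$element) || all(is.na(atoms$element)))
    atoms$element <- infer_element(atoms$name)
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  n_atoms <- nrow(atoms)
  if (is.matrix(xyz) && ncol(xyz) == 3 && nrow(xyz) == n_atoms)
    xyz <- matrix(t(xyz), nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms)
    stop("xyz has ", ncol(xyz), " columns; expected ", 3 * n_atoms,
         " (3 per atom)")
  if (nrow(xyz) < 1) stop("trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("coordinates must all be finite")
  # residue numbering must increase within each chain
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn)) # ties allowed (atoms of one residue), decreases not
      stop("residue numbers must be non-decreasing within chain ", ch)
  }
  structure(list(atoms = atoms, xyz = unname(xyz),
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frame(s), %d atoms, %d residues, %g ps/frame\n",
              n_frames(x), n_atoms(x), n_residues(x), x$frame_interval))
  invisible(x)
}

#' Number of frames / atoms / residues in a trajectory
#' @param traj a [trajectory()] object.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' @rdname n_frames
#' @export
n_residues <- function(traj) length(unique(residue_ids(traj)))

# "chain|resno" key preserving order of appearance
residue_ids <- function(traj) {
  paste(traj$atoms$chain, traj$atoms$resno, sep = "|")
}

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj a trajectory.
#' @param i frame index (1-based).
#' @return numeric matrix, Angstrom.
#' @export
frame_coords <- function(traj, i = 1) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

# replace coordinates of frame i from an n_atoms x 3 matrix
set_frame_coords <- function(traj, i, m) {
  traj$xyz[i, ] <- as.numeric(t(m))
  traj
}

# subset a trajectory by atom indices (keeps frame order)
subset_atoms <- function(traj, idx) {
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  trajectory(traj$atoms[idx, , drop = FALSE],
             traj$xyz[, cols, drop = FALSE],
             frame_interval = traj$frame_interval)
}

# subset frames, keeping topology
subset_frames <- function(traj, frames) {
  if (length(frames) < 1) stop("empty frame window")
  if (any(frames < 1 | frames > n_frames(traj)))
    stop("frame window out of range")
  trajectory(traj$atoms, traj$xyz[frames, , drop = FALSE],
             frame_interval = traj$frame_interval)
}

#' Select analysis atoms from a trajectory
#'
#' Returns a reduced trajectory containing only the requested atoms, in
#' the original residue order. Selector `"CB_or_CA_for_GLY"` gives exactly
#' one atom per residue: the C-beta, or the C-alpha for glycine (which has
#' none) -- the convention used for residue interaction networks.
#'
#' @param traj a [trajectory()].
#' @param selector one of `"CA"`, `"CB_or_CA_for_GLY"`, `"backbone"`
#'   (N, CA, C, O), `"heavy"` (all non-hydrogen), `"all"`.
#' @return a trajectory restricted to the selected atoms.
#' @export
select_atoms <- function(traj, selector = c("CA", "CB_or_CA_for_GLY",
                                            "backbone", "heavy", "all")) {
  selector <- match.arg(selector)
  a <- traj$atoms
  idx <- switch(selector,
    all = seq_len(nrow(a)),
    CA = which(a$name == "CA"),
    backbone = which(a$name %in% c("N", "CA", "C", "O")),
    heavy = which(a$element != "H"),
    CB_or_CA_for_GLY = {
      rid <- residue_ids(traj)
      ures <- unique(rid)
      out <- integer(length(ures))
      missing_res <- character(0)
      for (k in seq_along(ures)) {
        rows <- which(rid == ures[k])
        want <- if (a$resname[rows[1]] == "GLY") "CA" else "CB"
        hit <- rows[a$name[rows] == want]
        if (length(hit) != 1) {
          missing_res <- c(missing_res,
                           paste0(a$resname[rows[1]], a$resno[rows[1]]))
          out[k] <- NA_integer_
        } else out[k] <- hit
      }
      if (length(missing_res))
        stop("selection error: residue(s) lacking required CB/CA atom: ",
             paste(missing_res, collapse = ", "))
      out
    })
  if (selector == "CA") {
    rid <- residue_ids(traj)
    lacking <- setdiff(unique(rid), unique(rid[idx]))
    if (length(lacking))
      stop("selection error: residue(s) lacking CA atom: ",
           paste(lacking, collapse = ", "))
  }
  if (length(idx) == 0) stop("selection error: empty selection")
  subset_atoms(traj, idx)
}
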