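# Multi-model PDB input/output. Parsing and formatting of the fixed-width
# records is delegated to bio3d; this layer adds the validation the
# downstream analyses rely on (consistent atom counts across models,
# finite coordinates, highest-occupancy altLoc resolution) and maps the
# result onto the trajectory container.

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame, ordered by MODEL number;
#' a file with no MODEL records yields a one-frame trajectory. The
#' topology is taken from the first model. When alternate locations are
#' present, only the highest-occupancy conformer of each atom is kept
#' (first on ties), so every frame is a single-conformer structure.
#'
#' @param path path to a PDB file.
#' @param frame_interval time between models in picoseconds (metadata;
#'   default 25).
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path, frame_interval = 25) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("structure error: no ATOM/HETATM records in ", path)

  # malformed coordinate fields -> parse error naming the line
  atom_lines <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(lines[atom_lines], fld[1], fld[2])))
    if (anyNA(v))
      stop("parse error: malformed ATOM record at line ",
           atom_lines[which(is.na(v))[1]], " of ", path)
  }

  # atom counts must agree across MODEL blocks
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(i) {
      sum(is_atom[seq(bounds[i], bounds[i + 1] - 1L)])
    }, integer(1))
    if (length(unique(counts)) != 1)
      stop("structure error: models have inconsistent atom counts (",
           paste(unique(counts), collapse = ", "), ") in ", path)
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(serial = a$eleno, name = trimws(a$elety),
                      resname = trimws(a$resid), chain = a$chain,
                      resno = a$resno,
                      element = toupper(trimws(a$elesy)),
                      occ = a$o, stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  blank <- is.na(atoms$element) | !nzchar(atoms$element)
  atoms$element[blank] <- infer_element(atoms$name[blank])
  traj <- trajectory(atoms, pdb$xyz, frame_interval = frame_interval)

  # highest-occupancy altLoc filter
  alt <- trimws(a$alt)
  alt[is.na(alt)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    occ <- atoms$occ
    occ[is.na(occ)] <- 1
    keep <- !logical(length(key))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      keep[rows] <- FALSE
      keep[rows[which.max(occ[rows])]] <- TRUE
    }
    traj <- subset_atoms(traj, which(keep))
  }
  traj
}

#' Write a trajectory as a multi-model PDB file
#'
#' Frames are written as consecutive `MODEL`/`ENDMDL` blocks in the
#' wwPDB fixed-width format (coordinates to 3 decimals).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param frames integer frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path, frames = seq_len(n_frames(traj))) {
  a <- traj$atoms
  occ <- if (is.null(a$occ)) rep(1, nrow(a)) else ifelse(is.na(a$occ), 1, a$occ)
  bio3d::write.pdb(file = path,
                   xyz = traj$xyz[frames, , drop = FALSE],
                   type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resno,
                   o = occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}
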