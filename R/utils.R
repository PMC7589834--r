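# Shared constants and small helpers.

# Standard atomic masses (u) and van der Waals radii (Angstrom) for the
# elements that occur in protein heavy-atom / hydrogen models.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

.aa_one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Boltzmann constant in kJ/(mol K), the unit free-energy landscapes report.
.kB <- 0.0083145

#' Infer the element symbol from a PDB atom name
#'
#' Used when the element column is absent from an input file. The first
#' alphabetic character of the atom name is taken, with the usual
#' protein-atom conventions (names beginning with a digit such as "1HB"
#' are hydrogens).
#'
#' @param name character vector of atom names (e.g. "CA", "OG1", "1HB").
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  first <- sub("^[0-9']*", "", nm)
  el <- substr(first, 1, 1)
  el[el == ""] <- NA_character_
  el
}

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    bad <- unique(toupper(element)[is.na(m)])
    stop("no mass tabulated for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Quasi-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
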