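#' Build a structure table
#'
#' The package represents a protein (or any atom set) as a plain tibble with
#' columns `element`, `x`, `y`, `z`, `resno`, `chain` and `radius` (van der
#' Waals, in Angstrom). Hydrogens may be present but all geometric stages
#' operate on heavy atoms.
#'
#' @param element Element symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param resno Residue numbers (integer).
#' @param chain Chain identifiers.
#' @param radius Optional per-atom vdW radii; defaults by element.
#' @return A tibble of atoms.
#' @export
structure_table <- function(element, x, y, z, resno = 1L, chain = "A",
                            radius = NULL) {
  stopifnot(all(is.finite(c(x, y, z))))
  radius <- radius %||% vdw_radius(element)
  stopifnot(all(radius > 0))
  tibble(element = element, x = x, y = y, z = z,
         resno = as.integer(resno), chain = chain, radius = radius)
}

#' Default van der Waals radii (Angstrom)
#'
#' Bondi-style radii with a 1.7 A fallback for unlisted elements.
#'
#' @param element Element symbols.
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(element) {
  r <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
         B = 1.92, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
  out <- unname(r[element])
  out[is.na(out)] <- 1.7
  out
}

#' Read a PDB file into a structure table
#'
#' Thin wrapper over [bio3d::read.pdb()]; keeps ATOM/HETATM records and maps
#' them to the package's atom tibble.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep HETATM records? Default `FALSE`.
#' @return A structure tibble (see [structure_table()]).
#' @export
read_structure <- function(path, keep_hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  el <- at$elesy
  bad <- is.na(el) | el == ""
  # fall back on the first letter of the atom name when the element column
  # is absent (minimal/legacy PDB writers)
  el[bad] <- sub("^[0-9]*", "", at$elety[bad])
  el[bad] <- paste0(substr(el[bad], 1, 1))
  structure_table(element = el, x = at$x, y = at$y, z = at$z,
                  resno = at$resno, chain = at$chain)
}

# Heavy atoms only, as a coordinate matrix.
heavy_coords <- function(atoms) {
  h <- atoms$element != "H"
  as.matrix(atoms[h, c("x", "y", "z")])
}
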