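# Low-level bridges to OpenBabel (via ChemmineOB) and ChemmineR.
#
# All user-facing chemistry takes standardized SMILES; these internals parse
# them once into plain atom/bond tables that the descriptor, fingerprint and
# stereocenter code consumes.

# Convert a vector of SMILES to another OB format in one call. All inputs
# must be parsable; callers guard with ob_parse_ok() or standardization.
ob_convert <- function(smiles, to = "CAN", neutralize = FALSE) {
  src <- paste0(paste(smiles, seq_along(smiles), sep = "\t"), "\n",
                collapse = "")
  if (neutralize) {
    ChemmineOB::convertFormat("SMI", to, src,
                              options = data.frame(names = "neutralize",
                                                   args = ""))
  } else {
    ChemmineOB::convertFormat("SMI", to, src)
  }
}

# Canonical SMILES for each input (vectorized, order-preserving).
ob_canonical <- function(smiles, neutralize = FALSE) {
  out <- ob_convert(smiles, "CAN", neutralize = neutralize)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(lines) != length(smiles)) {
    abort("canonicalization dropped records; input must be pre-validated")
  }
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
}

# TRUE where OpenBabel can parse the record.
ob_parse_ok <- function(smiles) {
  vapply(smiles, function(s) {
    ok <- tryCatch({
      suppressWarnings(
        ChemmineOB::forEachMol("SMILES", paste0(s, "\n"), identity)
      )
      TRUE
    }, error = function(e) FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

# OBMol references for a vector of valid SMILES.
ob_mols <- function(smiles) {
  src <- paste0(paste(smiles, seq_along(smiles), sep = "\t"), "\n",
                collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  if (length(mols) != length(smiles)) {
    abort("OpenBabel dropped records during parsing")
  }
  mols
}

# Molecular formula and average molecular weight per molecule.
ob_props <- function(smiles) {
  p <- ChemmineOB::prop_OB(ob_mols(smiles))
  tibble(formula = p$formula, mw = p$MW)
}

# Parse a molecular formula like "C10H7NOS2" into a named count vector.
parse_formula <- function(formula) {
  m <- str_match_all(formula, "([A-Z][a-z]?)([0-9]*)")[[1]]
  counts <- ifelse(m[, 3] == "", 1L, suppressWarnings(as.integer(m[, 3])))
  stats::setNames(counts, m[, 2])
}

default_valence <- function(element, charge) {
  base <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
            Cl = 1, Br = 1, I = 1, Si = 4)
  v <- unname(base[element])
  v[is.na(v)] <- 0
  adj <- numeric(length(element))
  adj[element %in% c("N", "P", "O", "S")] <- charge[element %in% c("N", "P", "O", "S")]
  adj[element %in% c("B")] <- -charge[element %in% c("B")]
  adj[element %in% c("C")] <- -abs(charge[element %in% c("C")])
  pmax(v + adj, 0)
}

# Heavy-atom connection tables for a vector of valid (ideally standardized)
# SMILES. Returns a list with one element per molecule:
#   atoms: tibble(idx, element, charge, implh, degree)
#   bonds: tibble(a1, a2, order, ring) -- ring flagged via cycle membership
parse_mols <- function(smiles) {
  sdfstr <- ob_convert(smiles, "SDF")
  sdf <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(sdfstr, "\n")[[1]]))
  )
  if (length(sdf) != length(smiles)) {
    abort("SDF conversion dropped records during parsing")
  }
  lapply(seq_along(smiles), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    element <- sub("_.*$", "", rownames(ab))
    chg_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, nrow(ab))
    charge <- ifelse(chg_code == 0, 0, 4 - chg_code)
    n <- length(element)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = if (length(bb)) 1 else 0,
                                       ncol = max(3, length(bb)))
    bonds <- if (nrow(bb) > 0) {
      tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
    } else {
      tibble(a1 = integer(), a2 = integer(), order = integer())
    }
    degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
    bondsum <- numeric(n)
    if (nrow(bonds) > 0) {
      for (k in seq_len(nrow(bonds))) {
        o <- bonds$order[k]
        bondsum[bonds$a1[k]] <- bondsum[bonds$a1[k]] + o
        bondsum[bonds$a2[k]] <- bondsum[bonds$a2[k]] + o
      }
    }
    implh <- pmax(default_valence(element, charge) - bondsum, 0)
    bonds$ring <- ring_bond_flags(n, bonds)
    list(
      atoms = tibble(idx = seq_len(n), element = element, charge = charge,
                     implh = implh, degree = degree),
      bonds = bonds
    )
  })
}

# A bond is a ring bond iff it is not a bridge of the molecular graph.
ring_bond_flags <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds))
  flags[as.integer(br)] <- FALSE
  flags
}
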