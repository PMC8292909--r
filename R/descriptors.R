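#' Compute drug-likeness descriptors for standardized molecules
#'
#' Descriptors follow the library-preparation conventions used for
#' screening-library triage:
#'
#' * `mw` — average molecular weight (Da), implicit hydrogens included.
#' * `n_atoms` — total atom count *including* hydrogens (the stricter reading
#'   of "total number of atoms"; set `count_hydrogens = FALSE` for heavy atoms
#'   only).
#' * `n_rotatable` — non-ring single bonds between two heavy atoms that each
#'   carry at least one further heavy neighbour, excluding amide C–N bonds.
#' * `n_chiral` — atoms bearing four distinct substituents (assigned or not),
#'   determined by comparing canonical branch signatures.
#' * `elements` — list-column of element symbols present (hydrogen included
#'   whenever the formula contains it).
#'
#' @param molecules Tibble with `id` and `smiles` (standardized), or a
#'   character vector of SMILES.
#' @param count_hydrogens Should `n_atoms` include hydrogens? Default `TRUE`.
#' @return The input tibble with descriptor columns appended.
#' @examples
#' compute_descriptors(standardize_molecules("CCO"))
#' @export
compute_descriptors <- function(molecules, count_hydrogens = TRUE) {
  if (is.character(molecules)) {
    molecules <- tibble(
      id = names(molecules) %||% sprintf("mol_%d", seq_along(molecules)),
      smiles = unname(molecules)
    )
  }
  ok <- !is.na(molecules$smiles)
  res <- tibble(
    mw = rep(NA_real_, nrow(molecules)),
    n_atoms = NA_integer_, n_heavy = NA_integer_,
    n_rotatable = NA_integer_, n_chiral = NA_integer_,
    elements = vector("list", nrow(molecules))
  )
  if (any(ok)) {
    smi <- molecules$smiles[ok]
    pr <- ob_props(smi)
    tabs <- parse_mols(smi)
    counts <- lapply(pr$formula, parse_formula)
    n_h <- vapply(counts, function(ct) sum(ct[names(ct) == "H"]), numeric(1))
    n_heavy <- vapply(counts, function(ct) sum(ct[names(ct) != "H"]),
                      numeric(1))
    res$mw[ok] <- pr$mw
    res$n_heavy[ok] <- as.integer(n_heavy)
    res$n_atoms[ok] <- as.integer(n_heavy + if (count_hydrogens) n_h else 0)
    res$n_rotatable[ok] <- vapply(tabs, count_rotatable_bonds, integer(1))
    res$n_chiral[ok] <- vapply(tabs, count_stereocenters, integer(1))
    res$elements[ok] <- lapply(counts, function(ct) sort(names(ct)))
  }
  bind_cols(molecules, res)
}

# Rotatable bonds on a heavy-atom connection table, by the stated definition.
count_rotatable_bonds <- function(tab) {
  b <- tab$bonds
  if (nrow(b) == 0) return(0L)
  deg <- tab$atoms$degree
  rot <- b$order == 1 & !b$ring & deg[b$a1] >= 2 & deg[b$a2] >= 2 &
    !is_amide_cn(tab, b$a1, b$a2)
  as.integer(sum(rot))
}

# TRUE where bond (a1, a2) is an amide C-N: a C=O carbon singly bonded to N.
is_amide_cn <- function(tab, a1, a2) {
  el <- tab$atoms$element
  carbonyl <- rep(FALSE, nrow(tab$atoms))
  dbl_o <- tab$bonds$order == 2 &
    ((el[tab$bonds$a1] == "C" & el[tab$bonds$a2] == "O") |
       (el[tab$bonds$a2] == "C" & el[tab$bonds$a1] == "O"))
  if (any(dbl_o)) {
    cs <- ifelse(el[tab$bonds$a1[dbl_o]] == "C",
                 tab$bonds$a1[dbl_o], tab$bonds$a2[dbl_o])
    carbonyl[cs] <- TRUE
  }
  (el[a1] == "C" & carbonyl[a1] & el[a2] == "N") |
    (el[a2] == "C" & carbonyl[a2] & el[a1] == "N")
}

# Stereocenters: tetravalent atoms with four single-bonded substituents
# (implicit hydrogens counted, at most one), all four branches distinct.
# Branch identity is decided by a breadth-first canonical signature of the
# branch as seen from the candidate atom.
count_stereocenters <- function(tab) {
  atoms <- tab$atoms; bonds <- tab$bonds
  n <- nrow(atoms)
  if (n == 0) return(0L)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  single <- rep(TRUE, n)
  if (nrow(bonds) > 0) {
    multi <- bonds$order > 1
    single[unique(c(bonds$a1[multi], bonds$a2[multi]))] <- FALSE
  }
  cand <- which(atoms$degree + atoms$implh == 4 & atoms$implh <= 1 & single &
                  atoms$degree >= 3)
  n_chiral <- 0L
  for (a in cand) {
    sigs <- vapply(adj[[a]], function(b) branch_signature(a, b, atoms, adj),
                   character(1))
    if (atoms$implh[a] == 1) sigs <- c(sigs, "H")
    if (length(unique(sigs)) == 4) n_chiral <- n_chiral + 1L
  }
  n_chiral
}

# Canonical signature of the branch rooted at `root`, excluding `from`:
# per-BFS-shell sorted atom descriptors. Distinguishes branches up to graph
# symmetry at the resolution of (element, degree, implicit H, charge).
branch_signature <- function(from, root, atoms, adj) {
  n <- nrow(atoms)
  dist <- rep(NA_integer_, n)
  dist[from] <- -1L  # excluded
  dist[root] <- 0L
  frontier <- root
  shells <- character(0)
  d <- 0L
  while (length(frontier) > 0) {
    desc <- paste(atoms$element[frontier], atoms$degree[frontier],
                  atoms$implh[frontier], atoms$charge[frontier], sep = ".")
    shells <- c(shells, paste(sort(desc), collapse = ","))
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d + 1L
    frontier <- nxt
    d <- d + 1L
  }
  paste(shells, collapse = "|")
}
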