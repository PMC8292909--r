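#' SPOP degron motif definition
#'
#' The SPOP-binding degron is a five-residue short linear motif with
#' consensus nonpolar-polar-S-S/T-S/T (the EWS-FLI1 degron VTSSS is the
#' motivating instance). Position classes follow the canonical SPOP-degron
#' literature and are fully configurable.
#'
#' @param phi Residues accepted at position 1 (nonpolar class).
#' @param pi_ Residues accepted at position 2 (polar class).
#' @param p3,p4,p5 Residues accepted at positions 3-5.
#' @return A `degron_motif`: list of five character vectors.
#' @export
degron_motif <- function(phi = c("A", "V", "L", "I", "M", "F", "P", "G",
                                 "W", "Y", "C"),
                         pi_ = c("S", "T", "N", "Q", "D", "E", "H", "K",
                                 "R", "Y", "C"),
                         p3 = "S", p4 = c("S", "T"), p5 = c("S", "T")) {
  motif <- list(phi, pi_, p3, p4, p5)
  stopifnot(all(lengths(motif) > 0),
            all(unlist(motif) %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  structure(motif, class = "degron_motif")
}

aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Scan a protein sequence for SPOP degron matches
#'
#' Tests every overlapping 5-mer against the motif; `X` never matches.
#' Coordinates are 1-based, matching protein residue numbering.
#'
#' @param sequences Named character vector of amino-acid sequences, a single
#'   string, or a tibble with `seq_id` and `sequence`.
#' @param motif A [degron_motif()].
#' @return Tibble `(seq_id, start, peptide)` in ascending start order.
#' @examples
#' scan_spop_degrons("MPVTSSSFFGA")   # one VTSSS match at position 3
#' @export
scan_spop_degrons <- function(sequences, motif = degron_motif()) {
  seqs <- as_sequence_set(sequences)
  purrr::map_dfr(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    check_sequence(s, names(seqs)[i])
    L <- str_length(s)
    if (L < 5) {
      return(tibble(seq_id = character(), start = integer(),
                    peptide = character()))
    }
    chars <- strsplit(s, "")[[1]]
    hits <- which(vapply(seq_len(L - 4), function(p) {
      all(vapply(1:5, function(j) chars[p + j - 1] %in% motif[[j]],
                 logical(1)))
    }, logical(1)))
    tibble(seq_id = names(seqs)[i], start = as.integer(hits),
           peptide = vapply(hits, function(p) paste(chars[p:(p + 4)],
                                                    collapse = ""),
                            character(1)))
  })
}

as_sequence_set <- function(sequences) {
  if (is_tibble(sequences) || is.data.frame(sequences)) {
    stats::setNames(as.list(sequences$sequence), sequences$seq_id)
  } else {
    if (is.null(names(sequences))) {
      names(sequences) <- if (length(sequences) == 1) "seq_1" else
        sprintf("seq_%d", seq_along(sequences))
    }
    as.list(sequences)
  }
}

check_sequence <- function(s, id) {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0) {
    abort(sprintf("illegal character '%s' at position %d of %s",
                  chars[bad[1]], bad[1], id))
  }
  invisible(TRUE)
}

#' Apply point substitutions and re-scan for degrons
#'
#' Mirrors mutational degron knockouts (e.g. the S464A/S465A/S466A "3A"
#' serine-to-alanine mutant that ablates SPOP binding): substitute residues,
#' scan before and after, and report matches lost and gained.
#'
#' @param sequence A single amino-acid string.
#' @param positions Integer positions (1-based) to substitute.
#' @param residues Replacement residues (recycled to `length(positions)`).
#' @param motif A [degron_motif()].
#' @return List with `before`, `after` (match tibbles), `lost`, `gained`,
#'   and the mutated sequence.
#' @examples
#' mutate_and_rescan("MPVTSSSFFGA", positions = 5:7, residues = "A")
#' @export
mutate_and_rescan <- function(sequence, positions, residues,
                              motif = degron_motif()) {
  stopifnot(length(sequence) == 1)
  L <- str_length(sequence)
  if (any(positions < 1 | positions > L)) {
    abort(sprintf("substitution position out of range 1..%d", L))
  }
  residues <- rep_len(residues, length(positions))
  stopifnot(all(residues %in% aa_alphabet()))
  chars <- strsplit(sequence, "")[[1]]
  chars[positions] <- residues
  mutated <- paste(chars, collapse = "")
  before <- scan_spop_degrons(c(wt = sequence), motif)
  after <- scan_spop_degrons(c(mut = mutated), motif)
  list(
    before = before, after = after,
    lost = anti_join(select(before, "start", "peptide"),
                     select(after, "start"), by = "start"),
    gained = anti_join(select(after, "start", "peptide"),
                       select(before, "start"), by = "start"),
    mutated_sequence = mutated
  )
}

#' Scan sequences from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @param motif A [degron_motif()].
#' @return Match tibble as from [scan_spop_degrons()].
#' @export
scan_fasta_degrons <- function(path, motif = degron_motif()) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA input")
  }
  aa <- Biostrings::readAAStringSet(path)
  scan_spop_degrons(stats::setNames(as.character(aa), names(aa)), motif)
}
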