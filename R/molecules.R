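#' Read a SMILES file into a molecule table
#'
#' One record per line: a SMILES string optionally followed by whitespace and
#' an identifier. Missing identifiers become `mol_<line>`.
#'
#' @param path Path to a `.smi` file.
#' @return A tibble with columns `id`, `smiles`, `source_line`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[str_trim(lines) != ""]
  parts <- str_split(str_trim(lines), "\\s+", n = 2)
  tibble(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1 && parts[[i]][2] != "") parts[[i]][2]
      else sprintf("mol_%d", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1),
    source_line = lines
  )
}

#' Read an SDF file into a molecule table
#'
#' Records are converted to SMILES via OpenBabel; ids come from the SDF
#' title line (falling back to `mol_<n>`).
#'
#' @param path Path to an SDF file.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_sdf <- function(path) {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  ChemmineOB::convertFormatFile("SDF", "SMI", path, tmp)
  lines <- readLines(tmp, warn = FALSE)
  lines <- lines[str_trim(lines) != ""]
  parts <- str_split(lines, "\t|\\s+", n = 2)
  tibble(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1 && parts[[i]][2] != "") parts[[i]][2]
      else sprintf("mol_%d", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}

#' Write a molecule table to a SMILES file
#'
#' @param molecules Tibble with `smiles` and `id` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(molecules, path) {
  writeLines(paste(molecules$smiles, molecules$id, sep = "\t"), path)
  invisible(path)
}

#' Write a molecule table to an SDF file
#'
#' @param molecules Tibble with `smiles` and `id` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molecules, path) {
  src <- paste0(paste(molecules$smiles, molecules$id, sep = "\t"), "\n",
                collapse = "")
  writeLines(ChemmineOB::convertFormat("SMI", "SDF", src), path)
  invisible(path)
}

#' Standardize raw molecule records
#'
#' Applies the screening-library standardization contract: keep the largest
#' organic fragment (salt/counter-ion stripping), clear isotope labels,
#' neutralize charges where a plain (de)protonation permits, and write one
#' canonical SMILES form (so Kekule and aromatic inputs of the same molecule
#' collapse to identical records). The operation is idempotent.
#'
#' @param molecules A tibble with `id` and `smiles` columns (e.g. from
#'   [read_smiles()]), or a bare character vector of SMILES.
#' @return A tibble with columns `id`, `smiles` (standardized canonical form;
#'   `NA` on failure), `status` (`"ok"`, `"parse_error"` or `"empty"`) and
#'   `input_smiles`.
#' @examples
#' standardize_molecules(c("CC(=O)[O-].[Na+]", "[13CH4]", "C1=CC=CC=C1"))
#' @export
standardize_molecules <- function(molecules) {
  if (is.character(molecules)) {
    molecules <- tibble(
      id = names(molecules) %||% sprintf("mol_%d", seq_along(molecules)),
      smiles = unname(molecules)
    )
  }
  stopifnot(all(c("id", "smiles") %in% names(molecules)))
  out <- purrr::map(molecules$smiles, standardize_one)
  tibble(
    id = molecules$id,
    smiles = map_chr(out, "smiles"),
    status = map_chr(out, "status"),
    input_smiles = molecules$smiles
  )
}

standardize_one <- function(smi) {
  smi <- str_trim(smi %||% "")
  if (is.na(smi) || smi == "") {
    return(list(smiles = NA_character_, status = "empty"))
  }
  # Isotope labels are bracket-leading digits in SMILES; strip them textually
  # ([13CH4] -> [CH4]) before parsing.
  smi <- gsub("\\[([0-9]+)", "[", smi)
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  frags <- frags[frags != ""]
  if (length(frags) == 0) {
    return(list(smiles = NA_character_, status = "empty"))
  }
  if (!all(ob_parse_ok(frags))) {
    return(list(smiles = NA_character_, status = "parse_error"))
  }
  frag <- pick_main_fragment(frags)
  can <- tryCatch(ob_canonical(frag, neutralize = TRUE),
                  error = function(e) NA_character_)
  if (is.na(can) || can == "") {
    return(list(smiles = NA_character_, status = "parse_error"))
  }
  list(smiles = can, status = "ok")
}

# Largest organic (carbon-containing) fragment; ties broken by molecular
# weight, then lexicographically — deterministic for duplicate runs.
pick_main_fragment <- function(frags) {
  if (length(frags) == 1) return(frags)
  pr <- ob_props(frags)
  counts <- lapply(pr$formula, parse_formula)
  heavy <- vapply(counts, function(ct) sum(ct[names(ct) != "H"]), numeric(1))
  organic <- vapply(counts, function(ct) "C" %in% names(ct), logical(1))
  pool <- if (any(organic)) which(organic) else seq_along(frags)
  ord <- pool[order(-heavy[pool], -pr$mw[pool], frags[pool])]
  frags[ord[1]]
}
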