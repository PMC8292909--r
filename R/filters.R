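#' Screening-library filter configuration
#'
#' Bounds follow standard drug-like library preparation: molecular weight in
#' \[100, 700\] Da, at most 6 stereocenters, at most 60 atoms (hydrogens
#' included), at most 15 rotatable bonds, and elements restricted to
#' C, N, S, H, O, P, B and the halogens. All bounds are inclusive.
#'
#' @param mw_min,mw_max Molecular weight window in Da.
#' @param max_chiral Maximum number of stereocenters.
#' @param max_atoms Maximum total atom count.
#' @param max_rotatable Maximum rotatable-bond count.
#' @param allowed_elements Permitted element symbols.
#' @param count_hydrogens Whether `max_atoms` counts hydrogens.
#' @param rulesets Named list of SMARTS rule tables (columns `rule_id`,
#'   `smarts`); defaults to the shipped PAINS, toxicophore and medchem-rule
#'   subsets (see [default_rulesets()]).
#' @return A `filter_config` list.
#' @export
filter_config <- function(mw_min = 100, mw_max = 700, max_chiral = 6,
                          max_atoms = 60, max_rotatable = 15,
                          allowed_elements = c("C", "N", "S", "H", "O", "P",
                                               "B", "F", "Cl", "Br", "I"),
                          count_hydrogens = TRUE,
                          rulesets = default_rulesets()) {
  stopifnot(mw_min < mw_max, max_chiral >= 0, max_atoms >= 0,
            max_rotatable >= 0)
  validate_rulesets(rulesets)
  structure(
    list(mw_min = mw_min, mw_max = mw_max, max_chiral = max_chiral,
         max_atoms = max_atoms, max_rotatable = max_rotatable,
         allowed_elements = allowed_elements,
         count_hydrogens = count_hydrogens, rulesets = rulesets),
    class = "filter_config"
  )
}

#' Shipped substructure rulesets
#'
#' Small, documented SMARTS collections standing in for the vendor PAINS,
#' toxicophore and medicinal-chemistry rule sets (whose exact contents are
#' not public). Fully replaceable via the `rulesets` argument of
#' [filter_config()].
#'
#' @return Named list of tibbles with columns `rule_id`, `smarts`, `note`.
#' @export
default_rulesets <- function() {
  dir <- system.file("extdata", "smarts", package = "pocketscreen")
  files <- c(PAINS = "pains.tsv", toxicophores = "toxicophores.tsv",
             medchem_rules = "medchem_rules.tsv")
  lapply(files, function(f) {
    as_tibble(read.delim(file.path(dir, f), stringsAsFactors = FALSE))
  })
}

# Malformed SMARTS must fail at configuration time, not per molecule.
validate_rulesets <- function(rulesets) {
  probe <- ob_mols("CCO")
  for (nm in names(rulesets)) {
    rs <- rulesets[[nm]]
    stopifnot(all(c("rule_id", "smarts") %in% names(rs)))
    for (i in seq_len(nrow(rs))) {
      ok <- tryCatch({
        suppressWarnings(ChemmineOB::smartsSearch_OB(probe, rs$smarts[i]))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        abort(sprintf("malformed SMARTS in ruleset '%s': %s", nm,
                      rs$rule_id[i]))
      }
    }
  }
  invisible(TRUE)
}

#' Apply property filters to descriptor rows
#'
#' A molecule passes iff its weight lies in the (inclusive) window and all
#' count descriptors sit at or under their caps with only allowed elements.
#' Every violated rule is named.
#'
#' @param descriptors Tibble from [compute_descriptors()].
#' @param config A [filter_config()].
#' @return `descriptors` with `prop_pass` (logical) and `prop_reasons`
#'   (list-column of violated rule names) appended.
#' @export
apply_property_filters <- function(descriptors, config = filter_config()) {
  reasons <- pmap(
    list(descriptors$mw, descriptors$n_chiral, descriptors$n_atoms,
         descriptors$n_rotatable, descriptors$elements),
    function(mw, nc, na_, nr, el) {
      r <- character(0)
      if (is.na(mw)) return("no_descriptors")
      if (mw < config$mw_min) r <- c(r, "mw_below_min")
      if (mw > config$mw_max) r <- c(r, "mw_above_max")
      if (nc > config$max_chiral) r <- c(r, "too_many_chiral")
      if (na_ > config$max_atoms) r <- c(r, "too_many_atoms")
      if (nr > config$max_rotatable) r <- c(r, "too_many_rotatable")
      if (!all(el %in% config$allowed_elements)) r <- c(r, "element_not_allowed")
      r
    }
  )
  descriptors$prop_pass <- lengths(reasons) == 0
  descriptors$prop_reasons <- reasons
  descriptors
}

#' Apply substructure filters
#'
#' Fails a molecule iff any pattern of any configured ruleset matches; all
#' matching rule identifiers are reported.
#'
#' @param molecules Tibble with `id` and standardized `smiles`.
#' @param config A [filter_config()].
#' @return `molecules` with `sub_pass` and `sub_matches` (list-column of
#'   matched rule ids) appended.
#' @export
apply_substructure_filters <- function(molecules, config = filter_config()) {
  n <- nrow(molecules)
  matches <- replicate(n, character(0), simplify = FALSE)
  ok <- !is.na(molecules$smiles)
  if (any(ok) && length(config$rulesets) > 0) {
    mols <- ob_mols(molecules$smiles[ok])
    idx_ok <- which(ok)
    for (nm in names(config$rulesets)) {
      rs <- config$rulesets[[nm]]
      for (i in seq_len(nrow(rs))) {
        hit <- suppressWarnings(
          ChemmineOB::smartsSearch_OB(mols, rs$smarts[i])
        ) > 0
        for (j in which(hit)) {
          matches[[idx_ok[j]]] <- c(matches[[idx_ok[j]]], rs$rule_id[i])
        }
      }
    }
  }
  molecules$sub_pass <- lengths(matches) == 0
  molecules$sub_matches <- matches
  molecules
}

#' Run the full library filtering pipeline
#'
#' Stages are applied in fixed order: standardize, property filters,
#' substructure filters. The surviving stream preserves input order and the
#' whole pipeline is deterministic.
#'
#' @param molecules Tibble with `id` and `smiles` (raw), or character vector.
#' @param config A [filter_config()].
#' @return A `filter_result` list: `kept` (tibble of survivors with
#'   descriptors), `table` (per-compound stage outcomes and reasons) and
#'   `report` (a `filter_report` with stage counts).
#' @examples
#' res <- filter_library(c("CCO", "c1ccccc1CCN", "CC(=O)[O-].[Na+]"))
#' res$report
#' @export
filter_library <- function(molecules, config = filter_config()) {
  std <- standardize_molecules(molecules)
  n_input <- nrow(std)
  desc <- compute_descriptors(std, count_hydrogens = config$count_hydrogens)
  desc <- apply_property_filters(desc, config)
  desc <- apply_substructure_filters(desc, config)
  desc$reason <- pmap_chr3(desc)
  kept <- dplyr::filter(desc, .data$status == "ok" & .data$prop_pass &
                          .data$sub_pass)
  report <- new_filter_report(
    n_input = n_input,
    n_standardized = sum(desc$status == "ok"),
    n_property_pass = sum(desc$status == "ok" & desc$prop_pass),
    n_surviving = nrow(kept),
    reasons = dplyr::count(dplyr::filter(desc, .data$reason != "pass"),
                           .data$reason, name = "n")
  )
  structure(list(kept = kept, table = desc, report = report),
            class = "filter_result")
}

# First failing stage/reason per compound ("pass" for survivors).
pmap_chr3 <- function(desc) {
  vapply(seq_len(nrow(desc)), function(i) {
    if (desc$status[i] != "ok") return(desc$status[i])
    if (!desc$prop_pass[i]) return(desc$prop_reasons[[i]][1])
    if (!desc$sub_pass[i]) return(paste0("substructure:",
                                         desc$sub_matches[[i]][1]))
    "pass"
  }, character(1))
}

new_filter_report <- function(n_input, n_standardized, n_property_pass,
                              n_surviving, reasons) {
  stopifnot(n_surviving <= n_property_pass,
            n_property_pass <= n_standardized, n_standardized <= n_input)
  structure(list(n_input = n_input, n_standardized = n_standardized,
                 n_property_pass = n_property_pass,
                 n_surviving = n_surviving, reasons = reasons),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input:          %d\n", x$n_input))
  cat(sprintf("  standardized:   %d\n", x$n_standardized))
  cat(sprintf("  property pass:  %d\n", x$n_property_pass))
  cat(sprintf("  surviving:      %d\n", x$n_surviving))
  if (nrow(x$reasons) > 0) {
    cat("  rejections:\n")
    for (i in seq_len(nrow(x$reasons))) {
      cat(sprintf("    %-28s %d\n", x$reasons$reason[i], x$reasons$n[i]))
    }
  }
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @rdname filter_library
#' @param x A `filter_report` or `filter_result`.
#' @param ... Unused.
#' @export
tidy.filter_report <- function(x, ...) x$reasons

#' @export
tidy.filter_result <- function(x, ...) tidy(x$report)

#' @export
glance.filter_report <- function(x, ...) {
  tibble(n_input = x$n_input, n_standardized = x$n_standardized,
         n_property_pass = x$n_property_pass, n_surviving = x$n_surviving)
}

#' @export
glance.filter_result <- function(x, ...) glance(x$report)

#' @export
autoplot.filter_report <- function(object, ...) {
  ggplot(object$reasons, aes(x = stats::reorder(.data$reason, .data$n),
                             y = .data$n)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "compounds rejected") +
    theme_minimal()
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, n_standardized = report$n_standardized,
         n_property_pass = report$n_property_pass,
         n_surviving = report$n_surviving, reasons = report$reasons),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
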