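# Library standardization, descriptors, and the filter pipeline.

test_that("standardization strips salts, isotopes and unifies tautomer-free forms", {
  std <- standardize_molecules(c(
    salt = "CC(=O)[O-].[Na+]",
    isotope = "[13CH4]",
    kekule = "C1=CC=CC=C1",
    aromatic = "c1ccccc1"
  ))
  expect_equal(std$status, rep("ok", 4))
  # salt: acetate fragment kept and neutralized to acetic acid
  expect_equal(std$smiles[1], standardize_molecules("CC(=O)O")$smiles[1])
  # isotope label cleared: canonical methane
  expect_equal(std$smiles[2], standardize_molecules("C")$smiles[1])
  # Kekule and aromatic benzene collapse to one canonical form
  expect_identical(std$smiles[3], std$smiles[4])
})

test_that("standardization reports parse errors and empties with reasons", {
  std <- standardize_molecules(c("C1CC(", "", "CCO"))
  expect_equal(std$status, c("parse_error", "empty", "ok"))
  expect_true(is.na(std$smiles[1]) && is.na(std$smiles[2]))
})

test_that("standardization is idempotent across a generated library", {
  lib <- make_ligand_library(300, seed = 101)
  once <- standardize_molecules(lib[, c("id", "smiles")])
  ok <- once$status == "ok"
  twice <- standardize_molecules(once[ok, c("id", "smiles")])
  expect_identical(twice$smiles, once$smiles[ok])
  expect_true(all(twice$status == "ok"))
})

test_that("descriptors match hand-derived values", {
  d <- compute_descriptors(standardize_molecules(
    c("CCO", "CC", "CCCCCC", "C[C@H](N)C(=O)O")))
  expect_equal(d$mw[1], 46.07, tolerance = 1e-3)
  expect_equal(d$n_atoms[1], 9L)        # C2H6O
  expect_equal(d$n_rotatable[1], 0L)    # both heavy neighbours terminal-ish
  expect_equal(d$n_chiral[1], 0L)
  expect_equal(d$n_rotatable[2], 0L)    # ethane: both atoms terminal
  expect_equal(d$n_rotatable[3], 3L)    # n-hexane
  expect_equal(d$n_chiral[4], 1L)       # L-alanine alpha carbon
  expect_setequal(d$elements[[1]], c("C", "H", "O"))
})

test_that("rotatable-bond counts equal the brute-force oracle on small molecules", {
  lib <- make_ligand_library(120, seed = 55)
  std <- standardize_molecules(lib[, c("id", "smiles")])
  std <- std[std$status == "ok", ]
  desc <- compute_descriptors(std)
  small <- which(desc$n_heavy <= 20)
  tabs <- pocketscreen:::parse_mols(desc$smiles[small])
  oracle <- vapply(tabs, oracle_rotatable, integer(1))
  expect_equal(desc$n_rotatable[small], oracle)
})

test_that("property filters respect inclusive bounds and name violations", {
  desc <- tibble::tibble(
    id = c("benzene", "silane", "at_bounds"),
    smiles = NA_character_, status = "ok",
    mw = c(78.11, 150.3, 700), n_atoms = c(12L, 24L, 60L),
    n_heavy = c(6L, 11L, 40L), n_rotatable = c(0L, 1L, 15L),
    n_chiral = c(0L, 0L, 6L),
    elements = list(c("C", "H"), c("C", "H", "Si"), c("C", "H", "N", "O"))
  )
  out <- apply_property_filters(desc)
  expect_false(out$prop_pass[1])
  expect_true("mw_below_min" %in% out$prop_reasons[[1]])
  expect_false(out$prop_pass[2])
  expect_true("element_not_allowed" %in% out$prop_reasons[[2]])
  expect_true(out$prop_pass[3])   # exactly at every bound: passes
})

test_that("substructure filters flag PAINS cores and pass clean molecules", {
  mols <- standardize_molecules(c(rhod = "O=C1NC(=S)SC1=Cc1ccccc1",
                                  etoh = "CCO"))
  out <- apply_substructure_filters(mols)
  expect_false(out$sub_pass[1])
  expect_true(any(grepl("rhodanine", out$sub_matches[[1]])))
  expect_true(out$sub_pass[2])
  expect_length(out$sub_matches[[2]], 0)
  # empty ruleset: vacuous pass
  cfg0 <- filter_config(rulesets = list())
  out0 <- apply_substructure_filters(mols, cfg0)
  expect_true(all(out0$sub_pass))
})

test_that("malformed SMARTS fails at configuration time", {
  bad <- list(PAINS = tibble::tibble(rule_id = "broken", smarts = "C1CC("))
  expect_error(filter_config(rulesets = bad), "malformed SMARTS")
})

test_that("filter_library recovers planted truth exactly and deterministically", {
  lib <- make_ligand_library(100, seed = 7)
  res <- filter_library(lib[, c("id", "smiles")])
  expect_equal(res$report$n_input, 100)
  expect_equal(res$report$n_surviving, sum(lib$expect_pass))
  # per-compound agreement with the construction truth
  tab <- dplyr::left_join(res$table,
                          lib[, c("id", "expect_pass", "expect_reason")],
                          by = "id")
  agree <- mapply(function(r, er) {
    if (er == "pass") r == "pass" else startsWith(r, er)
  }, tab$reason, tab$expect_reason)
  expect_true(all(agree))
  # stage monotonicity
  expect_true(res$report$n_surviving <= res$report$n_property_pass)
  expect_true(res$report$n_property_pass <= res$report$n_standardized)
  expect_true(res$report$n_standardized <= res$report$n_input)
  # determinism: identical rerun
  res2 <- filter_library(lib[, c("id", "smiles")])
  expect_identical(res$table$reason, res2$table$reason)
  # survivors keep input order
  expect_identical(res$kept$id, lib$id[lib$id %in% res$kept$id])
})

test_that("filter decisions are invariant to input record order", {
  lib <- make_ligand_library(60, seed = 13,
                             violations = c(mw_low = 5, pains = 3,
                                            too_many_rotatable = 4))
  res1 <- filter_library(lib[, c("id", "smiles")])
  shuffled <- lib[rev(seq_len(nrow(lib))), ]
  res2 <- filter_library(shuffled[, c("id", "smiles")])
  r1 <- res1$table[order(res1$table$id), c("id", "reason")]
  r2 <- res2$table[order(res2$table$id), c("id", "reason")]
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("empty input yields an empty result with zero counts", {
  res <- filter_library(tibble::tibble(id = character(),
                                       smiles = character()))
  expect_equal(res$report$n_input, 0)
  expect_equal(res$report$n_surviving, 0)
  expect_equal(nrow(res$kept), 0)
})

test_that("SDF input round-trips through the standardizer", {
  smi <- c("CCO", "c1ccccc1Cl")
  sdf <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(paste(smi, c("a", "b"), sep = "\t"), "\n",
                         collapse = ""))
  path <- tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  tab <- read_sdf(path)
  expect_equal(nrow(tab), 2)
  std <- standardize_molecules(tab)
  expect_equal(std$smiles, standardize_molecules(smi)$smiles)
})
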