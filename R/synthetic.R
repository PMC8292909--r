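# Seeded generators that emulate every input the pipeline consumes: toy
# pocket structures, chain ligands, fragment-grammar SMILES libraries with
# planted filter violations, contact-count affinity oracles, and TMT
# intensity matrices with planted effects.

#' Synthetic pocket structure
#'
#' Builds a hollow cubic shell of pseudo-atoms with one internal cavity and
#' (optionally) a capped mouth channel, on a lattice aligned with voxel
#' centers. With the default flood-fill parameters (1 A spacing, strict
#' 2 A occupancy) the cavity voxel count has the closed form
#' `(shell_edge - 4)^3 (+ 2 mouth-channel voxels)`. Atom jitter is applied
#' tangentially to each face (the mouth surround and cap stay exact), so
#' seeds change coordinates but never the cavity topology.
#'
#' @param seed Integer RNG seed (controls jitter only).
#' @param shell_edge Atoms per shell edge (default 11; must be >= 4).
#' @param mouth Carve a capped mouth channel? Default `TRUE`.
#' @param jitter Maximum tangential displacement in Angstrom (default 0.25,
#'   clamped below 0.5).
#' @param cavity_edge Optional consistency check: expected cavity edge;
#'   errors if it exceeds `shell_edge - 4`.
#' @return A structure tibble with attribute `pocket_spec` (list with
#'   `shell_edge`, `mouth`, `cavity_center`, `cavity_voxels`).
#' @export
make_pocket <- function(seed = 1, shell_edge = 11, mouth = TRUE,
                        jitter = 0.25, cavity_edge = NULL) {
  L <- as.integer(shell_edge)
  stopifnot(L >= 4, jitter >= 0, jitter < 0.5)
  if (!is.null(cavity_edge) && cavity_edge > L - 4) {
    abort("cavity larger than shell")
  }
  if (mouth && (L < 9 || L %% 2 == 0)) {
    abort("mouth requires an odd shell_edge >= 9")
  }
  ax <- 0:(L - 1)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  on_face <- g[, 1] %in% c(0, L - 1) | g[, 2] %in% c(0, L - 1) |
    g[, 3] %in% c(0, L - 1)
  g <- g[on_face, , drop = FALSE]
  c0 <- (L - 1) %/% 2
  protected <- rep(FALSE, nrow(g))
  if (mouth) {
    in_mouth <- g[, 3] == L - 1 & pmax(abs(g[, 1] - c0), abs(g[, 2] - c0)) <= 1
    g <- g[!in_mouth, , drop = FALSE]
    protected <- g[, 3] == L - 1 &
      pmax(abs(g[, 1] - c0), abs(g[, 2] - c0)) <= 3
    cap <- as.matrix(expand.grid(x = c0 + (-2:2), y = c0 + (-2:2),
                                 z = L + 1))
    g <- rbind(g, cap)
    protected <- c(protected, rep(TRUE, nrow(cap)))
  }
  # tangential jitter: move each atom only within the plane of its face
  coords <- g + 0.5                       # atoms sit at voxel centers
  with_seed(as.integer(seed), {
    for (i in seq_len(nrow(coords))) {
      if (protected[i]) next
      normal_axis <- if (g[i, 1] %in% c(0, L - 1)) 1
      else if (g[i, 2] %in% c(0, L - 1)) 2 else 3
      tang <- setdiff(1:3, normal_axis)
      coords[i, tang] <- coords[i, tang] + runif(2, -jitter, jitter)
    }
  })
  st <- structure_table(element = rep("C", nrow(coords)),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        resno = seq_len(nrow(coords)), chain = "A")
  cavity_center <- rep(c0 + 0.5, 3)
  n_cavity <- max(L - 4, 0)^3 + if (mouth) 2L else 0L
  attr(st, "pocket_spec") <- list(shell_edge = L, mouth = mouth,
                                  cavity_center = cavity_center,
                                  cavity_voxels = n_cavity)
  st
}

#' Synthetic chain ligand conformer
#'
#' A self-avoiding random-walk chain of heavy atoms (C/N/O) with fixed bond
#' length; a stand-in 3D conformer for pose-generation and scoring tests.
#'
#' @param n_atoms Number of heavy atoms.
#' @param seed Integer RNG seed.
#' @param bond_length Step length in Angstrom (default 1.5).
#' @param min_sep Minimum non-bonded separation (default 1.2).
#' @return Atom tibble `(element, x, y, z)` centered at its centroid.
#' @export
make_chain_ligand <- function(n_atoms, seed = 1, bond_length = 1.5,
                              min_sep = 1.2) {
  stopifnot(n_atoms >= 1)
  xyz <- matrix(0, n_atoms, 3)
  el <- character(n_atoms)
  with_seed(as.integer(seed), {
    el <- sample(c("C", "N", "O"), n_atoms, replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))
    for (i in seq_len(n_atoms)[-1]) {
      repeat {
        dir <- rnorm(3)
        cand <- xyz[i - 1, ] + bond_length * dir / sqrt(sum(dir^2))
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(cross_dist2(matrix(cand, 1), prev)) >= min_sep^2) {
          xyz[i, ] <- cand
          break
        }
      }
    }
  })
  xyz <- sweep(xyz, 2, colMeans(xyz))
  tibble(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Contact-count affinity oracle
#'
#' @param a0 Baseline pK (default 4).
#' @param a1 Gain per protein-contacting ligand atom (default 0.3 pK; with
#'   ligands of 4-14 heavy atoms this spreads labels over roughly 1-3 pK,
#'   large against the 0.2 pK measurement noise, as in real affinity sets
#'   that span several log units).
#' @param a2 Penalty per clashing atom pair (default 0.5 pK).
#' @param contact_cutoff Contact distance in Angstrom (default 4).
#' @param clash_cutoff Clash distance in Angstrom (default 2.2).
#' @param noise_sd Gaussian label noise, pK units (default 0.2).
#' @return An `oracle_params` list.
#' @export
oracle_params <- function(a0 = 4, a1 = 0.3, a2 = 0.5, contact_cutoff = 4,
                          clash_cutoff = 2.2, noise_sd = 0.2) {
  stopifnot(a1 > 0, a2 >= 0, noise_sd >= 0)
  structure(list(a0 = a0, a1 = a1, a2 = a2,
                 contact_cutoff = contact_cutoff,
                 clash_cutoff = clash_cutoff, noise_sd = noise_sd),
            class = "oracle_params")
}

#' Oracle affinity label for a placed pose
#'
#' `label = a0 + a1 * n_contacts - a2 * n_clash_pairs + noise`, where a
#' contact is a ligand heavy atom within `contact_cutoff` of any pocket
#' heavy atom and a clash pair is any protein-ligand pair closer than
#' `clash_cutoff`. Noise (if any) is drawn from the current RNG stream;
#' with `noise_sd = 0` the label is a deterministic function of geometry.
#'
#' @param pocket Structure tibble (pocket atoms).
#' @param pose Ligand atoms tibble for one placed pose.
#' @param params An [oracle_params()].
#' @return Scalar pK-scale label.
#' @export
oracle_affinity <- function(pocket, pose, params = oracle_params()) {
  p_xyz <- heavy_coords(pocket)
  l_xyz <- as.matrix(pose[pose$element != "H", c("x", "y", "z")])
  d2 <- cross_dist2(l_xyz, p_xyz)
  contacts <- sum(apply(d2, 1, min) <= params$contact_cutoff^2)
  clashes <- sum(d2 < params$clash_cutoff^2)
  noise <- if (params$noise_sd > 0) rnorm(1, 0, params$noise_sd) else 0
  params$a0 + params$a1 * contacts - params$a2 * clashes + noise
}

#' Synthetic SMILES library with planted filter violations
#'
#' Assembles drug-like molecules from a small fragment grammar (all grammar
#' products pass every filter by construction) and plants exact numbers of
#' single-rule violators, plus benign salt/isotope forms that exercise
#' standardization but survive. The returned truth table is exact.
#'
#' @param n Library size.
#' @param seed Integer RNG seed.
#' @param violations Named integer vector of planted violator counts; names
#'   from `mw_low`, `mw_high`, `too_many_atoms`, `too_many_rotatable`,
#'   `too_many_chiral`, `element_not_allowed`, `pains`, `parse_error`.
#' @param n_salt,n_isotope Benign salt/isotope forms among the survivors.
#' @return Tibble `(id, smiles, category, expect_pass, expect_reason)`;
#'   feed `id`/`smiles` to [filter_library()] and compare against the rest.
#' @examples
#' lib <- make_ligand_library(20, seed = 1,
#'                            violations = c(mw_low = 3, pains = 2))
#' table(lib$expect_pass)
#' @export
make_ligand_library <- function(n = 100, seed = 1,
                                violations = c(mw_low = 7, mw_high = 6,
                                               too_many_atoms = 6,
                                               too_many_rotatable = 6,
                                               too_many_chiral = 6,
                                               element_not_allowed = 5,
                                               pains = 4),
                                n_salt = 6, n_isotope = 4) {
  stopifnot(n >= 1, all(violations >= 0))
  pools <- violation_pools()
  stopifnot(all(names(violations) %in% names(pools)))
  n_viol <- sum(violations)
  if (n_viol + n_salt + n_isotope > n) {
    abort("infeasible inventory: planted counts exceed library size")
  }
  rows <- list()
  with_seed(as.integer(seed), {
    for (cat in names(violations)) {
      k <- violations[[cat]]
      if (k == 0) next
      pool <- pools[[cat]]
      rows[[cat]] <- tibble(
        smiles = pool$smiles[((seq_len(k) - 1) %% nrow(pool)) + 1],
        category = cat, expect_pass = FALSE,
        expect_reason = pool$reason[((seq_len(k) - 1) %% nrow(pool)) + 1]
      )
    }
    n_clean <- n - n_viol
    clean <- vapply(seq_len(n_clean), function(i) grammar_molecule(),
                    character(1))
    cat_clean <- rep("clean", n_clean)
    if (n_salt > 0) {
      clean[seq_len(n_salt)] <- paste0(clean[seq_len(n_salt)], ".Cl")
      cat_clean[seq_len(n_salt)] <- "salt_form"
    }
    if (n_isotope > 0) {
      j <- n_salt + seq_len(n_isotope)
      clean[j] <- vapply(seq_along(j), function(k) grammar_molecule(TRUE),
                         character(1))
      clean[j] <- sub("c1cc", "[13cH]1cc", clean[j], fixed = TRUE)
      cat_clean[j] <- "isotope_form"
    }
    rows$clean <- tibble(smiles = clean, category = cat_clean,
                         expect_pass = TRUE, expect_reason = "pass")
    lib <- bind_rows(rows)
    lib <- lib[sample(nrow(lib)), , drop = FALSE]
  })
  lib$id <- sprintf("lib_%03d", seq_len(nrow(lib)))
  lib[, c("id", "smiles", "category", "expect_pass", "expect_reason")]
}

# One clean molecule from the fragment grammar. Every product is provably
# inside all property bounds and free of shipped substructure alerts.
grammar_molecule <- function(aromatic_only = FALSE) {
  scaffolds <- c("c1ccc(%s)cc1", "c1cc(%s)ncc1", "C1CCN(%s)CC1",
                 "O1CCN(%s)CC1")
  if (aromatic_only) scaffolds <- scaffolds[1:2]
  subst <- c("Cl", "OC", "C#N", "N(C)C", "C(=O)NC", "OCC", "S(=O)(=O)C",
             "C(F)(F)F", "C(=O)OC", "CCOC")
  ring2 <- c("c2ccccc2", "C2CCCCC2", "c2ccncc2", "C2CCN(C)CC2")
  sc <- sample(scaffolds, 1)
  if (runif(1) < 0.4) {
    sprintf(sc, paste0("C(=O)N", sample(ring2, 1)))
  } else {
    sprintf(sc, sample(subst, 1))
  }
}

# Fixed pools of single-rule violators. Each SMILES violates exactly the
# named rule and nothing else (verified in the test suite).
violation_pools <- function() {
  list(
    mw_low = tibble(
      smiles = c("CCO", "CCN", "CC(=O)C", "C1CC1", "CCOC", "CC(C)O",
                 "CCCO", "CCC(=O)C"),
      reason = "mw_below_min"
    ),
    mw_high = tibble(
      smiles = c("Brc1c(Br)c(Br)c2c(Br)c(Br)c(Br)c(Br)c2c1Br",
                 "Ic1c(I)c(I)c(I)c(I)c1I"),
      reason = "mw_above_max"
    ),
    too_many_atoms = tibble(
      smiles = c(
        "CC1(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C1(C)C",
        "CC1(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C(C)(C)C1(C)C"
      ),
      reason = "too_many_atoms"
    ),
    too_many_rotatable = tibble(
      smiles = c("COCCOCCOCCOCCOCCOCCOC", "CCCCCCCCCCCCCCCCCCC"),
      reason = "too_many_rotatable"
    ),
    too_many_chiral = tibble(
      smiles = c("CC(O)C(O)C(O)C(O)C(O)C(O)C(O)CO",
                 "CC(O)C(O)C(O)C(O)C(O)C(O)C(O)C(O)CO"),
      reason = "too_many_chiral"
    ),
    element_not_allowed = tibble(
      smiles = c("C[Si](C)(C)c1ccccc1", "C[Si](C)(C)OC(C)(C)C"),
      reason = "element_not_allowed"
    ),
    pains = tibble(
      smiles = c("O=C1NC(=S)SC1=Cc1ccccc1", "O=C1C=CC(=O)C=C1"),
      reason = "substructure"
    ),
    parse_error = tibble(
      smiles = c("C1CC(", "not_a_smiles(("),
      reason = "parse_error"
    )
  )
}

#' Synthetic screening dataset with oracle labels
#'
#' Generates pockets, chain ligands, clash-free pose ensembles, voxel grids
#' and contact-count oracle labels, split train/test by compound (no pose
#' leakage). The per-complex label is the Boltzmann aggregate (at
#' `label_beta`) of the per-pose oracle values plus Gaussian noise.
#'
#' @param n_complexes Number of complexes (default 500).
#' @param seed Integer RNG seed.
#' @param n_poses Poses per complex (default 64; desk-scale recovery
#'   experiments use 8).
#' @param spec Grid spec (default: 16-voxel, 2-channel protein/ligand
#'   occupancy grids).
#' @param params An [oracle_params()].
#' @param label_beta Inverse temperature for the label aggregation
#'   (default 1, matching the default scoring aggregation).
#' @param train_frac Fraction of complexes in the training split.
#' @return List: `grids` (matrix, one pose per column), `complex_of_grid`,
#'   `labels` (named by complex), `split` (`train`/`test` id vectors),
#'   `truth` tibble, `spec`, `params`.
#' @export
make_screen_dataset <- function(n_complexes = 500, seed = 1, n_poses = 64,
                                spec = grid_spec(edge = 16L,
                                                 channels = channel_scheme_minimal()),
                                params = oracle_params(), label_beta = 1,
                                train_frac = 0.8) {
  stopifnot(n_complexes >= 10)
  ids <- sprintf("cplx_%04d", seq_len(n_complexes))
  len <- spec$n_channels * spec$edge^3
  grids <- matrix(0, len, n_complexes * n_poses)
  labels <- numeric(n_complexes)
  mean_contacts <- numeric(n_complexes)
  # shells are sized so the whole complex (cap included) fits the grid:
  # the network must be able to see every atom the oracle counts
  shell_choices <- c(9L, 11L)
  max_span <- max(shell_choices) / 2 + 1.5   # cap plate is the farthest atom
  stopifnot(max_span <= spec$edge * spec$spacing / 2)
  with_seed(as.integer(seed), {
    for (i in seq_len(n_complexes)) {
      sub <- sub_seed(seed, ids[i]) %% 2000000000L
      shell <- shell_choices[1 + (sub %% length(shell_choices))]
      pocket <- make_pocket(seed = sub, shell_edge = shell, mouth = TRUE)
      ps <- attr(pocket, "pocket_spec")
      site <- flood_fill_site(pocket, ps$cavity_center,
                              max_radius = shell / 2 + 2)
      n_at <- 4 + (sub %% min(11L, shell - 4L))
      # shrink the chain until the cavity can host a clash-free ensemble
      repeat {
        lig <- make_chain_ligand(n_at, seed = sub + 1L)
        ens <- tryCatch(
          generate_poses(site, lig, n = n_poses, seed = sub + 2L,
                         max_attempts_per_pose = 2000),
          pocket_too_small = function(e) NULL
        )
        if (!is.null(ens) || n_at <= 4) break
        n_at <- n_at - 2L
      }
      if (is.null(ens)) {
        ens <- generate_poses(site, lig, n = n_poses, seed = sub + 2L)
      }
      pose_scores <- numeric(n_poses)
      for (p in seq_len(n_poses)) {
        pc <- pose_coords(ens, p)
        pose_scores[p] <- oracle_affinity(
          pocket, pc,
          oracle_params(a0 = params$a0, a1 = params$a1, a2 = params$a2,
                        contact_cutoff = params$contact_cutoff,
                        clash_cutoff = params$clash_cutoff, noise_sd = 0))
        fr <- complex_frame(pocket, pc, site$center)
        grids[, (i - 1) * n_poses + p] <- as.numeric(rasterize(fr, spec))
      }
      mean_contacts[i] <- (mean(pose_scores) - params$a0) / params$a1
      labels[i] <- boltzmann_aggregate(pose_scores, label_beta) +
        if (params$noise_sd > 0) rnorm(1, 0, params$noise_sd) else 0
    }
    n_train <- round(train_frac * n_complexes)
    train_ids <- sample(ids, n_train)
  })
  list(
    grids = grids,
    complex_of_grid = rep(ids, each = n_poses),
    labels = stats::setNames(labels, ids),
    split = list(train = sort(train_ids), test = sort(setdiff(ids, train_ids))),
    truth = tibble(complex = ids, label = labels,
                   mean_contacts = mean_contacts),
    spec = spec, params = params
  )
}

#' Synthetic TMT intensity matrix with planted effects
#'
#' Log-normal reporter intensities for a 10-plex design (3 control
#' channels, 3 depletion channels, plus unassigned channels that share the
#' run), channel-level loading factors, and a chosen number of proteins
#' with a planted log2 effect in the depletion (+Tet) group.
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param n_planted Planted-effect proteins (default 50).
#' @param planted_lfc Planted log2 fold change, `+Tet` over `-Tet`
#'   (default -1: abundance halves upon depletion).
#' @param sd_log2 Within-group replicate standard deviation on the log2
#'   scale (default 0.1).
#' @param n_ref,n_test Replicates per group (default 3 and 3).
#' @param n_extra Additional unassigned channels to fill the 10-plex
#'   (default 4).
#' @param loading Channel loading factors (recycled); default draws
#'   log-normal factors with 25% spread.
#' @param baseline_mean,baseline_sd Log2-scale protein baseline parameters.
#' @param seed Integer RNG seed.
#' @return List: `intensities` tibble, `design` (see [channel_design()]),
#'   `truth` tibble `(protein, planted, lfc)`.
#' @export
make_tmt_fixture <- function(n_proteins = 1000, n_planted = 50,
                             planted_lfc = -1, sd_log2 = 0.1,
                             n_ref = 3, n_test = 3, n_extra = 4,
                             loading = NULL, baseline_mean = 20,
                             baseline_sd = 2, seed = 1) {
  stopifnot(n_planted <= n_proteins, n_ref >= 2, n_test >= 2)
  n_chan <- n_ref + n_test + n_extra
  chans <- sprintf("tmt_%02d", seq_len(n_chan))
  groups <- c(rep("minus_tet", n_ref), rep("plus_tet", n_test),
              rep("unused", n_extra))
  proteins <- sprintf("PROT%04d", seq_len(n_proteins))
  with_seed(as.integer(seed), {
    if (is.null(loading)) loading <- exp(rnorm(n_chan, 0, 0.25))
    loading <- rep_len(loading, n_chan)
    planted <- sample(proteins, n_planted)
    base <- rnorm(n_proteins, baseline_mean, baseline_sd)
    m <- matrix(0, n_proteins, n_chan)
    for (j in seq_len(n_chan)) {
      eff <- ifelse(groups[j] == "plus_tet" & proteins %in% planted,
                    planted_lfc, 0)
      m[, j] <- 2^(base + eff + rnorm(n_proteins, 0, sd_log2)) * loading[j]
    }
  })
  intensities <- bind_cols(tibble(protein = proteins),
                           as_tibble(stats::setNames(as.data.frame(m), chans)))
  list(
    intensities = intensities,
    design = channel_design(chans, groups),
    truth = tibble(protein = proteins,
                   planted = proteins %in% planted,
                   lfc = ifelse(proteins %in% planted, planted_lfc, 0)),
    loading = loading
  )
}
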