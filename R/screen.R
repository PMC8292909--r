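#' Circular substructure fingerprints
#'
#' A deterministic ECFP-style fingerprint: atom environments are iteratively
#' hashed out to `radius` bonds (initial invariants: element, heavy degree,
#' implicit hydrogens, charge, ring membership) and all identifiers are
#' folded into a fixed-length bit vector.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @param radius Environment radius in bonds (default 2).
#' @param nbits Folded length (default 2048).
#' @return A logical matrix, one row per molecule.
#' @export
circular_fingerprint <- function(smiles, radius = 2, nbits = 2048) {
  tabs <- parse_mols(smiles)
  out <- matrix(FALSE, length(smiles), nbits)
  for (i in seq_along(tabs)) {
    tab <- tabs[[i]]
    n <- nrow(tab$atoms)
    ring_atom <- rep(FALSE, n)
    if (nrow(tab$bonds) > 0) {
      ra <- unique(c(tab$bonds$a1[tab$bonds$ring],
                     tab$bonds$a2[tab$bonds$ring]))
      ring_atom[ra] <- TRUE
    }
    ids <- vapply(seq_len(n), function(a) {
      hash_ints(c(utf8ToInt(tab$atoms$element[a]),
                  tab$atoms$degree[a], tab$atoms$implh[a],
                  tab$atoms$charge[a] + 10, as.integer(ring_atom[a])))
    }, numeric(1))
    all_ids <- ids
    nbrs <- vector("list", n)
    orders <- vector("list", n)
    for (k in seq_len(nrow(tab$bonds))) {
      a1 <- tab$bonds$a1[k]; a2 <- tab$bonds$a2[k]; o <- tab$bonds$order[k]
      nbrs[[a1]] <- c(nbrs[[a1]], a2); orders[[a1]] <- c(orders[[a1]], o)
      nbrs[[a2]] <- c(nbrs[[a2]], a1); orders[[a2]] <- c(orders[[a2]], o)
    }
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(n), function(a) {
        if (length(nbrs[[a]]) == 0) return(hash_ints(c(r, ids[a])))
        env <- sort(orders[[a]] * 4294967296 + ids[nbrs[[a]]])
        hash_ints(c(r, ids[a], env %% 4294967296, env %/% 4294967296))
      }, numeric(1))
      all_ids <- c(all_ids, ids)
    }
    out[i, (all_ids %% nbits) + 1] <- TRUE
  }
  rownames(out) <- names(smiles)
  out
}

#' Tanimoto distance matrix between fingerprint rows
#'
#' @param fp Logical fingerprint matrix (rows = molecules).
#' @return Symmetric matrix of `1 - Tanimoto similarity`.
#' @export
tanimoto_distance <- function(fp) {
  fp <- fp * 1
  inter <- tcrossprod(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  1 - sim
}

#' Score a compound library against a site
#'
#' For each compound: generate the pose ensemble inside the site, rasterize
#' each pose with the model's grid spec, score the poses and Boltzmann-
#' aggregate. Per-compound randomness derives from `seed` and the compound
#' id (not its position), so the ranking is invariant to library order.
#' Compounds without a usable conformer are skipped with a message.
#'
#' @param model A trained `scoring_model`.
#' @param library Tibble with `id` and a `conformer` list-column of atom
#'   tibbles (`element`, `x`, `y`, `z`). See [make_chain_ligand()] or your
#'   own 3D embedding upstream.
#' @param site A `pocket_site`.
#' @param n_poses Ensemble size per compound (default 64).
#' @param seed Base seed.
#' @return A `ranked_table` tibble `(id, score, rank)`, sorted by descending
#'   score; ties broken lexicographically by id. Higher score = better
#'   (pKi/pIC50 scale).
#' @export
score_library <- function(model, library, site, n_poses = 64, seed = 1) {
  stopifnot(all(c("id", "conformer") %in% names(library)))
  rows <- purrr::map(seq_len(nrow(library)), function(i) {
    lig <- library$conformer[[i]]
    id <- library$id[i]
    if (is.null(lig) || nrow(lig) == 0) {
      message("skipping compound without conformer: ", id)
      return(NULL)
    }
    ens <- tryCatch(
      generate_poses(site, lig, n = n_poses, seed = sub_seed(seed, id)),
      pocket_too_small = function(e) NULL
    )
    if (is.null(ens)) {
      message("skipping compound that cannot be posed: ", id)
      return(NULL)
    }
    grids <- lapply(seq_len(n_poses), function(p) {
      fr <- complex_frame(site$structure, pose_coords(ens, p), site$center)
      rasterize(fr, model$spec)
    })
    tibble(id = id, score = predict_affinity(model, grids)$score)
  })
  tab <- bind_rows(rows)
  ranked_table(tab)
}

#' Assemble a ranked table
#'
#' @param tab Tibble with `id` and `score`.
#' @return The table sorted by descending score (ties by id) with a `rank`
#'   column `1..n`.
#' @export
ranked_table <- function(tab) {
  out <- arrange(tab, desc(.data$score), .data$id)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("ranked_table", class(out))
  out
}

#' Keep the top-k ranked compounds
#'
#' @param table A `ranked_table`.
#' @param k How many rows to keep (default 5000, the examination window used
#'   before diverse selection).
#' @return The first `min(k, n)` rows, order preserved.
#' @export
top_k <- function(table, k = 5000) {
  stopifnot(k >= 0)
  dplyr::slice_head(table, n = min(k, nrow(table)))
}

#' Greedy MaxMin diverse subset selection
#'
#' Picks `k` structurally diverse compounds from ranked candidates: start at
#' the top-ranked compound, then repeatedly add the candidate whose minimum
#' Tanimoto distance to the already-selected set is largest (ties broken by
#' id). Stands in for the scaffold-diversity triage applied to a top-5000
#' window (default `k = 89`).
#'
#' @param candidates A `ranked_table` (or tibble with `id`), plus either a
#'   `smiles` column or a precomputed fingerprint matrix via `fp`.
#' @param k Number of picks (default 89).
#' @param fp Optional fingerprint matrix aligned with `candidates` rows.
#' @param radius,nbits Fingerprint parameters when computed from `smiles`.
#' @return Character vector of selected ids, in pick order.
#' @export
pick_diverse <- function(candidates, k = 89, fp = NULL, radius = 2,
                         nbits = 2048) {
  stopifnot(nrow(candidates) >= 1)
  if (is.null(fp)) {
    stopifnot("smiles" %in% names(candidates))
    fp <- circular_fingerprint(candidates$smiles, radius, nbits)
  }
  ids <- candidates$id
  k <- min(k, length(ids))
  d <- tanimoto_distance(fp)
  sel <- 1L                              # top-ranked candidate
  min_d <- d[, 1]
  while (length(sel) < k) {
    min_d[sel] <- -Inf
    best <- max(min_d)
    cand <- which(min_d == best)
    nxt <- cand[order(ids[cand])][1]
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  ids[sel]
}
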