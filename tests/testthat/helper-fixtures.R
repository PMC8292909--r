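# Shared fixtures and independent oracles used across the suite.

# --- independent flood-fill oracle -----------------------------------------
# Brute force: full occupancy over the lattice, then repeated neighbour
# sweeps until the reachable set stops growing. Shares no code with the
# package BFS.
oracle_flood <- function(atoms_xyz, seed_xyz, spacing = 1, r_occ = 2,
                         max_radius = 12) {
  v0 <- floor(seed_xyz / spacing)
  v0c <- (v0 + 0.5) * spacing
  R <- floor(max_radius / spacing)
  ax <- -R:R
  vox <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  centers <- sweep(vox * spacing, 2, v0c, "+")
  occupied <- rep(FALSE, nrow(vox))
  if (nrow(atoms_xyz) > 0) {
    for (chunk in split(seq_len(nrow(vox)),
                        ceiling(seq_len(nrow(vox)) / 4000))) {
      d2 <- outer(rowSums(centers[chunk, , drop = FALSE]^2),
                  rowSums(atoms_xyz^2), "+") -
        2 * tcrossprod(centers[chunk, , drop = FALSE], atoms_xyz)
      occupied[chunk] <- apply(d2, 1, min) < r_occ^2
    }
  }
  inside <- rowSums(vox^2) * spacing^2 <= max_radius^2 + 1e-9
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  reach <- !occupied & inside & vox[, 1] == 0 & vox[, 2] == 0 & vox[, 3] == 0
  if (!any(reach)) return(NULL)   # buried seed
  repeat {
    grew <- FALSE
    idx <- which(reach)
    nb <- do.call(rbind, lapply(seq_len(3), function(ax_i) {
      rbind(
        {
          v <- vox[idx, , drop = FALSE]; v[, ax_i] <- v[, ax_i] + 1L; v
        },
        {
          v <- vox[idx, , drop = FALSE]; v[, ax_i] <- v[, ax_i] - 1L; v
        }
      )
    }))
    hit <- match(paste(nb[, 1], nb[, 2], nb[, 3]), key)
    hit <- hit[!is.na(hit)]
    new <- hit[!reach[hit] & !occupied[hit] & inside[hit]]
    if (length(new) > 0) {
      reach[new] <- TRUE
      grew <- TRUE
    }
    if (!grew) break
  }
  vox[reach, , drop = FALSE]
}

sort_voxels <- function(v) {
  v <- as.matrix(v)
  dimnames(v) <- NULL
  v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
}

# --- independent rotatable-bond oracle -------------------------------------
# Naive enumeration: ring test by path search avoiding the bond itself.
oracle_rotatable <- function(tab) {
  b <- tab$bonds
  if (nrow(b) == 0) return(0L)
  n <- nrow(tab$atoms)
  adj <- lapply(seq_len(n), function(a) {
    c(b$a2[b$a1 == a], b$a1[b$a2 == a])
  })
  connected_avoiding <- function(from, to, skip1, skip2) {
    seen <- rep(FALSE, n)
    stack <- from
    seen[from] <- TRUE
    while (length(stack) > 0) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (nb in adj[[a]]) {
        if ((a == skip1 && nb == skip2) || (a == skip2 && nb == skip1)) next
        if (!seen[nb]) {
          if (nb == to) return(TRUE)
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    FALSE
  }
  el <- tab$atoms$element
  carbonyl_c <- unique(unlist(lapply(seq_len(nrow(b)), function(k) {
    if (b$order[k] != 2) return(NULL)
    if (el[b$a1[k]] == "C" && el[b$a2[k]] == "O") return(b$a1[k])
    if (el[b$a2[k]] == "C" && el[b$a1[k]] == "O") return(b$a2[k])
    NULL
  })))
  count <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1) next
    a1 <- b$a1[k]; a2 <- b$a2[k]
    if (length(adj[[a1]]) < 2 || length(adj[[a2]]) < 2) next
    if (connected_avoiding(a1, a2, a1, a2)) next   # ring bond
    amide <- (el[a1] == "C" && a1 %in% carbonyl_c && el[a2] == "N") ||
      (el[a2] == "C" && a2 %in% carbonyl_c && el[a1] == "N")
    if (amide) next
    count <- count + 1L
  }
  count
}

# --- independent degron oracle ---------------------------------------------
# Regex with lookahead (to catch overlaps), built from the motif classes.
oracle_degron_starts <- function(seq, motif) {
  classes <- vapply(motif, function(cl) paste0("[", paste(cl, collapse = ""),
                                               "]"), character(1))
  rx <- paste0("(?=", paste(classes, collapse = ""), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# --- generic-position complex frames ---------------------------------------
# Random frame whose atoms are pairwise > 1.8 A apart and inside a ball of
# radius `rmax`, so each atom occupies its own voxel under any rigid motion.
random_generic_frame <- function(n_atoms, seed, rmax = 10) {
  withr::with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n_atoms) {
      cand <- runif(3, -rmax, rmax)
      if (sum(cand^2) > rmax^2) next
      if (nrow(pts) == 0 ||
          min(colSums((t(pts) - cand)^2)) > 1.8^2) {
        pts <- rbind(pts, cand)
      }
    }
    entity <- sample(c("protein", "ligand"), n_atoms, replace = TRUE)
    element <- sample(c("C", "N", "O", "S", "Cl"), n_atoms, replace = TRUE)
  })
  fr <- tibble::tibble(entity = entity, element = element,
                       x = pts[, 1], y = pts[, 2], z = pts[, 3])
  attr(fr, "centered") <- TRUE
  class(fr) <- c("complex_frame", class(fr))
  fr
}

# Small cached pocket + site + ligand for pose/scoring tests.
tiny_site <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pocket <- make_pocket(seed = 42, shell_edge = 11)
      ps <- attr(pocket, "pocket_spec")
      cache <<- list(
        pocket = pocket,
        site = flood_fill_site(pocket, ps$cavity_center, max_radius = 8),
        spec = ps
      )
    }
    cache
  }
})
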