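#' Define a binding site by flood fill from a seed point
#'
#' Grows a pocket region from a seed through unoccupied voxels of a regular
#' lattice. The lattice is absolute: cell `i` spans
#' `[i*spacing, (i+1)*spacing)` per axis, so any seed point inside the same
#' cell yields the identical voxel set. A voxel is *occupied* when a heavy
#' atom lies strictly closer than `r_occ` to its center. Growth proceeds in
#' 6-connected steps and is truncated at Euclidean distance `max_radius`
#' (voxel center to seed-voxel center).
#'
#' @param structure Structure tibble (see [structure_table()]).
#' @param seed_xyz Numeric length-3 seed point (Angstrom).
#' @param spacing Lattice spacing in Angstrom (default 1).
#' @param r_occ Occupancy radius in Angstrom (default 2): voxels with a heavy
#'   atom closer than this are walls.
#' @param max_radius Truncation radius in Angstrom (default 12).
#' @param d_site Residue-annotation distance (default 4.5): residues with an
#'   atom within `d_site` of a flooded voxel center are listed as site
#'   residues.
#' @return A `pocket_site`: flooded voxels (integer offsets relative to the
#'   seed voxel), the seed voxel, absolute voxel centers, the site center
#'   (centroid of voxel centers), site residues, and the structure itself.
#' @examples
#' pocket <- make_pocket(seed = 1)
#' site <- flood_fill_site(pocket, attr(pocket, "pocket_spec")$cavity_center)
#' site
#' @export
flood_fill_site <- function(structure, seed_xyz, spacing = 1, r_occ = 2,
                            max_radius = 12, d_site = 4.5) {
  stopifnot(length(seed_xyz) == 3, all(is.finite(seed_xyz)), spacing > 0)
  if (nrow(structure) == 0) abort("empty structure")
  coords <- heavy_coords(structure)
  v0 <- floor(seed_xyz / spacing)                # seed voxel (absolute index)
  v0_center <- (v0 + 0.5) * spacing
  R <- as.integer(floor(max_radius / spacing))
  nside <- 2L * R + 1L
  occ <- occupancy_grid(coords, v0_center, spacing, R, r_occ)
  center_lin <- linear_index(rep(R + 1L, 3), nside)
  if (occ[center_lin]) abort("seed_buried", class = "seed_buried")

  inside <- ball_mask(R, spacing, max_radius, nside)
  visited <- logical(nside^3)
  visited[center_lin] <- TRUE
  frontier <- center_lin
  strides <- c(1L, nside, nside * nside)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    gi <- arrayInd(frontier, rep(nside, 3))
    for (ax in 1:3) {
      for (s in c(-1L, 1L)) {
        movable <- if (s < 0) gi[, ax] > 1L else gi[, ax] < nside
        cand <- frontier[movable] + s * strides[ax]
        cand <- cand[!visited[cand] & !occ[cand] & inside[cand]]
        if (length(cand)) {
          visited[cand] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
    }
    frontier <- unique(nxt)
  }
  lin <- which(visited)
  offs <- arrayInd(lin, rep(nside, 3)) - (R + 1L)   # offsets from seed voxel
  centers <- sweep(offs * spacing, 2, v0_center, "+")
  residues <- site_residues(structure, centers, d_site)
  new_pocket_site(
    voxels = offs, seed_voxel = v0, spacing = spacing,
    centers = centers, residues = residues, structure = structure,
    params = list(r_occ = r_occ, max_radius = max_radius, d_site = d_site)
  )
}

# Occupancy over the (2R+1)^3 lattice centered on the seed voxel center.
# Strict inequality: occupied iff dist(atom, voxel center) < r_occ.
occupancy_grid <- function(coords, v0_center, spacing, R, r_occ) {
  nside <- 2L * R + 1L
  occ <- logical(nside^3)
  if (nrow(coords) == 0) return(occ)
  rel <- sweep(coords, 2, v0_center)            # atom coords relative to seed voxel center
  reach <- r_occ / spacing
  keep <- abs(rel[, 1]) <= (R + reach) & abs(rel[, 2]) <= (R + reach) &
    abs(rel[, 3]) <= (R + reach)
  rel <- rel[keep, , drop = FALSE]
  for (i in seq_len(nrow(rel))) {
    a <- rel[i, ] / spacing                     # in voxel units
    lo <- pmax(ceiling(a - reach), -R)
    hi <- pmin(floor(a + reach), R)
    if (any(lo > hi)) next
    gx <- seq.int(lo[1], hi[1]); gy <- seq.int(lo[2], hi[2])
    gz <- seq.int(lo[3], hi[3])
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    d2 <- (g[, 1] - a[1])^2 + (g[, 2] - a[2])^2 + (g[, 3] - a[3])^2
    hit <- g[d2 < reach^2, , drop = FALSE]
    if (nrow(hit)) {
      occ[(hit[, 1] + R) + nside * (hit[, 2] + R) +
            nside * nside * (hit[, 3] + R) + 1L] <- TRUE
    }
  }
  occ
}

ball_mask <- function(R, spacing, max_radius, nside) {
  ax <- seq.int(-R, R)
  g <- expand.grid(x = ax, y = ax, z = ax)
  (g$x^2 + g$y^2 + g$z^2) * spacing^2 <= max_radius^2 + 1e-9
}

linear_index <- function(ijk, nside) {
  ijk[1] + nside * (ijk[2] - 1L) + nside * nside * (ijk[3] - 1L)
}

site_residues <- function(structure, centers, d_site) {
  h <- structure$element != "H"
  at <- structure[h, , drop = FALSE]
  if (nrow(at) == 0 || nrow(centers) == 0) {
    return(tibble(chain = character(), resno = integer()))
  }
  bb_lo <- apply(centers, 2, min) - d_site
  bb_hi <- apply(centers, 2, max) + d_site
  near <- at$x >= bb_lo[1] & at$x <= bb_hi[1] &
    at$y >= bb_lo[2] & at$y <= bb_hi[2] &
    at$z >= bb_lo[3] & at$z <= bb_hi[3]
  at <- at[near, , drop = FALSE]
  if (nrow(at) == 0) return(tibble(chain = character(), resno = integer()))
  d2 <- cross_dist2(as.matrix(at[, c("x", "y", "z")]), centers)
  hit <- apply(d2, 1, min) <= d_site^2 + 1e-9
  distinct(tibble(chain = at$chain[hit], resno = at$resno[hit]))
}

new_pocket_site <- function(voxels, seed_voxel, spacing, centers, residues,
                            structure, params) {
  stopifnot(nrow(voxels) >= 1)
  structure(
    list(voxels = voxels, seed_voxel = seed_voxel, spacing = spacing,
         centers = centers, center = colMeans(centers), residues = residues,
         structure = structure, params = params),
    class = "pocket_site"
  )
}

#' @export
print.pocket_site <- function(x, ...) {
  cat("<pocket_site>\n")
  cat(sprintf("  voxels:   %d (spacing %.2f A)\n", nrow(x$voxels), x$spacing))
  cat(sprintf("  center:   (%.2f, %.2f, %.2f) A\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  residues: %d\n", nrow(x$residues)))
  invisible(x)
}

#' @rdname flood_fill_site
#' @param x A `pocket_site`.
#' @param ... Unused.
#' @export
tidy.pocket_site <- function(x, ...) {
  tibble(ix = x$voxels[, 1], iy = x$voxels[, 2], iz = x$voxels[, 3],
         x = x$centers[, 1], y = x$centers[, 2], z = x$centers[, 3])
}

#' @export
glance.pocket_site <- function(x, ...) {
  tibble(n_voxels = nrow(x$voxels), spacing = x$spacing,
         center_x = x$center[1], center_y = x$center[2],
         center_z = x$center[3], n_residues = nrow(x$residues))
}

#' @export
autoplot.pocket_site <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_tile(aes(fill = .data$z), width = object$spacing,
              height = object$spacing) +
    scale_fill_viridis_c(name = "z (A)") +
    ggplot2::facet_wrap(~iz) +
    labs(x = "x (A)", y = "y (A)") +
    theme_minimal()
}

#' Define a binding site from a residue list
#'
#' Computes the centroid of the named residues' atoms, snaps to the nearest
#' unoccupied lattice voxel, and flood fills from there. This is how a site
#' is seeded from mutagenesis- or homology-derived residue lists (e.g. the
#' 25 residues lining the deubiquitinase S1 distal ubiquitin-binding pocket).
#'
#' @param structure Structure tibble.
#' @param residue_ids Character vector `"chain:resno"` (e.g. `"A:249"`) or
#'   integer residue numbers (any chain). Duplicates are ignored.
#' @inheritParams flood_fill_site
#' @param search_radius How far (Angstrom) from the centroid to search for an
#'   open seed voxel (default 8).
#' @return A `pocket_site`.
#' @export
site_from_residues <- function(structure, residue_ids, spacing = 1,
                               r_occ = 2, max_radius = 12, d_site = 4.5,
                               search_radius = 8) {
  sel <- parse_residue_ids(residue_ids)
  if (is.null(sel$chain)) {
    hit <- structure$resno %in% sel$resno
    missing <- setdiff(sel$resno, structure$resno)
  } else {
    key_struct <- paste(structure$chain, structure$resno, sep = ":")
    key_sel <- paste(sel$chain, sel$resno, sep = ":")
    hit <- key_struct %in% key_sel
    missing <- setdiff(key_sel, key_struct)
  }
  if (length(missing) > 0) {
    abort(sprintf("residues not in structure: %s",
                  paste(missing, collapse = ", ")))
  }
  centroid <- colMeans(as.matrix(structure[hit, c("x", "y", "z")]))
  seed <- nearest_open_voxel(structure, centroid, spacing, r_occ,
                             search_radius)
  flood_fill_site(structure, seed, spacing = spacing, r_occ = r_occ,
                  max_radius = max_radius, d_site = d_site)
}

parse_residue_ids <- function(residue_ids) {
  residue_ids <- unique(residue_ids)
  if (is.numeric(residue_ids)) {
    return(list(chain = NULL, resno = as.integer(residue_ids)))
  }
  if (all(str_detect(residue_ids, ":"))) {
    parts <- str_split(residue_ids, ":", n = 2)
    list(chain = vapply(parts, `[[`, character(1), 1),
         resno = as.integer(vapply(parts, `[[`, character(1), 2)))
  } else {
    list(chain = NULL, resno = as.integer(residue_ids))
  }
}

# Nearest unoccupied voxel center to a point, ties broken by lattice order.
nearest_open_voxel <- function(structure, point, spacing, r_occ,
                               search_radius) {
  coords <- heavy_coords(structure)
  R <- as.integer(ceiling(search_radius / spacing))
  v0 <- floor(point / spacing)
  ax <- seq.int(-R, R)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  centers <- sweep(g, 2, as.numeric((v0 + 0.5) * spacing), "+")
  d2seed <- rowSums(sweep(centers, 2, point)^2)
  ord <- order(d2seed, g[, 1], g[, 2], g[, 3])
  for (i in ord) {
    c_i <- centers[i, , drop = FALSE]
    if (min(cross_dist2(c_i, coords)) >= r_occ^2) {
      return(as.numeric(c_i))
    }
  }
  abort("no open voxel near the residue centroid")
}
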