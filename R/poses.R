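#' Generate a rigid-body pose ensemble inside a pocket
#'
#' Places a rigid ligand conformer repeatedly inside the flooded pocket:
#' rotations are uniform on SO(3) (Shoemake quaternions), translations put
#' the ligand centroid on a uniformly chosen flooded-voxel center, and poses
#' clashing with the protein (any heavy-atom pair closer than `clash_cutoff`)
#' are rejected. The ensemble is fully reproducible from `(inputs, seed)`.
#'
#' @param site A `pocket_site` from [flood_fill_site()].
#' @param ligand Tibble of ligand atoms with `element`, `x`, `y`, `z`
#'   (a single 3D conformer).
#' @param n Number of accepted poses (default 64, the screening ensemble
#'   size).
#' @param seed Integer RNG seed.
#' @param clash_cutoff Minimum allowed protein-ligand heavy-atom distance in
#'   Angstrom (default 2.2).
#' @param max_attempts_per_pose Rejection-sampling budget; fewer than one
#'   acceptance per 10,000 attempts aborts with `"pocket_too_small"`.
#' @return A `pose_ensemble`: the centered ligand, a tibble of poses with
#'   rotation/translation list-columns, and provenance.
#' @examples
#' pocket <- make_pocket(seed = 1)
#' site <- flood_fill_site(pocket, attr(pocket, "pocket_spec")$cavity_center)
#' lig <- make_chain_ligand(n_atoms = 6, seed = 2)
#' generate_poses(site, lig, n = 8, seed = 3)
#' @export
generate_poses <- function(site, ligand, n = 64, seed = 1,
                           clash_cutoff = 2.2,
                           max_attempts_per_pose = 10000) {
  stopifnot(inherits(site, "pocket_site"), n >= 1)
  lig <- ligand[ligand$element != "H", , drop = FALSE]
  if (nrow(lig) == 0) abort("ligand has no heavy atoms")
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))     # centroid at origin
  prot <- heavy_coords(site$structure)
  # restrict clash partners to atoms near the pocket
  margin <- max(sqrt(rowSums(lig_xyz^2))) + clash_cutoff + 1
  bb_lo <- apply(site$centers, 2, min) - margin
  bb_hi <- apply(site$centers, 2, max) + margin
  near <- prot[, 1] >= bb_lo[1] & prot[, 1] <= bb_hi[1] &
    prot[, 2] >= bb_lo[2] & prot[, 2] <= bb_hi[2] &
    prot[, 3] >= bb_lo[3] & prot[, 3] <= bb_hi[3]
  prot_near <- prot[near, , drop = FALSE]
  n_vox <- nrow(site$centers)

  rotations <- vector("list", n)
  translations <- vector("list", n)
  with_seed(as.integer(seed), {
    accepted <- 0L
    attempts <- 0L
    budget <- max_attempts_per_pose * n
    while (accepted < n) {
      if (attempts >= budget) {
        abort("pocket_too_small", class = "pocket_too_small")
      }
      attempts <- attempts + 1L
      rot <- random_rotation()
      vox <- if (n_vox == 1) 1L else sample.int(n_vox, 1)
      tr <- as.numeric(site$centers[vox, ])
      placed <- tcrossprod(lig_xyz, rot)
      placed <- sweep(placed, 2, tr, "+")
      clash <- nrow(prot_near) > 0 &&
        min(cross_dist2(placed, prot_near)) < clash_cutoff^2
      if (!clash) {
        accepted <- accepted + 1L
        rotations[[accepted]] <- rot
        translations[[accepted]] <- tr
      }
    }
  })
  structure(
    list(ligand = as_tibble(cbind(tibble(element = lig$element),
                                  as.data.frame(lig_xyz))) |>
           stats::setNames(c("element", "x", "y", "z")),
         poses = tibble(pose = seq_len(n), rotation = rotations,
                        translation = translations),
         n_poses = n, seed = as.integer(seed),
         clash_cutoff = clash_cutoff, site_center = site$center),
    class = "pose_ensemble"
  )
}

#' Transformed ligand coordinates for one pose
#'
#' @param ensemble A `pose_ensemble`.
#' @param i Pose index.
#' @return Tibble of ligand atoms with transformed coordinates.
#' @export
pose_coords <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "pose_ensemble"),
            i >= 1, i <= ensemble$n_poses)
  xyz <- as.matrix(ensemble$ligand[, c("x", "y", "z")])
  placed <- tcrossprod(xyz, ensemble$poses$rotation[[i]])
  placed <- sweep(placed, 2, ensemble$poses$translation[[i]], "+")
  tibble(element = ensemble$ligand$element,
         x = placed[, 1], y = placed[, 2], z = placed[, 3])
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("<pose_ensemble> %d poses of a %d-heavy-atom ligand (seed %d)\n",
              x$n_poses, nrow(x$ligand), x$seed))
  invisible(x)
}

#' Serialize a pose ensemble as a JSON transform list
#'
#' @param ensemble A `pose_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses_json <- function(ensemble, path) {
  jsonlite::write_json(
    list(
      seed = ensemble$seed, n_poses = ensemble$n_poses,
      clash_cutoff = ensemble$clash_cutoff,
      ligand = as.list(ensemble$ligand),
      rotations = lapply(ensemble$poses$rotation, function(m)
        unclass(as.data.frame(m))),
      translations = ensemble$poses$translation
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname generate_poses
#' @param x A `pose_ensemble`.
#' @param ... Unused.
#' @export
tidy.pose_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_poses), function(i) {
    mutate(pose_coords(x, i), pose = i, .before = 1)
  })
}
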