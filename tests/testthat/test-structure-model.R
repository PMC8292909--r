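# Flood-fill site definition and rigid-body pose sampling.

test_that("flood fill reproduces the hollow-shell closed form", {
  p7 <- make_pocket(seed = 1, shell_edge = 7, mouth = FALSE)
  s7 <- flood_fill_site(p7, attr(p7, "pocket_spec")$cavity_center)
  expect_equal(nrow(s7$voxels), 27)           # 3x3x3 interior
  p11 <- make_pocket(seed = 5, shell_edge = 11, mouth = TRUE)
  ps <- attr(p11, "pocket_spec")
  s11 <- flood_fill_site(p11, ps$cavity_center, max_radius = 8)
  expect_equal(nrow(s11$voxels), ps$cavity_voxels)   # 7^3 + mouth channel
})

test_that("flood fill edge cases: radius zero, in-voxel seed shifts, buried seed", {
  p <- make_pocket(seed = 3)
  ps <- attr(p, "pocket_spec")
  s0 <- flood_fill_site(p, ps$cavity_center, max_radius = 0)
  expect_equal(nrow(s0$voxels), 1)
  sA <- flood_fill_site(p, ps$cavity_center, max_radius = 8)
  sB <- flood_fill_site(p, ps$cavity_center + c(0.4, -0.3, 0.2),
                        max_radius = 8)
  expect_identical(sort_voxels(sA$voxels), sort_voxels(sB$voxels))
  expect_error(flood_fill_site(p, c(1.5, 1.5, 1.5), max_radius = 8),
               class = "seed_buried")
  expect_error(flood_fill_site(p[0, ], ps$cavity_center), "empty structure")
})

test_that("flood fill equals brute-force reachability on random lattices", {
  n_cases <- 25
  for (case in seq_len(n_cases)) {
    withr::with_seed(3000 + case, {
      n_atoms <- sample(10:60, 1)
      atoms <- matrix(runif(3 * n_atoms, -9, 9), ncol = 3)
      max_radius <- sample(6:12, 1)
    })
    st <- structure_table(rep("C", nrow(atoms)), atoms[, 1], atoms[, 2],
                          atoms[, 3])
    seed_xyz <- c(0.5, 0.5, 0.5)
    expected <- oracle_flood(atoms, seed_xyz, max_radius = max_radius)
    if (is.null(expected)) {
      expect_error(flood_fill_site(st, seed_xyz, max_radius = max_radius),
                   class = "seed_buried")
    } else {
      site <- flood_fill_site(st, seed_xyz, max_radius = max_radius)
      expect_identical(sort_voxels(site$voxels), sort_voxels(expected))
    }
  }
})

test_that("translating structure and seed by a lattice vector translates the site", {
  p <- make_pocket(seed = 9, shell_edge = 9, mouth = TRUE)
  ps <- attr(p, "pocket_spec")
  s1 <- flood_fill_site(p, ps$cavity_center, max_radius = 7)
  shift <- c(5, -3, 2)   # whole-voxel translation
  p2 <- dplyr::mutate(p, x = x + shift[1], y = y + shift[2],
                      z = z + shift[3])
  s2 <- flood_fill_site(p2, ps$cavity_center + shift, max_radius = 7)
  expect_identical(sort_voxels(s1$voxels), sort_voxels(s2$voxels))
  expect_equal(s2$center, s1$center + shift)
})

test_that("site_from_residues centers on the residue centroid and floods", {
  fx <- tiny_site()
  # name all shell residues: centroid is the cavity center region
  p <- fx$pocket
  some <- unique(p$resno)
  site <- site_from_residues(p, some, max_radius = 8)
  expect_s3_class(site, "pocket_site")
  expect_gt(nrow(site$voxels), 100)
  # site residues cover a sizeable fraction of the named list
  expect_gte(nrow(site$residues) / length(some), 0.2)
  # duplicates are ignored
  site2 <- site_from_residues(p, c(some, some[1:5]), max_radius = 8)
  expect_identical(sort_voxels(site$voxels), sort_voxels(site2$voxels))
  expect_error(site_from_residues(p, c(some, 99999L)),
               "not in structure")
})

test_that("pose ensembles are clash-free, rigid, seeded and order-invariant", {
  fx <- tiny_site()
  lig <- make_chain_ligand(7, seed = 21)
  ens <- generate_poses(fx$site, lig, n = 64, seed = 8)
  expect_equal(ens$n_poses, 64)
  prot <- as.matrix(fx$pocket[, c("x", "y", "z")])
  lig0 <- as.matrix(ens$ligand[, c("x", "y", "z")])
  d0 <- dist(lig0)
  bbox_lo <- apply(fx$site$centers, 2, min) - fx$site$spacing / 2
  bbox_hi <- apply(fx$site$centers, 2, max) + fx$site$spacing / 2
  for (i in c(1, 17, 64)) {
    pc <- as.matrix(pose_coords(ens, i)[, c("x", "y", "z")])
    expect_gte(sqrt(min(pocketscreen:::cross_dist2(pc, prot))), 2.2)
    expect_lt(max(abs(dist(pc) - d0)), 1e-6)      # rigid transform
    centroid <- colMeans(pc)
    expect_true(all(centroid >= bbox_lo & centroid <= bbox_hi))
  }
  # determinism
  ens2 <- generate_poses(fx$site, lig, n = 64, seed = 8)
  expect_identical(ens$poses, ens2$poses)
  # ligand atom order must not change the sampled transforms
  perm <- rev(seq_len(nrow(lig)))
  ens3 <- generate_poses(fx$site, lig[perm, ], n = 16, seed = 8)
  ens4 <- generate_poses(fx$site, lig, n = 16, seed = 8)
  expect_identical(ens3$poses$rotation, ens4$poses$rotation)
  expect_identical(ens3$poses$translation, ens4$poses$translation)
})

test_that("an oversized ligand in a sealed pocket aborts as too small", {
  p <- make_pocket(seed = 2, shell_edge = 7, mouth = FALSE)
  site <- flood_fill_site(p, attr(p, "pocket_spec")$cavity_center,
                          max_radius = 4)
  big <- make_chain_ligand(40, seed = 3)
  expect_error(
    generate_poses(site, big, n = 4, seed = 1, max_attempts_per_pose = 50),
    class = "pocket_too_small"
  )
})
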