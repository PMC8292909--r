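# Library scoring, ranking, top-k and MaxMin diversity selection.

test_that("score_library ranks deterministically and order-invariantly", {
  fx <- tiny_site()
  m <- init_scoring_model(
    network_config(conv = tibble::tibble(filters = c(4L, 8L),
                                         kernel = c(3L, 3L),
                                         stride = c(2L, 2L)),
                   fc_units = 8L, in_channels = 2L, edge = 16L),
    seed = 2,
    spec = grid_spec(edge = 16L, channels = channel_scheme_minimal())
  )
  lib <- tibble::tibble(
    id = c("cpd_a", "cpd_b", "cpd_c"),
    conformer = lapply(4:6, function(n) make_chain_ligand(n, seed = n))
  )
  rt <- score_library(m, lib, fx$site, n_poses = 6, seed = 17)
  expect_equal(nrow(rt), 3)
  expect_equal(rt$rank, 1:3)
  expect_true(all(diff(rt$score) <= 0))
  rt2 <- score_library(m, lib, fx$site, n_poses = 6, seed = 17)
  expect_identical(as.data.frame(rt), as.data.frame(rt2))
  # shuffling the library must not change any compound's score or rank
  rt3 <- score_library(m, lib[c(3, 1, 2), ], fx$site, n_poses = 6, seed = 17)
  expect_identical(as.data.frame(rt), as.data.frame(rt3))
  # a compound without a conformer is skipped with a message
  lib_bad <- dplyr::bind_rows(lib,
                              tibble::tibble(id = "cpd_d",
                                             conformer = list(NULL)))
  expect_message(rt4 <- score_library(m, lib_bad, fx$site, n_poses = 6,
                                      seed = 17),
                 "without conformer")
  expect_equal(nrow(rt4), 3)
})

test_that("top_k slices the head of a ranked table", {
  rt <- ranked_table(tibble::tibble(id = c("a", "b", "c"),
                                    score = c(3, 1, 2)))
  expect_equal(rt$id, c("a", "c", "b"))
  expect_equal(nrow(top_k(rt, 0)), 0)
  expect_equal(top_k(rt, 10)$id, rt$id)
  expect_equal(top_k(rt, 2)$id, c("a", "c"))
})

test_that("ranked_table breaks score ties lexicographically by id", {
  rt <- ranked_table(tibble::tibble(id = c("z", "a", "m"),
                                    score = c(1, 1, 1)))
  expect_equal(rt$id, c("a", "m", "z"))
  expect_equal(rt$rank, 1:3)
})

test_that("circular fingerprints are deterministic and separate scaffolds", {
  smi <- c("c1ccccc1CCN", "c1ccccc1CCN", "C1CCNCC1")
  fp <- circular_fingerprint(smi)
  expect_identical(fp[1, ], fp[2, ])
  expect_false(identical(fp[1, ], fp[3, ]))
  d <- tanimoto_distance(fp)
  expect_equal(d[1, 2], 0)
  expect_gt(d[1, 3], 0.3)
})

test_that("pick_diverse never picks a structural duplicate before a distinct scaffold", {
  cands <- tibble::tibble(
    id = c("A", "A_dup", "B"),
    score = c(3, 2, 1),
    smiles = c("c1ccccc1CCN", "c1ccccc1CCN", "OCC(O)C(O)CO")
  )
  picks <- pick_diverse(ranked_table(cands), k = 2)
  expect_equal(picks, c("A", "B"))
  # k >= n returns everything
  expect_setequal(pick_diverse(ranked_table(cands), k = 10),
                  cands$id)
})

test_that("each greedy pick equals the exhaustive per-step optimum (n<=8, k<=4)", {
  for (case in 1:12) {
    withr::with_seed(7000 + case, {
      n <- sample(4:8, 1)
      k <- sample(2:4, 1)
      nb <- 32
      fp <- matrix(runif(n * nb) < 0.3, n, nb)
    })
    cands <- tibble::tibble(id = sprintf("m%02d", seq_len(n)),
                            score = seq(n, 1))
    picks <- pick_diverse(cands, k = k, fp = fp)
    d <- tanimoto_distance(fp)
    # replay the selection; at each step verify no candidate beats the pick
    sel <- match(picks[1], cands$id)
    expect_equal(sel, 1L)                     # seeded at the top-ranked
    for (step in 2:k) {
      chosen <- match(picks[step], cands$id)
      remaining <- setdiff(seq_len(n), sel)
      mind <- vapply(remaining,
                     function(j) min(d[j, sel]), numeric(1))
      expect_equal(min(d[chosen, sel]), max(mind))
      # tie-break: no lexicographically earlier id achieves the optimum
      best_ids <- cands$id[remaining[mind == max(mind)]]
      expect_equal(picks[step], sort(best_ids)[1])
      sel <- c(sel, chosen)
    }
  }
})

test_that("MaxMin beats random subsets of the same size almost always", {
  lib <- make_ligand_library(40, seed = 3,
                             violations = c(mw_low = 0))
  fp <- circular_fingerprint(lib$smiles)
  d <- tanimoto_distance(fp)
  cands <- tibble::tibble(id = lib$id, score = seq(nrow(lib), 1))
  picks <- pick_diverse(cands, k = 8, fp = fp)
  sel <- match(picks, cands$id)
  min_greedy <- min(d[sel, sel][upper.tri(diag(8))])
  wins <- 0
  for (trial in 1:100) {
    withr::with_seed(8000 + trial, rs <- sample(nrow(lib), 8))
    min_rand <- min(d[rs, rs][upper.tri(diag(8))])
    if (min_greedy >= min_rand) wins <- wins + 1
  }
  expect_gte(wins, 95)
})
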