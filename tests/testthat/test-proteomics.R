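# TMT channel normalization, differential abundance, thresholds, overlap.

test_that("channel normalization equalizes sums and preserves ratios", {
  m <- tibble::tibble(protein = c("P1", "P2"),
                      a = c(40, 60), b = c(100, 200))
  out <- normalize_channels(m)
  expect_equal(sum(out$a), 200)          # mean of {100, 300}
  expect_equal(sum(out$b), 200)
  expect_equal(out$a, c(40, 60) * 2)     # scale factors 2 and 2/3
  expect_equal(out$b, c(100, 200) * 2 / 3)
  expect_equal(out$a[1] / out$a[2], 40 / 60)
  # already-equal channels: identity
  eq <- tibble::tibble(protein = c("P1", "P2"), a = c(1, 3), b = c(2, 2))
  expect_equal(normalize_channels(eq), eq)
  # idempotence
  expect_equal(normalize_channels(out), out)
  # rank order within a channel is untouched
  withr::with_seed(5, big <- tibble::tibble(protein = sprintf("P%03d", 1:50),
                                            a = rexp(50), b = 3 * rexp(50)))
  nb <- normalize_channels(big)
  expect_equal(order(nb$a), order(big$a))
  # zero-sum channel is named in the error
  zz <- tibble::tibble(protein = "P1", a = 1, b = 0)
  expect_error(normalize_channels(zz), "b")
})

test_that("differential abundance matches hand-built cases", {
  des <- channel_design(c("r1", "r2", "r3", "t1", "t2", "t3"),
                        c(rep("minus_tet", 3), rep("plus_tet", 3)))
  m <- tibble::tibble(
    protein = c("flat", "doubled", "zeroed"),
    r1 = c(5, 10, 4), r2 = c(5, 10.01, 4), r3 = c(5, 9.99, 4),
    t1 = c(5, 20, 0), t2 = c(5, 20.02, 0), t3 = c(5, 19.98, 0)
  )
  st <- differential_abundance(m, des)
  expect_equal(st$log2fc[1], 0)
  expect_equal(st$p_value[1], 1)         # constant protein, flagged
  expect_equal(st$flag[1], "constant")
  expect_equal(st$log2fc[2], 1, tolerance = 1e-3)
  expect_lt(st$p_value[2], 0.05)
  expect_equal(st$flag[3], "zero_group_mean")
  expect_true(is.na(st$log2fc[3]))
})

test_that("swapping group labels flips the fold change and keeps p", {
  fx <- make_tmt_fixture(n_proteins = 60, n_planted = 10, seed = 8)
  norm <- normalize_channels(fx$intensities)
  a <- differential_abundance(norm, fx$design)
  b <- differential_abundance(norm, fx$design, reference = "plus_tet",
                              test = "minus_tet")
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p_value, a$p_value)
})

test_that("thresholds use the published cuts with an inclusive fold-change boundary", {
  st <- tibble::tibble(
    protein = c("at_cut", "below_cut", "p_gated", "up_hit"),
    log2fc = c(-0.5, -0.49, -2.0, 0.72),
    p_value = c(0.04, 0.04, 0.06, 0.001),
    flag = "ok"
  )
  out <- apply_thresholds(st)
  expect_equal(out$call, c("down", "ns", "ns", "up"))
})

test_that("packaged target tables reproduce the published significant counts", {
  t1 <- target_table("down")
  t2 <- target_table("up")
  expect_equal(nrow(t1), 33)
  expect_equal(nrow(t2), 6)
  expect_true(all(t1$log2fc <= -0.5))    # inclusive boundary: SRPK1 at -0.5
  expect_true(all(t2$log2fc >= 0.5))
  expect_equal(t1$log2fc[t1$gene == "SRPK1"], -0.5)
})

test_that("overlap classification partitions the common significant set", {
  st <- apply_thresholds(tibble::tibble(
    protein = c("A", "B", "C", "D", "E", "F"),
    log2fc = c(-1, -0.8, 0.9, 0.7, -1.2, 0.1),
    p_value = c(0.01, 0.02, 0.01, 0.03, 0.4, 0.01),
    flag = "ok"
  ))
  second <- tibble::tibble(protein = c("A", "B", "C", "D", "Z"),
                           call = c("down", "up", "up", "down", "up"))
  rep <- overlap_with_targets(st, targets = c("A", "B", "C", "X"),
                              second = second)
  expect_equal(rep$n_present, 3)
  expect_equal(rep$down, c("A", "B"))
  expect_equal(rep$up, "C")
  expect_equal(rep$groups$IV, "A")       # down/down
  expect_equal(rep$groups$II, "B")       # down here, up there
  expect_equal(rep$groups$I, "C")        # up/up
  expect_equal(rep$groups$III, "D")      # up here, down there
  # groups are disjoint and cover the common significant set
  all_ids <- unlist(rep$groups)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_setequal(all_ids, c("A", "B", "C", "D"))
  # disjoint id universes give empty overlaps
  rep0 <- overlap_with_targets(st, targets = c("Q", "R"))
  expect_equal(rep0$n_present, 0)
  expect_equal(rep0$n_down + rep0$n_up, 0)
})

test_that("planted effects are recovered on a small fixture", {
  fx <- make_tmt_fixture(n_proteins = 300, n_planted = 20, seed = 41)
  st <- fx$intensities |>
    normalize_channels() |>
    differential_abundance(fx$design) |>
    apply_thresholds()
  planted <- fx$truth$protein[fx$truth$planted]
  recovered <- sum(planted %in% st$protein[st$call == "down"])
  expect_gte(recovered, 18)
  false_pos <- sum(st$call != "ns" & !st$protein %in% planted)
  expect_lte(false_pos, 10)
})

test_that("loading factors are recoverable by normalization", {
  fx <- make_tmt_fixture(n_proteins = 100, n_planted = 0, seed = 6,
                         loading = c(1, 2, 0.5, 1.5, 0.8, 1.2, 1, 1, 1, 1))
  norm <- normalize_channels(fx$intensities)
  sums <- vapply(norm[, -1], sum, numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 1e-12)
})

test_that("an FDR-adjusted gate is never more permissive than raw p", {
  fx <- make_tmt_fixture(n_proteins = 200, n_planted = 10, seed = 31)
  st <- fx$intensities |>
    normalize_channels() |>
    differential_abundance(fx$design)
  raw <- apply_thresholds(st)
  fdr <- apply_thresholds(st, p_adjust = "BH")
  expect_lte(sum(fdr$call != "ns"), sum(raw$call != "ns"))
  # FDR-significant calls are a subset of raw-significant calls
  expect_true(all(fdr$protein[fdr$call != "ns"] %in%
                    raw$protein[raw$call != "ns"]))
  # some planted effects survive the correction (n = 3 Welch p-values are
  # heavy-tailed, so BH at m = 200 costs real power)
  planted <- fx$truth$protein[fx$truth$planted]
  expect_gte(sum(planted %in% fdr$protein[fdr$call == "down"]), 3)
})
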