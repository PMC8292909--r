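# The 3D-CNN scorer: configuration, aggregation, prediction, training.

tiny_config <- function() {
  network_config(conv = tibble::tibble(filters = c(4L, 8L),
                                       kernel = c(3L, 3L),
                                       stride = c(2L, 1L)),
                 fc_units = 8L, in_channels = 2L, edge = 8L)
}

tiny_spec <- function() grid_spec(edge = 8L, channels = channel_scheme_minimal())

test_that("network configuration validates and counts parameters in closed form", {
  cfg <- network_config()
  expect_equal(cfg$sizes, c(30L, 28L, 13L, 6L, 2L, 1L))
  hand <- (27 * 16 * 32 + 32) + (27 * 32 * 64 + 64) + (27 * 64 * 64 + 64) +
    (27 * 64 * 64 + 64) + (8 * 64 * 64 + 64) +
    (64 * 256 + 256) + (256 + 1)
  expect_equal(cfg$n_parameters, hand)
  # a stack that collapses below one voxel is rejected
  expect_error(
    network_config(conv = tibble::tibble(filters = c(8L, 8L),
                                         kernel = c(5L, 5L),
                                         stride = c(4L, 4L)),
                   edge = 8L),
    class = "architecture_invalid"
  )
})

test_that("initialization is seeded and the forward pass is finite", {
  m1 <- init_scoring_model(tiny_config(), seed = 7, spec = tiny_spec())
  m2 <- init_scoring_model(tiny_config(), seed = 7, spec = tiny_spec())
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$fc, m2$fc)
  zero <- matrix(0, 2 * 8^3, 1)
  s <- pocketscreen:::net_forward(m1, zero)$scores
  expect_true(is.finite(s))
})

test_that("Boltzmann aggregation matches closed forms and limits", {
  expect_equal(boltzmann_aggregate(rep(2.5, 5), beta = 3.7), 2.5)
  expect_equal(boltzmann_aggregate(c(0, 1), beta = 0), 0.5)
  expect_equal(boltzmann_aggregate(c(0, 1), beta = 1),
               exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_lt(abs(boltzmann_aggregate(c(0, 1), beta = 50) - 1), 1e-9)
  expect_error(boltzmann_aggregate(numeric(0)), "empty")
})

test_that("aggregation is monotone in beta, bounded, and permutation-invariant", {
  withr::with_seed(4, s <- rnorm(10))
  betas <- c(0, 0.5, 1, 2, 5, 20)
  vals <- vapply(betas, function(b) boltzmann_aggregate(s, b), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))        # toward max(s)
  expect_true(all(vals >= min(s) - 1e-12 & vals <= max(s) + 1e-12))
  expect_equal(vals[1], mean(s))
  expect_equal(boltzmann_aggregate(rev(s), 1.3),
               boltzmann_aggregate(s, 1.3))
})

test_that("predict_affinity aggregates pose scores and enforces the grid spec", {
  m <- init_scoring_model(tiny_config(), seed = 2, spec = tiny_spec())
  withr::with_seed(9, X <- matrix(runif(2 * 8^3 * 5) < 0.05, ncol = 5) * 1)
  pr <- predict_affinity(m, X)
  expect_equal(pr$score,
               boltzmann_aggregate(pr$pose_scores, m$beta))
  expect_gte(pr$score, min(pr$pose_scores))
  expect_lte(pr$score, max(pr$pose_scores))
  # single pose: aggregate equals the pose score
  one <- predict_affinity(m, X[, 1, drop = FALSE])
  expect_equal(one$score, one$pose_scores)
  # pose order invariance
  pr2 <- predict_affinity(m, X[, 5:1])
  expect_equal(pr2$score, pr$score)
  # mismatched grid shape is refused
  expect_error(predict_affinity(m, matrix(0, 100, 2)),
               class = "grid_spec_mismatch")
  wrong <- rasterize(random_generic_frame(5, 1), grid_spec(edge = 30))
  expect_error(predict_affinity(m, wrong), class = "grid_spec_mismatch")
})

test_that("training reduces the loss and converges on constant labels", {
  m <- init_scoring_model(tiny_config(), seed = 5, spec = tiny_spec())
  withr::with_seed(11, {
    X <- matrix(as.numeric(runif(2 * 8^3 * 24) < 0.05), ncol = 24)
  })
  ids <- rep(sprintf("c%02d", 1:12), each = 2)     # 12 complexes, 2 poses
  y <- stats::setNames(rep(5, 12), unique(ids))    # identical label
  fit <- train_scoring_model(m, X, ids, y, epochs = 150, batch_size = 6,
                             lr = 5e-3, seed = 3)
  expect_lt(fit$trace$mse[nrow(fit$trace)], fit$trace$mse[1])
  preds <- vapply(unique(ids), function(id) {
    predict_affinity(fit, X[, ids == id, drop = FALSE])$score
  }, numeric(1))
  expect_true(all(abs(preds - 5) < 0.1))
})

test_that("training is bit-reproducible for a fixed seed", {
  m <- init_scoring_model(tiny_config(), seed = 5, spec = tiny_spec())
  withr::with_seed(12, {
    X <- matrix(as.numeric(runif(2 * 8^3 * 16) < 0.05), ncol = 16)
  })
  ids <- rep(sprintf("c%02d", 1:8), each = 2)
  y <- stats::setNames(rnorm(8, 5), unique(ids))
  f1 <- train_scoring_model(m, X, ids, y, epochs = 5, batch_size = 4,
                            seed = 21)
  f2 <- train_scoring_model(m, X, ids, y, epochs = 5, batch_size = 4,
                            seed = 21)
  expect_identical(f1$layers, f2$layers)
  expect_identical(f1$fc, f2$fc)
  expect_identical(f1$trace, f2$trace)
})

test_that("tidy and glance summarize a model", {
  m <- init_scoring_model(tiny_config(), seed = 1, spec = tiny_spec())
  td <- tidy(m)
  expect_equal(nrow(td), 4)   # 2 conv + 2 dense
  expect_equal(sum(td$n_parameters), m$config$n_parameters)
  gl <- glance(m)
  expect_equal(gl$epochs_trained, 0L)
})

test_that("checkpoints round-trip through JSON with identical predictions", {
  m <- init_scoring_model(tiny_config(), seed = 9, spec = tiny_spec())
  withr::with_seed(3, X <- matrix(as.numeric(runif(2 * 8^3 * 4) < 0.05),
                                  ncol = 4))
  path <- tempfile(fileext = ".json")
  write_scoring_model(m, path)
  m2 <- read_scoring_model(path)
  expect_equal(predict_affinity(m2, X)$pose_scores,
               predict_affinity(m, X)$pose_scores, tolerance = 1e-12)
})
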