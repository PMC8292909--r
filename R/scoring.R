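#' Configure the 3D convolutional affinity scorer
#'
#' The default architecture mirrors the screening scorer: five valid-padded
#' 3D convolutions of 32x3^3, 64x3^3, 64x3^3, 64x3^3, 64x2^3
#' (filters x cubic kernel edge) with rectified-linear activations, followed
#' by a fully connected layer of 256 ReLU units and a single scalar output
#' on the pKi/pIC50 scale. Strides (1, 2, 2, 2, 1) collapse the default
#' 30-voxel grid to 1^3 before the dense head. Any layer stack that drives
#' the spatial extent below one voxel is rejected.
#'
#' @param conv Tibble (or data frame) with columns `filters`, `kernel`,
#'   `stride`, one row per convolutional layer.
#' @param fc_units Hidden units in the dense layer (default 256).
#' @param in_channels Input channels (must match the grid spec).
#' @param edge Input grid edge in voxels.
#' @return A `network_config` with the per-layer spatial sizes and the
#'   closed-form parameter count attached.
#' @examples
#' cfg <- network_config()
#' cfg$n_parameters
#' @export
network_config <- function(conv = tibble(filters = c(32L, 64L, 64L, 64L, 64L),
                                         kernel = c(3L, 3L, 3L, 3L, 2L),
                                         stride = c(1L, 2L, 2L, 2L, 1L)),
                           fc_units = 256L, in_channels = 16L, edge = 30L) {
  conv <- as_tibble(conv)
  stopifnot(all(c("filters", "kernel", "stride") %in% names(conv)),
            fc_units >= 1, in_channels >= 1, edge >= 1)
  sizes <- integer(nrow(conv) + 1)
  sizes[1] <- as.integer(edge)
  for (l in seq_len(nrow(conv))) {
    if (sizes[l] < conv$kernel[l]) {
      abort("architecture_invalid", class = "architecture_invalid")
    }
    sizes[l + 1] <- (sizes[l] - conv$kernel[l]) %/% conv$stride[l] + 1L
    if (sizes[l + 1] < 1) {
      abort("architecture_invalid", class = "architecture_invalid")
    }
  }
  in_ch <- c(as.integer(in_channels), conv$filters[-nrow(conv)])
  n_conv <- sum(conv$kernel^3 * in_ch * conv$filters + conv$filters)
  flat <- conv$filters[nrow(conv)] * sizes[length(sizes)]^3
  n_fc <- flat * fc_units + fc_units + fc_units + 1
  structure(
    list(conv = conv, fc_units = as.integer(fc_units),
         in_channels = as.integer(in_channels), edge = as.integer(edge),
         sizes = sizes, flat = as.integer(flat),
         n_parameters = n_conv + n_fc),
    class = "network_config"
  )
}

# Compact config suited to 16^3 two-channel desk-scale grids.
#' @rdname network_config
#' @export
network_config_small <- function(in_channels = 2L, edge = 16L) {
  network_config(conv = tibble(filters = c(8L, 16L, 16L),
                               kernel = c(3L, 3L, 3L),
                               stride = c(2L, 2L, 1L)),
                 fc_units = 32L, in_channels = in_channels, edge = edge)
}

#' Initialize a scoring model
#'
#' He-normal weight initialization from a seeded generator; two inits with
#' the same seed are identical.
#'
#' @param config A [network_config()].
#' @param seed Integer RNG seed.
#' @param spec Grid spec the model is bound to; predictions refuse grids
#'   whose spec fingerprint differs. Defaults to a spec matching the config.
#' @param beta Boltzmann aggregation inverse temperature (default 1).
#' @return A `scoring_model`.
#' @export
init_scoring_model <- function(config, seed = 1, spec = NULL, beta = 1) {
  stopifnot(inherits(config, "network_config"), beta >= 0, is.finite(beta))
  if (is.null(spec)) {
    spec <- if (config$in_channels == 2) {
      grid_spec(edge = config$edge, channels = channel_scheme_minimal())
    } else {
      grid_spec(edge = config$edge)
    }
  }
  stopifnot(spec$n_channels == config$in_channels,
            spec$edge == config$edge)
  layers <- vector("list", nrow(config$conv))
  fc <- NULL
  with_seed(as.integer(seed), {
    in_ch <- config$in_channels
    for (l in seq_len(nrow(config$conv))) {
      k <- config$conv$kernel[l]; f <- config$conv$filters[l]
      fanin <- k^3 * in_ch
      layers[[l]] <- list(
        W = matrix(rnorm(fanin * f, sd = sqrt(2 / fanin)), fanin, f),
        b = numeric(f)
      )
      in_ch <- f
    }
    fc <- list(
      W1 = matrix(rnorm(config$flat * config$fc_units,
                        sd = sqrt(2 / config$flat)),
                  config$flat, config$fc_units),
      b1 = numeric(config$fc_units),
      W2 = matrix(rnorm(config$fc_units, sd = sqrt(2 / config$fc_units)),
                  config$fc_units, 1),
      b2 = 0
    )
  })
  m <- structure(
    list(config = config, layers = layers, fc = fc, beta = beta,
         grid_fp = grid_fingerprint(spec), spec = spec, trace = NULL),
    class = "scoring_model"
  )
  m$caches <- build_conv_caches(m)
  m
}

# Precompute, per conv layer, the gather index (im2col) and its sparse
# scatter transpose for the input-gradient pass.
build_conv_caches <- function(model) {
  cfg <- model$config
  caches <- vector("list", nrow(cfg$conv))
  in_ch <- cfg$in_channels
  for (l in seq_len(nrow(cfg$conv))) {
    D <- cfg$sizes[l]; K <- cfg$conv$kernel[l]; s <- cfg$conv$stride[l]
    O <- cfg$sizes[l + 1]
    pos <- seq.int(0L, by = s, length.out = O)
    # patch grid: x fastest, matching the channel-fastest voxel layout
    patches <- as.matrix(expand.grid(x = pos, y = pos, z = pos))
    offs <- as.matrix(expand.grid(c = seq_len(in_ch) - 1L,
                                  kx = 0:(K - 1), ky = 0:(K - 1),
                                  kz = 0:(K - 1)))
    ck <- nrow(offs)
    idx <- integer(ck * nrow(patches))
    ptr <- 1L
    for (p in seq_len(nrow(patches))) {
      vx <- patches[p, 1] + offs[, "kx"]
      vy <- patches[p, 2] + offs[, "ky"]
      vz <- patches[p, 3] + offs[, "kz"]
      idx[ptr:(ptr + ck - 1L)] <-
        offs[, "c"] + in_ch * (vx + D * (vy + D * vz)) + 1L
      ptr <- ptr + ck
    }
    len_in <- in_ch * D^3
    S <- Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                              dims = c(length(idx), len_in))
    caches[[l]] <- list(idx = idx, S = S, ck = ck, n_patches = nrow(patches),
                        in_ch = in_ch, out_ch = cfg$conv$filters[l])
    in_ch <- cfg$conv$filters[l]
  }
  caches
}

# Forward pass over a batch. X: (in_channels*edge^3) x B matrix, channel
# fastest. Returns scores and (optionally) the activations needed by the
# backward pass.
net_forward <- function(model, X, keep = FALSE) {
  B <- ncol(X)
  acts <- if (keep) vector("list", length(model$layers)) else NULL
  A <- X
  for (l in seq_along(model$layers)) {
    cc <- model$caches[[l]]
    Xg <- A[cc$idx, , drop = FALSE]
    dim(Xg) <- c(cc$ck, cc$n_patches * B)
    Z <- crossprod(model$layers[[l]]$W, Xg) + model$layers[[l]]$b
    Apost <- Z * (Z > 0)
    if (keep) acts[[l]] <- list(Xg = Xg, mask = Z > 0)
    dim(Apost) <- c(cc$out_ch * cc$n_patches, B)
    A <- Apost
  }
  H <- crossprod(model$fc$W1, A) + model$fc$b1
  Hr <- H * (H > 0)
  scores <- as.numeric(crossprod(model$fc$W2, Hr) + model$fc$b2)
  if (!keep) return(list(scores = scores))
  list(scores = scores, acts = acts, flat = A, H = H, Hr = Hr)
}

# Backward pass: gradient of sum_i dscore[i] * score_i wrt all parameters.
net_backward <- function(model, fwd, dscore) {
  B <- length(dscore)
  dHr <- model$fc$W2 %*% matrix(dscore, nrow = 1)
  dW2 <- fwd$Hr %*% matrix(dscore, ncol = 1)
  db2 <- sum(dscore)
  dH <- dHr * (fwd$H > 0)
  dW1 <- fwd$flat %*% Matrix::t(dH)
  db1 <- rowSums(dH)
  dA <- model$fc$W1 %*% dH                       # (flat) x B
  grads_conv <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    cc <- model$caches[[l]]
    dApost <- as.matrix(dA)
    dim(dApost) <- c(cc$out_ch, cc$n_patches * B)
    dZ <- dApost * fwd$acts[[l]]$mask
    grads_conv[[l]] <- list(W = fwd$acts[[l]]$Xg %*% Matrix::t(dZ),
                            b = rowSums(dZ))
    if (l > 1) {
      dXg <- model$layers[[l]]$W %*% dZ          # ck x (P*B)
      dim(dXg) <- c(cc$ck * cc$n_patches, B)
      dA <- Matrix::crossprod(cc$S, dXg)
    }
  }
  list(conv = grads_conv,
       fc = list(W1 = as.matrix(dW1), b1 = db1, W2 = as.matrix(dW2),
                 b2 = db2))
}

#' Boltzmann-weighted aggregation of pose scores
#'
#' Combines an ensemble of per-pose scores into one value via the
#' softmax-weighted mean \eqn{\sum_i s_i e^{\beta s_i} / \sum_i e^{\beta
#' s_i}}, computed with a max-shift for overflow safety. At `beta = 0` this
#' is the arithmetic mean; as `beta` grows it approaches the maximum. The
#' result always lies in `[min(s), max(s)]` and is invariant to score order.
#'
#' @param scores Numeric vector of pose scores (at least one, all finite).
#' @param beta Inverse temperature, `>= 0`.
#' @return A scalar aggregate score.
#' @examples
#' boltzmann_aggregate(c(0, 1), beta = 0)  # 0.5
#' boltzmann_aggregate(c(0, 1), beta = 1)  # exp(1) / (1 + exp(1))
#' @export
boltzmann_aggregate <- function(scores, beta = 1) {
  if (length(scores) == 0) abort("empty score vector")
  stopifnot(all(is.finite(scores)), beta >= 0, is.finite(beta))
  w <- boltzmann_weights(scores, beta)
  sum(w * scores)
}

boltzmann_weights <- function(scores, beta) {
  e <- exp(beta * (scores - max(scores)))
  e / sum(e)
}

#' Predict an affinity from a pose-grid ensemble
#'
#' Runs the per-pose forward passes and Boltzmann-aggregates the pose scores.
#'
#' @param model A `scoring_model`.
#' @param grids A list of `grid_tensor`s (or a pre-flattened matrix with one
#'   pose per column) sharing the model's grid spec.
#' @param beta Aggregation inverse temperature; defaults to the model's.
#' @return List with `score` (the aggregate) and `pose_scores`.
#' @export
predict_affinity <- function(model, grids, beta = model$beta) {
  X <- check_grids(model, grids)
  sc <- net_forward(model, X)$scores
  list(score = boltzmann_aggregate(sc, beta), pose_scores = sc)
}

check_grids <- function(model, grids) {
  if (is.matrix(grids)) {
    if (nrow(grids) != model$config$in_channels * model$config$edge^3) {
      abort("grid_spec_mismatch", class = "grid_spec_mismatch")
    }
    return(grids)
  }
  if (inherits(grids, "grid_tensor")) grids <- list(grids)
  fps <- lapply(grids, function(g) grid_fingerprint(attr(g, "spec")))
  if (!all(vapply(fps, identical, logical(1), model$grid_fp))) {
    abort("grid_spec_mismatch", class = "grid_spec_mismatch")
  }
  grid_matrix(grids)
}

#' Train the scoring model
#'
#' Minimizes the mean squared error between Boltzmann-aggregated ensemble
#' scores and pKi/pIC50-scale labels with the Adam adaptive-moment method,
#' over seeded shuffled minibatches of complexes (default 64 per gradient
#' step). Aggregation is inside the loss, so pose weighting is learned
#' end-to-end. Training is reproducible given the seed (single-threaded
#' numerics).
#'
#' @param model A `scoring_model` from [init_scoring_model()].
#' @param grids Matrix of flattened pose grids, one column per pose, or list
#'   of `grid_tensor`s.
#' @param complex_of_grid Integer/character id mapping each pose column to
#'   its complex.
#' @param labels Named (by complex id) or ordered numeric vector of affinity
#'   labels, one per complex.
#' @param epochs Training epochs (default 30).
#' @param batch_size Complexes per gradient step (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Shuffle seed.
#' @param beta Aggregation inverse temperature (defaults to the model's).
#' @return The trained model, with a per-epoch `trace` tibble
#'   (`epoch`, `mse`).
#' @export
train_scoring_model <- function(model, grids, complex_of_grid, labels,
                                epochs = 30, batch_size = 64, lr = 1e-3,
                                seed = 1, beta = model$beta) {
  X <- check_grids(model, grids)
  cplx <- as.character(complex_of_grid)
  ids <- unique(cplx)
  y <- if (!is.null(names(labels))) labels[ids] else {
    stopifnot(length(labels) == length(ids)); stats::setNames(labels, ids)
  }
  stopifnot(all(is.finite(y)), batch_size >= 1)
  pose_cols <- split(seq_len(ncol(X)), factor(cplx, levels = ids))
  opt <- adam_state(model)
  trace <- numeric(epochs)
  step <- 0L
  with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(ids))
      sse <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1, length(ord))]
        cols <- unlist(pose_cols[batch], use.names = FALSE)
        n_pose <- lengths(pose_cols[batch])
        fwd <- net_forward(model, X[, cols, drop = FALSE], keep = TRUE)
        per <- split(fwd$scores, rep(seq_along(batch), n_pose))
        aggs <- numeric(length(batch))
        dsc <- numeric(length(fwd$scores))
        pos <- 0L
        for (b in seq_along(batch)) {
          s <- per[[b]]
          wgt <- boltzmann_weights(s, beta)
          agg <- sum(wgt * s)
          aggs[b] <- agg
          resid <- agg - y[ids[batch[b]]]
          dsc[pos + seq_along(s)] <-
            (2 / length(batch)) * resid * wgt * (1 + beta * (s - agg))
          pos <- pos + length(s)
        }
        loss <- mean((aggs - y[ids[batch]])^2)
        if (!is.finite(loss)) {
          abort("diverged", class = "diverged")
        }
        sse <- sse + loss * length(batch)
        grads <- net_backward(model, fwd, dsc)
        step <- step + 1L
        model <- adam_update(model, grads, opt, lr, step)
      }
      trace[ep] <- sse / length(ids)
    }
  })
  model$trace <- tibble(epoch = seq_len(epochs), mse = trace)
  model
}

adam_state <- function(model) {
  e <- new.env(parent = emptyenv())
  zeros_like <- function(p) lapply(p, function(x) x * 0)
  e$m <- list(conv = lapply(model$layers, zeros_like),
              fc = zeros_like(model$fc))
  e$v <- e$m
  e
}

adam_update <- function(model, grads, opt, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^step)
    vhat <- v2 / (1 - beta2^step)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  for (l in seq_along(model$layers)) {
    for (nm in c("W", "b")) {
      r <- upd(model$layers[[l]][[nm]], grads$conv[[l]][[nm]],
               opt$m$conv[[l]][[nm]], opt$v$conv[[l]][[nm]])
      model$layers[[l]][[nm]] <- r$p
      opt$m$conv[[l]][[nm]] <- r$m; opt$v$conv[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    r <- upd(model$fc[[nm]], grads$fc[[nm]], opt$m$fc[[nm]], opt$v$fc[[nm]])
    model$fc[[nm]] <- r$p
    opt$m$fc[[nm]] <- r$m; opt$v$fc[[nm]] <- r$v
  }
  model
}

#' Save or load a scoring-model checkpoint
#'
#' One self-contained JSON file holding the layer configuration, all
#' weights, the aggregation temperature and the grid-spec fingerprint.
#'
#' @param model A `scoring_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly ([write_scoring_model()]); the restored model
#'   ([read_scoring_model()]).
#' @export
write_scoring_model <- function(model, path) {
  jsonlite::write_json(
    list(
      conv = as.list(model$config$conv),
      fc_units = model$config$fc_units,
      in_channels = model$config$in_channels,
      edge = model$config$edge,
      beta = model$beta,
      grid_fp = model$grid_fp,
      layers = lapply(model$layers, function(l)
        list(W = as.numeric(l$W), dim_W = dim(l$W), b = l$b)),
      fc = list(W1 = as.numeric(model$fc$W1), dim_W1 = dim(model$fc$W1),
                b1 = model$fc$b1, W2 = as.numeric(model$fc$W2),
                b2 = model$fc$b2)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_scoring_model
#' @export
read_scoring_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- network_config(conv = as_tibble(js$conv), fc_units = js$fc_units,
                        in_channels = js$in_channels, edge = js$edge)
  spec <- if (js$in_channels == 2) {
    grid_spec(edge = js$edge, channels = channel_scheme_minimal())
  } else {
    grid_spec(edge = js$edge)
  }
  m <- init_scoring_model(cfg, seed = 0, spec = spec, beta = js$beta)
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$W <- matrix(js$layers$W[[l]], js$layers$dim_W[[l]][1],
                              js$layers$dim_W[[l]][2])
    m$layers[[l]]$b <- js$layers$b[[l]]
  }
  m$fc$W1 <- matrix(js$fc$W1, js$fc$dim_W1[1], js$fc$dim_W1[2])
  m$fc$b1 <- js$fc$b1
  m$fc$W2 <- matrix(js$fc$W2, ncol = 1)
  m$fc$b2 <- js$fc$b2
  m$grid_fp <- js$grid_fp
  m
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("<scoring_model>\n")
  cat(sprintf("  input:  %d channels x %d^3 voxels\n",
              x$config$in_channels, x$config$edge))
  cat(sprintf("  conv:   %s\n",
              paste(sprintf("%dx%d^3/s%d", x$config$conv$filters,
                            x$config$conv$kernel, x$config$conv$stride),
                    collapse = ", ")))
  cat(sprintf("  dense:  %d ReLU -> 1\n", x$config$fc_units))
  cat(sprintf("  params: %d   beta: %.3g   trained: %s\n",
              x$config$n_parameters, x$beta,
              if (is.null(x$trace)) "no" else
                sprintf("%d epochs", nrow(x$trace))))
  invisible(x)
}

#' @rdname train_scoring_model
#' @param x A `scoring_model`.
#' @param ... Unused.
#' @export
tidy.scoring_model <- function(x, ...) {
  cfg <- x$config
  in_ch <- c(cfg$in_channels, cfg$conv$filters[-nrow(cfg$conv)])
  conv <- tibble(
    layer = paste0("conv", seq_len(nrow(cfg$conv))),
    filters = cfg$conv$filters, kernel = cfg$conv$kernel,
    stride = cfg$conv$stride, out_edge = cfg$sizes[-1],
    n_parameters = cfg$conv$kernel^3 * in_ch * cfg$conv$filters +
      cfg$conv$filters
  )
  fc <- tibble(
    layer = c("fc1", "fc2"),
    filters = c(cfg$fc_units, 1L), kernel = NA_integer_,
    stride = NA_integer_, out_edge = NA_integer_,
    n_parameters = c(cfg$flat * cfg$fc_units + cfg$fc_units,
                     cfg$fc_units + 1L)
  )
  bind_rows(conv, fc)
}

#' @export
glance.scoring_model <- function(x, ...) {
  tibble(
    n_parameters = x$config$n_parameters,
    beta = x$beta,
    epochs_trained = if (is.null(x$trace)) 0L else nrow(x$trace),
    final_mse = if (is.null(x$trace)) NA_real_ else
      x$trace$mse[nrow(x$trace)]
  )
}

#' @export
autoplot.scoring_model <- function(object, ...) {
  if (is.null(object$trace)) abort("model has no training trace")
  ggplot(object$trace, aes(x = .data$epoch, y = .data$mse)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "epoch", y = "training MSE (pK units^2)") +
    theme_minimal()
}
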