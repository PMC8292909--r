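#' Voxel grid specification
#'
#' The featurizer rasterizes a protein-ligand complex into a binary occupancy
#' tensor of `n_channels x edge^3`. The default channel scheme crosses the
#' entity (protein/ligand) with eight element classes (C, N, O, S, P, B,
#' halogen, other), giving 16 channels. Voxels are half-open cubes
#' `[x, x + spacing)`; the default 30-voxel, 1-Angstrom grid spans
#' `[-15, +15)` per axis around the site center.
#'
#' @param edge Voxels per axis (default 30).
#' @param spacing Voxel edge length in Angstrom (default 1).
#' @param channels Channel scheme tibble from [channel_scheme()].
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(edge = 30L, spacing = 1, channels = channel_scheme()) {
  stopifnot(edge >= 4, spacing > 0)
  structure(list(edge = as.integer(edge), spacing = spacing,
                 channels = channels, n_channels = nrow(channels)),
            class = "grid_spec")
}

#' Channel scheme for grid featurization
#'
#' @param classes Named list mapping class names to element symbol vectors;
#'   an `other` class absorbing everything else is always appended.
#' @param entities Entities to cross with the classes.
#' @return Tibble with columns `channel`, `entity`, `class`.
#' @export
channel_scheme <- function(classes = list(C = "C", N = "N", O = "O", S = "S",
                                          P = "P", B = "B",
                                          halogen = c("F", "Cl", "Br", "I")),
                           entities = c("protein", "ligand")) {
  cls <- c(names(classes), "other")
  tb <- tidyr::expand_grid(entity = entities, class = cls)
  tb$channel <- seq_len(nrow(tb))
  attr(tb, "class_members") <- classes
  tb[, c("channel", "entity", "class")]
}

# Minimal 2-channel scheme (protein / ligand occupancy only); used for
# desk-scale training sets.
#' @rdname channel_scheme
#' @export
channel_scheme_minimal <- function() {
  channel_scheme(classes = list(), entities = c("protein", "ligand"))
}

element_class <- function(element, classes) {
  out <- rep("other", length(element))
  for (nm in names(classes)) out[element %in% classes[[nm]]] <- nm
  out
}

#' Build a site-centered complex frame
#'
#' Joins protein atoms and one ligand pose into a single table in
#' site-centered coordinates (site center at the origin). Centering is
#' applied once; the frame records it.
#'
#' @param structure Protein structure tibble.
#' @param ligand Ligand atoms tibble (one pose, `element`, `x`, `y`, `z`).
#' @param center Site center (length-3, Angstrom), e.g. `site$center`.
#' @return A `complex_frame` tibble with columns `entity`, `element`,
#'   `x`, `y`, `z`.
#' @export
complex_frame <- function(structure, ligand, center) {
  fr <- bind_rows(
    tibble(entity = "protein", element = structure$element,
           x = structure$x, y = structure$y, z = structure$z),
    tibble(entity = "ligand", element = ligand$element,
           x = ligand$x, y = ligand$y, z = ligand$z)
  )
  fr$x <- fr$x - center[1]; fr$y <- fr$y - center[2]; fr$z <- fr$z - center[3]
  attr(fr, "centered") <- TRUE
  class(fr) <- c("complex_frame", class(fr))
  fr
}

#' Re-center a frame (idempotent)
#'
#' @param frame A `complex_frame`.
#' @param center Center to subtract; ignored if the frame is already
#'   centered.
#' @return The centered frame.
#' @export
center_frame <- function(frame, center = c(0, 0, 0)) {
  if (isTRUE(attr(frame, "centered"))) return(frame)
  frame$x <- frame$x - center[1]
  frame$y <- frame$y - center[2]
  frame$z <- frame$z - center[3]
  attr(frame, "centered") <- TRUE
  frame
}

#' Random rotation/translation augmentation of a complex frame
#'
#' Applies one uniform random rotation about the origin followed by a
#' translation uniform in `[-t_max, t_max]^3` to the whole complex. Seeded
#' and reproducible; rigid (all pairwise distances preserved).
#'
#' @param frame A centered `complex_frame`.
#' @param seed Integer RNG seed.
#' @param t_max Translation half-range in Angstrom (default 2).
#' @return The transformed frame, with the transform in attributes
#'   `rotation` and `translation`.
#' @export
augment_frame <- function(frame, seed, t_max = 2) {
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  rot <- NULL; tr <- NULL
  with_seed(as.integer(seed), {
    rot <- random_rotation()
    tr <- runif(3, -t_max, t_max)
  })
  out <- tcrossprod(xyz, rot)
  out <- sweep(out, 2, tr, "+")
  frame$x <- out[, 1]; frame$y <- out[, 2]; frame$z <- out[, 3]
  attr(frame, "rotation") <- rot
  attr(frame, "translation") <- tr
  frame
}

#' Rasterize a complex frame into a voxel occupancy tensor
#'
#' Voxel `(i, j, k)` of channel `c` is 1 iff at least one atom of that
#' channel's entity/element class has its center inside the voxel cube.
#' Atoms outside the grid are ignored; an empty frame gives an all-zero
#' tensor.
#'
#' @param frame A centered `complex_frame`.
#' @param spec A [grid_spec()].
#' @param smooth_sd Optional Gaussian smoothing bandwidth in Angstrom.
#'   The default (0) gives binary presence occupancy; a positive value
#'   instead deposits, per atom, `exp(-d^2 / (2 * smooth_sd^2))` into every
#'   voxel center within `3 * smooth_sd` (values then exceed the binary
#'   range and are capped at 1).
#' @return A `grid_tensor`: numeric array of dimension
#'   `c(n_channels, edge, edge, edge)` with values in `[0, 1]` (binary in
#'   the default mode) and the spec attached as attribute `spec`.
#' @export
rasterize <- function(frame, spec = grid_spec(), smooth_sd = 0) {
  if (smooth_sd > 0) return(rasterize_smooth(frame, spec, smooth_sd))
  E <- spec$edge; s <- spec$spacing
  classes <- attr(spec$channels, "class_members") %||%
    attr(channel_scheme(), "class_members")
  vals <- array(0, dim = c(spec$n_channels, E, E, E))
  if (nrow(frame) > 0) {
    cls <- element_class(frame$element, classes)
    key <- paste(frame$entity, cls, sep = ".")
    chan_key <- paste(spec$channels$entity, spec$channels$class, sep = ".")
    chan <- match(key, chan_key)
    ix <- floor(frame$x / s + E / 2)
    iy <- floor(frame$y / s + E / 2)
    iz <- floor(frame$z / s + E / 2)
    keep <- !is.na(chan) & ix >= 0 & ix < E & iy >= 0 & iy < E &
      iz >= 0 & iz < E
    if (any(keep)) {
      lin <- chan[keep] + spec$n_channels *
        (ix[keep] + E * (iy[keep] + E * iz[keep]))
      vals[lin] <- 1
    }
  }
  structure(vals, spec = spec, class = "grid_tensor")
}

# Gaussian-density variant of rasterize(); capped at 1 per voxel.
rasterize_smooth <- function(frame, spec, smooth_sd) {
  E <- spec$edge; s <- spec$spacing
  classes <- attr(spec$channels, "class_members") %||%
    attr(channel_scheme(), "class_members")
  vals <- array(0, dim = c(spec$n_channels, E, E, E))
  if (nrow(frame) == 0) {
    return(structure(vals, spec = spec, class = "grid_tensor"))
  }
  cls <- element_class(frame$element, classes)
  chan <- match(paste(frame$entity, cls, sep = "."),
                paste(spec$channels$entity, spec$channels$class, sep = "."))
  reach <- 3 * smooth_sd / s
  for (a in seq_len(nrow(frame))) {
    if (is.na(chan[a])) next
    v <- c(frame$x[a], frame$y[a], frame$z[a]) / s + E / 2 - 0.5
    lo <- pmax(ceiling(v - reach), 0)
    hi <- pmin(floor(v + reach), E - 1)
    if (any(lo > hi)) next
    g <- as.matrix(expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2],
                               iz = lo[3]:hi[3]))
    d2 <- ((g[, 1] - v[1])^2 + (g[, 2] - v[2])^2 + (g[, 3] - v[3])^2) * s^2
    w <- exp(-d2 / (2 * smooth_sd^2))
    lin <- chan[a] + spec$n_channels * (g[, 1] + E * (g[, 2] + E * g[, 3]))
    vals[lin] <- pmin(vals[lin] + w, 1)
  }
  structure(vals, spec = spec, class = "grid_tensor")
}

# Flatten a grid tensor (or list of them) to a column matrix, channel
# fastest -- the layout the scoring network consumes.
grid_matrix <- function(grids) {
  if (inherits(grids, "grid_tensor")) grids <- list(grids)
  vapply(grids, as.numeric, numeric(length(grids[[1]])))
}

# Short fingerprint of a grid spec; models refuse mismatched inputs.
grid_fingerprint <- function(spec) {
  list(edge = spec$edge, spacing = spec$spacing,
       n_channels = spec$n_channels,
       scheme = paste(spec$channels$entity, spec$channels$class,
                      collapse = "|"))
}

#' Per-channel occupancy counts
#'
#' @param grid A `grid_tensor`.
#' @return Tibble with `channel` and `n_occupied`.
#' @export
channel_counts <- function(grid) {
  spec <- attr(grid, "spec")
  tibble(channel = seq_len(spec$n_channels),
         n_occupied = as.numeric(apply(grid, 1, sum)))
}
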