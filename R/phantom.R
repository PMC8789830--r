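# Synthetic vascular phantom: random-walk vessel tubes in a speckle-like
# static background, imaged as repeated frames in which flow voxels
# decorrelate between repeats while static tissue varies only by additive
# noise. This emulates the statistics that repeated-B-scan angiography
# relies on: an angiogram formed from more repeats has a less noisy flow
# estimate.

#' Phantom specification
#'
#' Parameters of the synthetic vascular volume and its repeated-frame
#' imaging model.
#'
#' @param grid_size integer vector `(X, Y, Z)`, each at least 8 voxels.
#' @param n_vessels number of vessel centerlines (random-walk tubes).
#' @param radius_range numeric `(min, max)` tube radius in voxels.
#' @param flow_decorrelation in `[0, 1]`: fraction of the flow signal
#'   resampled at each repeat (AR(1) with inter-repeat correlation
#'   `1 - flow_decorrelation`). 0 means frozen flow, 1 fully decorrelated.
#' @param static_noise_sigma additive Gaussian noise scale applied to every
#'   voxel at every repeat (the static-tissue decorrelation floor).
#' @param seed integer seed; the same spec always generates bit-identical
#'   volumes.
#' @return A list of class `octra_phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64L, 64L, 64L), n_vessels = 6L,
                         radius_range = c(1.5, 3), flow_decorrelation = 0.7,
                         static_noise_sigma = 0.02, seed = 1L) {
  grid_size <- as.integer(grid_size)
  stopifnot(length(grid_size) == 3L, all(grid_size >= 8L),
            n_vessels >= 0, length(radius_range) == 2L,
            radius_range[1] > 0, radius_range[2] >= radius_range[1],
            flow_decorrelation >= 0, flow_decorrelation <= 1,
            static_noise_sigma >= 0)
  structure(list(grid_size = grid_size, n_vessels = as.integer(n_vessels),
                 radius_range = as.numeric(radius_range),
                 flow_decorrelation = flow_decorrelation,
                 static_noise_sigma = static_noise_sigma,
                 seed = as.integer(seed)),
            class = "octra_phantom_spec")
}

# replicate-pad smoothing along one axis of a 3-d array with a short kernel
smooth_axis <- function(a, kernel, axis) {
  n <- dim(a)[axis]
  half <- (length(kernel) - 1L) %/% 2L
  out <- a * 0
  for (o in seq_along(kernel)) {
    off <- o - 1L - half
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[o] * switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
  }
  out
}

smooth3d <- function(a, sigma = 1) {
  k <- gauss_kernel1d(5L, sigma)
  for (ax in 1:3) a <- smooth_axis(a, k, ax)
  a
}

#' Generate a synthetic vessel volume
#'
#' Draws `n_vessels` correlated random-walk centerlines, dilates each to a
#' tube with a radius sampled from `radius_range`, and lays them over a
#' smoothed-noise static background. Deterministic given `spec$seed`.
#'
#' @param spec an [phantom_spec()].
#' @return A list with `vessel_mask` (logical `(X, Y, Z)` array) and
#'   `tissue_volume` (numeric array in `[0, 1]`).
#' @export
generate_vessel_volume <- function(spec) {
  stopifnot(inherits(spec, "octra_phantom_spec"))
  gs <- spec$grid_size
  if (any(gs < 2 * ceiling(spec$radius_range[1]) + 1)) {
    stop("grid ", paste(gs, collapse = "x"),
         " too small to contain a vessel of radius ", spec$radius_range[1])
  }
  withr::with_seed(spec$seed, {
    mask <- array(FALSE, dim = gs)
    for (v in seq_len(spec$n_vessels)) {
      rad <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      mask <- mask | random_walk_tube(gs, rad)
    }
    tissue <- smooth3d(array(stats::rnorm(prod(gs)), dim = gs), sigma = 1)
    tissue <- tissue / stats::sd(tissue)
    tissue <- pmin(pmax(0.35 + 0.08 * tissue, 0), 1)
    list(vessel_mask = mask, tissue_volume = tissue)
  })
}

# one correlated random-walk centerline dilated to a tube of radius `rad`
random_walk_tube <- function(gs, rad, turn = 0.35) {
  start <- stats::runif(3) * (gs - 1) + 1
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  n_steps <- 2L * max(gs)
  pts <- matrix(NA_real_, n_steps, 3)
  p <- start
  for (i in seq_len(n_steps)) {
    pts[i, ] <- p
    dir <- dir + turn * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    p <- p + dir
    if (any(p < 1) || any(p > gs)) break
  }
  pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
  dilate_centerline(pts, gs, rad)
}

# mark all voxels within `rad` of any centerline point
dilate_centerline <- function(pts, gs, rad) {
  mask <- array(FALSE, dim = gs)
  if (nrow(pts) == 0L) return(mask)
  r <- ceiling(rad)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= rad^2, , drop = FALSE]
  off <- as.matrix(off)
  ctr <- round(pts)
  for (i in seq_len(nrow(ctr))) {
    vox <- sweep(off, 2, ctr[i, ], `+`)
    keep <- vox[, 1] >= 1 & vox[, 1] <= gs[1] &
            vox[, 2] >= 1 & vox[, 2] <= gs[2] &
            vox[, 3] >= 1 & vox[, 3] <= gs[3]
    vox <- vox[keep, , drop = FALSE]
    mask[vox] <- TRUE
  }
  mask
}

#' Simulate repeated imaging frames of a phantom
#'
#' Static voxels vary across repeats only by additive Gaussian noise
#' (`spec$static_noise_sigma`); vessel voxels additionally carry a flow
#' component resampled each repeat as an AR(1) process with inter-repeat
#' correlation `1 - spec$flow_decorrelation`. Frames are clipped to
#' `[0, 1]`.
#'
#' @param vessel_mask,tissue_volume as returned by
#'   [generate_vessel_volume()]; must have identical dimensions.
#' @param n_repeats number of repeated frames (R >= 2).
#' @param spec the [phantom_spec()] that generated the volume.
#' @return A list of class `octra_series` with `frames`
#'   (`(R, X, Y, Z)` array in `[0, 1]`), `vessel_mask`, and `spec`.
#' @export
simulate_repeats <- function(vessel_mask, tissue_volume, n_repeats, spec) {
  stopifnot(inherits(spec, "octra_phantom_spec"), n_repeats >= 2)
  if (!identical(dim(vessel_mask), dim(tissue_volume))) {
    stop("vessel_mask and tissue_volume dimensions differ")
  }
  gs <- dim(tissue_volume)
  n_repeats <- as.integer(n_repeats)
  rho <- 1 - spec$flow_decorrelation
  nv <- sum(vessel_mask)
  v_level <- 0.35
  v_amp <- 0.15
  frames <- array(0, dim = c(n_repeats, gs))
  withr::with_seed(spec$seed + 1L, {
    flow <- if (nv > 0) stats::rnorm(nv) else numeric(0)
    base <- tissue_volume
    base[vessel_mask] <- base[vessel_mask] + v_level
    for (r in seq_len(n_repeats)) {
      if (r > 1 && nv > 0) {
        flow <- rho * flow + sqrt(1 - rho^2) * stats::rnorm(nv)
      }
      fr <- base
      if (nv > 0) fr[vessel_mask] <- fr[vessel_mask] + v_amp * flow
      if (spec$static_noise_sigma > 0) {
        fr <- fr + stats::rnorm(prod(gs), sd = spec$static_noise_sigma)
      }
      frames[r, , , ] <- pmin(pmax(fr, 0), 1)
    }
  })
  structure(list(frames = frames, vessel_mask = vessel_mask, spec = spec),
            class = "octra_series")
}

#' Generate a full phantom series in one call
#'
#' Convenience wrapper: [generate_vessel_volume()] followed by
#' [simulate_repeats()].
#'
#' @inheritParams generate_vessel_volume
#' @inheritParams simulate_repeats
#' @return An `octra_series`; see [simulate_repeats()].
#' @export
phantom_series <- function(spec, n_repeats = 8L) {
  vol <- generate_vessel_volume(spec)
  simulate_repeats(vol$vessel_mask, vol$tissue_volume, n_repeats, spec)
}

#' Build a synthetic supervised pair set
#'
#' Generates as many phantom volumes as needed (one per seed offset) and
#' collects their depth-slice training pairs until `n_pairs` are
#' available. Slices are filtered for vessel content so empty sections do
#' not dominate.
#'
#' @param n_pairs number of pairs to return.
#' @param size enface extent in pixels (square volumes of depth
#'   `size`).
#' @param r enface downsampling ratio.
#' @param seed base seed; volume `k` uses `seed + k`.
#' @param n_vessels vessels per volume.
#' @param min_vessel_fraction slice retention rule (see [make_pairs()]).
#' @return A list of `octra_pair` objects of length `n_pairs`.
#' @export
synthetic_pair_set <- function(n_pairs, size = 48L, r = 2L, seed = 1L,
                               n_vessels = 6L, min_vessel_fraction = 0.02) {
  pairs <- list()
  k <- 0L
  while (length(pairs) < n_pairs && k < 10L * ceiling(n_pairs / size)) {
    spec <- phantom_spec(grid_size = c(size, size, size),
                         n_vessels = n_vessels, seed = seed + k)
    series <- phantom_series(spec, n_repeats = 8L)
    pairs <- c(pairs, make_pairs(series, r, seed = seed + k,
                                 min_vessel_fraction = min_vessel_fraction))
    k <- k + 1L
  }
  if (length(pairs) < n_pairs) {
    stop("could not assemble ", n_pairs, " pairs with sufficient vessel ",
         "content")
  }
  pairs[seq_len(n_pairs)]
}
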