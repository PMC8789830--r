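# Angiogram formation from repeated frames, enface downsampling, training
# pair assembly, sectioning/MIP, dataset splitting and augmentation.
#
# Conventions: volumes are (X, Y, Z) with (X, Y) the enface plane (x fast
# axis, y slow axis) and z depth; repeated series are (R, X, Y, Z);
# indices reported to the user (depth_index, split indices) are 0-based.

#' Enface image container
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param kind `"sectioned"` (one depth slice) or `"mip"` (maximum
#'   intensity projection over depth).
#' @param depth_index 0-based depth index for sectioned images; `NULL` for
#'   MIP.
#' @return A list of class `octra_enface`.
#' @export
enface_image <- function(pixels, kind = c("sectioned", "mip"),
                         depth_index = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(pixels), min(pixels) >= 0, max(pixels) <= 1)
  if (kind == "mip" && !is.null(depth_index)) {
    stop("MIP images carry no depth_index")
  }
  structure(list(pixels = pixels, kind = kind, depth_index = depth_index),
            class = "octra_enface")
}

#' Form a decorrelation angiogram from repeated frames
#'
#' The flow estimate at each voxel is the mean absolute difference over
#' the `n_use - 1` adjacent frame pairs, min-max normalized to `[0, 1]`
#' per volume. An all-constant pre-normalization volume maps to all zeros
#' (zero-range rule). More repeats average more inter-frame samples, so
#' the estimate's dispersion shrinks with `n_use` — the property that
#' makes 8-repeat angiograms higher quality than 2-repeat ones.
#'
#' @param series an `octra_series` (or any list with a `(R, X, Y, Z)`
#'   `frames` array).
#' @param first_repeat 0-based index of the first repeat used.
#' @param n_use number of consecutive repeats used (>= 2).
#' @param normalize min-max normalize to `[0, 1]` (the default); with
#'   `FALSE` the raw mean-absolute-difference estimate is returned,
#'   useful for comparing estimator dispersion across repeat counts.
#' @return A list of class `octra_angiogram` with `values` (`(X, Y, Z)`
#'   array in `[0, 1]`), `n_repeats_used`, and `sampling_ratio` (1 for a
#'   fully-sampled series).
#' @export
compute_angiogram <- function(series, first_repeat = 0L, n_use = NULL,
                              normalize = TRUE) {
  fr <- series$frames
  R <- dim(fr)[1]
  if (is.null(n_use)) n_use <- R
  if (n_use < 2) stop("n_use must be >= 2: no inter-frame signal otherwise")
  if (first_repeat + n_use > R) {
    stop("first_repeat + n_use = ", first_repeat + n_use,
         " exceeds available repeats (", R, ")")
  }
  idx <- first_repeat + seq_len(n_use)
  acc <- 0
  for (i in seq_len(n_use - 1L)) {
    acc <- acc + abs(fr[idx[i + 1L], , , ] - fr[idx[i], , , ])
  }
  vals <- acc / (n_use - 1L)
  rng <- range(vals)
  if (normalize) {
    vals <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1]) else vals * 0
  }
  structure(list(values = vals, n_repeats_used = as.integer(n_use),
                 sampling_ratio = series$sampling_ratio %||% 1L,
                 raw_range = rng),
            class = "octra_angiogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Downsample the enface plane by strided subsampling
#'
#' Keeps every `r`-th sample along x and y (depth untouched), mimicking a
#' raster scan with an `r` times larger step size; samples are skipped,
#' not averaged. Works on an `octra_angiogram`, an `octra_series`, or a
#' plain 3-d array.
#'
#' @param vol volume to downsample.
#' @param r integer ratio >= 1; the enface dimensions must be divisible by
#'   `r` (no implicit cropping).
#' @return Same type as the input with enface dimensions divided by `r`.
#' @export
downsample_enface <- function(vol, r) {
  r <- as.integer(r)
  stopifnot(r >= 1)
  if (r == 1L) return(vol)
  if (inherits(vol, "octra_series")) {
    d <- dim(vol$frames)
    check_divisible(d[2], d[3], r)
    keep_x <- seq(1L, d[2], by = r)
    keep_y <- seq(1L, d[3], by = r)
    out <- vol
    out$frames <- vol$frames[, keep_x, keep_y, , drop = FALSE]
    if (!is.null(out$vessel_mask)) {
      out$vessel_mask <- out$vessel_mask[keep_x, keep_y, , drop = FALSE]
    }
    out$sampling_ratio <- (vol$sampling_ratio %||% 1L) * r
    return(out)
  }
  vals <- if (inherits(vol, "octra_angiogram")) vol$values else vol
  d <- dim(vals)
  check_divisible(d[1], d[2], r)
  sub <- vals[seq(1L, d[1], by = r), seq(1L, d[2], by = r), , drop = FALSE]
  if (inherits(vol, "octra_angiogram")) {
    vol$values <- sub
    vol$sampling_ratio <- vol$sampling_ratio * r
    return(vol)
  }
  sub
}

check_divisible <- function(nx, ny, r) {
  if (nx %% r != 0L || ny %% r != 0L) {
    stop("enface dimensions ", nx, "x", ny, " not divisible by ratio ", r)
  }
}

#' Build supervised training pairs from a repeated series
#'
#' The high-resolution, high-quality target (`hr_hq`) is the angiogram
#' from all 8 repeats of the fully-sampled series; the high-resolution,
#' low-quality intermediate (`hr_lq`) comes from one uniformly chosen
#' adjacent repeat pair `(i, i+1)`; the network input (`lr_lq`) is the
#' same repeat pair of the `r`-times enface-downsampled series. One pair
#' is emitted per retained depth slice.
#'
#' @param series an `octra_series` with at least 8 repeats.
#' @param r enface downsampling ratio.
#' @param seed integer seed for the repeat-pair selection.
#' @param min_vessel_fraction,threshold slice-retention rule passed to
#'   [section_and_filter()] applied to the `hr_hq` volume; the default
#'   keeps every slice.
#' @return A list of `octra_pair` objects, each with `lr_lq`, `hr_lq`,
#'   `hr_hq` ([enface_image()] objects), `ratio` and `depth_index`.
#' @export
make_pairs <- function(series, r, seed = 1L, min_vessel_fraction = 0,
                       threshold = 0.2) {
  R <- dim(series$frames)[1]
  if (R < 8L) stop("pair construction requires at least 8 repeats; got ", R)
  hr_hq <- compute_angiogram(series, 0L, 8L)
  lr_series <- downsample_enface(series, r)
  pair_start <- withr::with_seed(seed, sample.int(7L, 1L)) - 1L
  hr_lq <- compute_angiogram(series, pair_start, 2L)
  lr_lq <- compute_angiogram(lr_series, pair_start, 2L)
  kept <- section_and_filter(hr_hq, min_vessel_fraction, threshold)
  lapply(kept, function(img) {
    z <- img$depth_index + 1L
    structure(list(
      lr_lq = enface_image(lr_lq$values[, , z], "sectioned", img$depth_index),
      hr_lq = enface_image(hr_lq$values[, , z], "sectioned", img$depth_index),
      hr_hq = img,
      ratio = as.integer(r),
      depth_index = img$depth_index
    ), class = "octra_pair")
  })
}

#' Maximum intensity projection over a depth range
#'
#' @param vol an `octra_angiogram` or 3-d array.
#' @param depth_range 0-based inclusive `(from, to)` depth indices;
#'   defaults to the full depth.
#' @return An [enface_image()] of kind `"mip"`.
#' @export
mip <- function(vol, depth_range = NULL) {
  vals <- if (inherits(vol, "octra_angiogram")) vol$values else vol
  nz <- dim(vals)[3]
  if (is.null(depth_range)) depth_range <- c(0L, nz - 1L)
  if (length(depth_range) != 2L || depth_range[1] > depth_range[2]) {
    stop("empty depth range")
  }
  if (depth_range[1] < 0 || depth_range[2] >= nz) {
    stop("depth range outside [0, ", nz - 1L, "]")
  }
  zidx <- (depth_range[1]:depth_range[2]) + 1L
  px <- apply(vals[, , zidx, drop = FALSE], c(1, 2), max)
  enface_image(px, "mip")
}

#' Section a volume into depth slices with sufficient vessel content
#'
#' Keeps depth slices whose fraction of pixels above `threshold` is at
#' least `min_vessel_fraction` — an automated stand-in for manual
#' selection of slices with sufficient vessel profiles.
#'
#' @param vol an `octra_angiogram` or 3-d array.
#' @param min_vessel_fraction required fraction in `[0, 1]`; 0 keeps all.
#' @param threshold intensity above which a pixel counts as vessel.
#' @return A list of [enface_image()] objects (possibly empty), each with
#'   its 0-based `depth_index`.
#' @export
section_and_filter <- function(vol, min_vessel_fraction = 0,
                               threshold = 0.2) {
  stopifnot(min_vessel_fraction >= 0, min_vessel_fraction <= 1)
  vals <- if (inherits(vol, "octra_angiogram")) vol$values else vol
  d <- dim(vals)
  out <- list()
  for (z in seq_len(d[3])) {
    sl <- vals[, , z]
    if (mean(sl > threshold) >= min_vessel_fraction) {
      out[[length(out) + 1L]] <- enface_image(sl, "sectioned", z - 1L)
    }
  }
  out
}

#' Split image indices into training and validation sets
#'
#' Seeded shuffle followed by a `round(n * a / (a + b))` cut for ratio
#' `(a, b)`; the split is disjoint and exhaustive. With the study's 9:1
#' ratio, 2000 images split into 1800 and 200.
#'
#' @param n number of images (>= 2).
#' @param ratio positive `(train, val)` weights, default `c(9, 1)`.
#' @param seed integer seed.
#' @return A list with 0-based `train` and `val` index vectors.
#' @export
split_dataset <- function(n, ratio = c(9, 1), seed = 1L) {
  stopifnot(n >= 2, length(ratio) == 2L, all(ratio > 0))
  n_train <- round(n * ratio[1] / sum(ratio))
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- withr::with_seed(seed, sample.int(n)) - 1L
  list(train = perm[seq_len(n_train)], val = perm[(n_train + 1L):n])
}

#' Dihedral augmentation of a square enface image
#'
#' Applies one element of the 8-element group generated by 90-degree
#' rotations and axis flips. Rotations are restricted to multiples of 90
#' degrees so ground truth is never interpolated.
#'
#' @param img an [enface_image()] or square matrix.
#' @param seed seed for the uniformly chosen group element, or use
#'   `element` directly.
#' @param element integer 0..7 (`rotations + 4 * flip`); overrides `seed`.
#' @return Same type as the input, with the transform applied.
#' @export
augment <- function(img, seed = 1L, element = NULL) {
  px <- if (inherits(img, "octra_enface")) img$pixels else img
  if (nrow(px) != ncol(px)) {
    stop("augmentation requires a square image (rotation changes shape)")
  }
  if (is.null(element)) {
    element <- withr::with_seed(seed, sample.int(8L, 1L)) - 1L
  }
  stopifnot(element %in% 0:7)
  out <- apply_dihedral(px, element)
  if (inherits(img, "octra_enface")) {
    img$pixels <- out
    img
  } else out
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_dihedral <- function(m, element) {
  k <- element %% 4L
  flip <- element %/% 4L
  if (flip == 1L) m <- m[nrow(m):1, , drop = FALSE]
  for (i in seq_len(k)) m <- rot90cw(m)
  m
}

# inverse element of the dihedral action as composed in apply_dihedral
dihedral_inverse <- function(element) {
  for (e in 0:7) {
    probe <- matrix(seq_len(9), 3)
    if (identical(apply_dihedral(apply_dihedral(probe, element), e), probe)) {
      return(e)
    }
  }
  stop("unreachable")
}

#' Augment all three images of a training pair consistently
#'
#' @param pair an `octra_pair`.
#' @param seed,element as in [augment()].
#' @return The pair with the same group element applied to `lr_lq`,
#'   `hr_lq` and `hr_hq`.
#' @export
augment_pair <- function(pair, seed = 1L, element = NULL) {
  if (is.null(element)) {
    element <- withr::with_seed(seed, sample.int(8L, 1L)) - 1L
  }
  for (f in c("lr_lq", "hr_lq", "hr_hq")) {
    pair[[f]] <- augment(pair[[f]], element = element)
  }
  pair
}
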