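# Evaluation suite: image-reconstruction indices (SSIM, MS-SSIM, PSNR),
# angiogram-quality measures (RMS contrast, skeleton-based vessel
# connectivity) and the acquisition-time speed-up model.

as_pixels <- function(x) {
  if (inherits(x, "octra_enface")) x$pixels else x
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical images (MSE 0)
#' yield `Inf` with a warning; [evaluate_pairs()] excludes such values
#' from summary means.
#'
#' @param y,yhat images of identical shape.
#' @param data_range dynamic range (1 for `[0, 1]` angiograms).
#' @return PSNR in dB.
#' @export
psnr <- function(y, yhat, data_range = 1) {
  y <- as_pixels(y); yhat <- as_pixels(yhat)
  check_same_shape(y, yhat)
  mse <- mean((y - yhat)^2)
  if (mse == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5),
#' stabilizers `C1 = (0.01)^2`, `C2 = (0.03)^2` for unit dynamic range,
#' averaged over the valid filter region.
#'
#' @inheritParams psnr
#' @param window odd Gaussian window size.
#' @param sigma Gaussian window standard deviation.
#' @return Index `<= 1`, equal to 1 iff the images are identical.
#' @export
ssim <- function(y, yhat, window = 11L, sigma = 1.5) {
  y <- as_pixels(y); yhat <- as_pixels(yhat)
  check_same_shape(y, yhat)
  ag_with_graph(ag_value(ag_ssim(ag_const(as_tensor4(y)),
                                 ag_const(as_tensor4(yhat)),
                                 win = window, sigma = sigma)))
}

#' Multiscale structural similarity index
#'
#' @inheritParams ssim
#' @param scales number of dyadic scales (max 5); errors if the image is
#'   too small, naming the feasible maximum.
#' @return Index `<= 1`, equal to 1 iff identical.
#' @export
ms_ssim <- function(y, yhat, scales = 5L, window = 11L, sigma = 1.5) {
  y <- as_pixels(y); yhat <- as_pixels(yhat)
  check_same_shape(y, yhat)
  ag_with_graph(ag_value(ag_msssim(ag_const(as_tensor4(y)),
                                   ag_const(as_tensor4(yhat)),
                                   scales = scales, win = window,
                                   sigma = sigma)))
}

#' Root-mean-square contrast
#'
#' Population standard deviation of the pixel intensities.
#'
#' @param img image (matrix or enface image).
#' @return Non-negative scalar; 0 for a constant image.
#' @export
rms_contrast <- function(img) {
  px <- as_pixels(img)
  sqrt(mean((px - mean(px))^2))
}

## ---- skeleton-based vessel connectivity --------------------------------

# Zhang-Suen topological thinning of a logical matrix
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask * 1L
  pad <- function(a) {
    out <- matrix(0L, nrow(a) + 2L, ncol(a) + 2L)
    out[2:(nrow(a) + 1L), 2:(ncol(a) + 1L)] <- a
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      # 8-neighborhood in the conventional clockwise order P2..P9
      p2 <- p[ri - 1L, ci]; p3 <- p[ri - 1L, ci + 1L]; p4 <- p[ri, ci + 1L]
      p5 <- p[ri + 1L, ci + 1L]; p6 <- p[ri + 1L, ci]; p7 <- p[ri + 1L, ci - 1L]
      p8 <- p[ri, ci - 1L]; p9 <- p[ri - 1L, ci - 1L]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0L
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L
      if (step == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-connected component sizes of a logical matrix, via a pixel-adjacency
# graph (EBImage's labeling is 4-connected, which merges fewer pixels
# than the metric definition requires)
component_sizes8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(integer(0))
  nr <- nrow(mask)
  rc <- arrayInd(idx, dim(mask))
  id <- integer(length(mask))
  id[idx] <- seq_along(idx)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nb <- cbind(rc[, 1] + off[1], rc[, 2] + off[2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= ncol(mask)
    nbi <- id[(nb[ok, 2] - 1L) * nr + nb[ok, 1]]
    has <- nbi > 0L
    edges <- rbind(edges, cbind(which(ok)[has], nbi[has]))
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(idx),
                                                      seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)
  tabulate(comp$membership, comp$no)
}

#' Skeleton-based vessel connectivity
#'
#' Binarizes the angiogram, thins the foreground to a one-pixel skeleton
#' (Zhang-Suen), labels 8-connected skeleton components and reports the
#' fraction of skeleton pixels belonging to components of at least
#' `min_component` pixels. Isolated specks therefore lower the score.
#'
#' @param img image (matrix or enface image) in `[0, 1]`.
#' @param binarize `"otsu"` for an Otsu threshold, or a numeric threshold
#'   in (0, 1).
#' @param min_component minimum component size counted as connected.
#' @return Proportion in `[0, 1]`, or `NA` (with a warning) when the
#'   binarized foreground is empty.
#' @export
vessel_connectivity <- function(img, binarize = "otsu", min_component = 5L) {
  px <- as_pixels(img)
  thr <- if (identical(binarize, "otsu")) {
    EBImage::otsu(px, range = c(0, 1))
  } else {
    stopifnot(is.numeric(binarize), length(binarize) == 1L)
    binarize
  }
  fg <- px > thr
  if (!any(fg)) {
    warning("empty foreground after binarization: connectivity undefined")
    return(NA_real_)
  }
  sk <- skeletonize(fg)
  if (!any(sk)) {
    warning("empty skeleton: connectivity undefined")
    return(NA_real_)
  }
  sizes <- component_sizes8(sk)
  comp_px <- sum(sizes[sizes >= min_component])
  comp_px / sum(sizes)
}

## ---- evaluation harness ------------------------------------------------

#' Evaluate reconstruction methods over a set of pairs
#'
#' Computes SSIM, MS-SSIM, PSNR, RMS contrast and vessel connectivity for
#' every method on every pair (ground truth: `hr_hq`), and aggregates
#' mean and standard deviation per method. Infinite PSNR and undefined
#' connectivity values are excluded from the summaries.
#'
#' @param pairs list of `octra_pair` objects.
#' @param G optional trained `octra_generator`, evaluated as method
#'   `"generator"`.
#' @param baselines character vector of interpolation baselines from
#'   [interpolate_upsample()] (`"nearest"`, `"bicubic"`, `"lanczos"`).
#' @param bilateral if `TRUE`, adds `"bicubic+bilateral"` (bilateral
#'   filtering of the bicubic result).
#' @param msssim_scales scales for MS-SSIM (reduced automatically to the
#'   feasible maximum for the pair size).
#' @param connectivity compute the (comparatively slow) vessel
#'   connectivity metric.
#' @return A list of class `octra_metrics_report` with `per_image` (long
#'   data frame) and `summary` (mean and sd per method and metric).
#' @export
evaluate_pairs <- function(pairs, G = NULL,
                           baselines = c("nearest", "bicubic", "lanczos"),
                           bilateral = FALSE, msssim_scales = 5L,
                           connectivity = TRUE) {
  stopifnot(length(pairs) >= 1L)
  d <- dim(pairs[[1]]$hr_hq$pixels)
  msssim_scales <- min(msssim_scales, msssim_max_scales(d[1], d[2]))
  methods <- character(0)
  if (!is.null(G)) methods <- "generator"
  methods <- c(methods, baselines)
  if (bilateral) methods <- c(methods, "bicubic+bilateral")
  rows <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    truth <- p$hr_hq$pixels
    r <- p$ratio
    for (m in methods) {
      rec <- switch(m,
        generator = as_pixels(reconstruct(p$lr_lq, G)),
        `bicubic+bilateral` = as_pixels(bilateral_filter(
          interpolate_upsample(p$lr_lq, r, "bicubic"))),
        as_pixels(interpolate_upsample(p$lr_lq, r, m)))
      conn <- if (connectivity) {
        suppressWarnings(vessel_connectivity(rec))
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        image = i - 1L, method = m,
        ssim = ssim(truth, rec),
        ms_ssim = ms_ssim(truth, rec, scales = msssim_scales),
        psnr_db = suppressWarnings(psnr(truth, rec)),
        rms_contrast = rms_contrast(rec),
        connectivity = conn)
    }
  }
  per_image <- do.call(rbind, rows)
  agg <- function(v) {
    v <- v[is.finite(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }
  summ <- do.call(rbind, lapply(split(per_image, per_image$method),
    function(df) {
      out <- data.frame(method = df$method[1])
      for (met in c("ssim", "ms_ssim", "psnr_db", "rms_contrast",
                    "connectivity")) {
        a <- agg(df[[met]])
        out[[paste0(met, "_mean")]] <- a["mean"]
        out[[paste0(met, "_sd")]] <- a["sd"]
      }
      out
    }))
  rownames(summ) <- NULL
  structure(list(per_image = per_image, summary = summ),
            class = "octra_metrics_report")
}

## ---- acquisition-time model --------------------------------------------

#' Acquisition-time model
#'
#' Protocol constants of the fully-sampled, 8-repeat acquisition: 10 um
#' scanning step, 8 repeated B-scans, mean volume acquisition time
#' 17.8 s, 400 x 400 enface points.
#'
#' @param base_step_um fully-sampled scanning step size in micrometers.
#' @param base_repeats B-scan repeats of the high-quality protocol.
#' @param base_time_s mean acquisition time of that protocol in seconds.
#' @param enface_points `(x, y)` sample counts of the enface plane.
#' @return A list of class `octra_acquisition_model`.
#' @export
acquisition_model <- function(base_step_um = 10, base_repeats = 8L,
                              base_time_s = 17.8,
                              enface_points = c(400L, 400L)) {
  stopifnot(base_step_um > 0, base_repeats >= 1, base_time_s > 0,
            all(enface_points > 0))
  structure(list(base_step_um = base_step_um,
                 base_repeats = as.integer(base_repeats),
                 base_time_s = base_time_s,
                 enface_points = as.integer(enface_points)),
            class = "octra_acquisition_model")
}

#' Acquisition speed-up of an undersampled protocol
#'
#' Undersampling both enface axes by `r` visits `r^2` times fewer
#' positions and using `n_repeats` of the `base_repeats` B-scans saves a
#' further linear factor: `speedup = r^2 * base_repeats / n_repeats`.
#' With the default model, `(r = 2, n = 2)` gives 16x and about 1.1 s;
#' `(4, 2)` gives 64x and 0.28 s; `(8, 2)` gives 256x and 0.07 s.
#'
#' @param model an [acquisition_model()].
#' @param r enface downsampling ratio (>= 1).
#' @param n_repeats B-scan repeats used (1..`base_repeats`).
#' @return A list with `speedup` and `time_s` (seconds, 2 significant
#'   figures).
#' @export
acquisition_speedup <- function(model = acquisition_model(), r, n_repeats) {
  stopifnot(r >= 1, n_repeats >= 1, n_repeats <= model$base_repeats)
  speedup <- r^2 * model$base_repeats / n_repeats
  t <- model$base_time_s / speedup
  # two significant figures, but never fewer digits than the integer part
  list(speedup = speedup,
       time_s = signif(t, max(2, ceiling(log10(t)) + 1)))
}

#' Equivalent scanning step size of a downsampling ratio
#'
#' @inheritParams acquisition_speedup
#' @return Step size in micrometers (`base_step_um * r`).
#' @export
equivalent_step_size <- function(model = acquisition_model(), r) {
  stopifnot(r >= 1)
  model$base_step_um * r
}
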