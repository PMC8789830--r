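# Interpolation-based reconstruction baselines and the bilateral filter.
#
# Alignment follows the sample-grid ("corner-pixel") convention of the
# strided downsampling: LR pixel (i, j) sits at HR position (r*i, r*j)
# (0-based), so nearest/bicubic/Lanczos upsampling followed by strided
# downsampling returns the input exactly.

# 1-D interpolation weight matrix mapping n_in samples to n_out = r * n_in
# output positions at source coordinates u / r, with replicate boundaries
interp_matrix <- function(n_in, r, method) {
  kern <- switch(method,
    # half-open tie break so that each LR pixel replicates into an r x r block
    nearest = list(f = function(t) as.numeric(t > -0.5 & t <= 0.5), support = 1),
    bicubic = list(f = keys_cubic, support = 2),
    lanczos = list(f = lanczos3, support = 3),
    stop("unknown interpolation method: ", method))
  n_out <- r * n_in
  W <- matrix(0, n_out, n_in)
  for (u in seq_len(n_out) - 1L) {
    x <- u / r
    lo <- floor(x) - kern$support + 1L
    hi <- floor(x) + kern$support
    js <- lo:hi
    w <- kern$f(x - js)
    if (sum(w) != 0) w <- w / sum(w)
    js <- pmin(pmax(js, 0L), n_in - 1L)   # replicate boundary
    for (k in seq_along(js)) {
      W[u + 1L, js[k] + 1L] <- W[u + 1L, js[k] + 1L] + w[k]
    }
  }
  W
}

# Keys cubic convolution kernel, a = -0.5 (reproduces linear ramps)
keys_cubic <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

lanczos3 <- function(t, a = 3) {
  out <- ifelse(abs(t) < a, sinc(t) * sinc(t / a), 0)
  out[t == 0] <- 1
  out
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Interpolation-based enface upsampling
#'
#' Separable kernel interpolation (nearest-neighbor, Keys bicubic, or
#' Lanczos-3) on the sample grid, aligned so that retained low-resolution
#' samples map back to their original high-resolution positions under the
#' strided-downsampling convention of [downsample_enface()]. Output is
#' clipped to `[0, 1]`.
#'
#' @param img low-resolution image (matrix or [enface_image()]).
#' @param r integer upsampling ratio (>= 1; 1 is the identity).
#' @param method `"nearest"`, `"bicubic"` or `"lanczos"`.
#' @return Image of `r` times the input size, same container type.
#' @export
interpolate_upsample <- function(img, r, method = c("nearest", "bicubic",
                                                    "lanczos")) {
  method <- match.arg(method)
  r <- as.integer(r)
  stopifnot(r >= 1)
  px <- as_pixels(img)
  if (r > 1L) {
    Wr <- interp_matrix(nrow(px), r, method)
    Wc <- interp_matrix(ncol(px), r, method)
    px <- pmin(pmax(Wr %*% px %*% t(Wc), 0), 1)
  }
  if (inherits(img, "octra_enface")) {
    enface_image(px, img$kind, img$depth_index)
  } else px
}

#' Bilateral filter
#'
#' Edge-preserving weighted mean with Gaussian spatial and range kernels;
#' used to enhance interpolation baselines before comparison. The window
#' radius is `ceiling(3 * sigma_spatial)` unless given. Output values are
#' convex combinations of input values, so shape and range are preserved.
#'
#' @param img image in `[0, 1]` (matrix or [enface_image()]).
#' @param sigma_spatial spatial Gaussian scale in pixels.
#' @param sigma_range intensity Gaussian scale.
#' @param radius window radius in pixels.
#' @return Filtered image, same container type and shape.
#' @export
bilateral_filter <- function(img, sigma_spatial = 3, sigma_range = 0.1,
                             radius = NULL) {
  stopifnot(sigma_spatial > 0, sigma_range > 0)
  px <- as_pixels(img)
  if (is.null(radius)) radius <- ceiling(3 * sigma_spatial)
  nr <- nrow(px); nc <- ncol(px)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  ridx <- seq_len(nr)
  cidx <- seq_len(nc)
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      ws <- exp(-(di^2 + dj^2) / (2 * sigma_spatial^2))
      if (ws < 1e-12) next
      shifted <- px[pmin(pmax(ridx + di, 1L), nr),
                    pmin(pmax(cidx + dj, 1L), nc)]
      wr <- exp(-(shifted - px)^2 / (2 * sigma_range^2))
      w <- ws * wr
      num <- num + w * shifted
      den <- den + w
    }
  }
  out <- num / den
  if (inherits(img, "octra_enface")) {
    enface_image(out, img$kind, img$depth_index)
  } else out
}
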