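# Structural-similarity graph builders shared by the loss functions
# (differentiable, used in training) and the evaluation metrics.
#
# Filtering follows the standard formulation: an 11x11 Gaussian window
# (sigma 1.5) applied as a *valid* convolution, so the similarity map is
# the interior region only; statistics use the weighted (population)
# moments. Constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 with L = 1 for
# [0,1] images.

gauss_kernel1d <- function(size, sigma) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian valid filtering of an (H, W, 1, N) node
ag_gauss_filter <- function(x, win = 11L, sigma = 1.5) {
  k <- gauss_kernel1d(win, sigma)
  kv <- array(k, dim = c(win, 1L, 1L, 1L))
  kh <- array(k, dim = c(1L, win, 1L, 1L))
  x <- ag_conv2d(x, ag_const(kv), b = NULL, stride = 1L, pad = 0L)
  ag_conv2d(x, ag_const(kh), b = NULL, stride = 1L, pad = 0L)
}

# mean luminance term and contrast-structure term of SSIM; returns a list
# of scalar nodes (means over the valid map): list(l_cs = mean(l*cs),
# cs = mean(cs))
ag_ssim_terms <- function(x, y, win = 11L, sigma = 1.5,
                          c1 = 0.01^2, c2 = 0.03^2) {
  mx <- ag_gauss_filter(x, win, sigma)
  my <- ag_gauss_filter(y, win, sigma)
  mxx <- ag_gauss_filter(ag_mul(x, x), win, sigma)
  myy <- ag_gauss_filter(ag_mul(y, y), win, sigma)
  mxy <- ag_gauss_filter(ag_mul(x, y), win, sigma)
  vx <- ag_sub(mxx, ag_mul(mx, mx))
  vy <- ag_sub(myy, ag_mul(my, my))
  cxy <- ag_sub(mxy, ag_mul(mx, my))
  l_num <- ag_add(ag_scale(ag_mul(mx, my), 2), c1)
  l_den <- ag_add(ag_add(ag_mul(mx, mx), ag_mul(my, my)), c1)
  cs_num <- ag_add(ag_scale(cxy, 2), c2)
  cs_den <- ag_add(ag_add(vx, vy), c2)
  l <- ag_div(l_num, l_den)
  cs <- ag_div(cs_num, cs_den)
  list(l_cs = ag_mean(ag_mul(l, cs)), cs = ag_mean(cs))
}

# single-scale mean SSIM node
ag_ssim <- function(x, y, win = 11L, sigma = 1.5) {
  d <- dim(x$value)
  if (d[1] < win || d[2] < win) {
    stop("image (", d[1], "x", d[2], ") smaller than the ", win, "x", win,
         " SSIM window")
  }
  ag_ssim_terms(x, y, win, sigma)$l_cs
}

# standard multiscale exponents (5 scales); with fewer scales the leading
# exponents are renormalized to sum to one
msssim_weights <- function(scales) {
  w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (scales > length(w)) stop("at most ", length(w), " scales supported")
  w <- w[seq_len(scales)]
  w / sum(w)
}

# largest number of dyadic scales at which the window still fits
msssim_max_scales <- function(h, w, win = 11L) {
  s <- 0L
  while (min(h, w) >= win && s < 5L) {
    s <- s + 1L
    h <- h %/% 2L
    w <- w %/% 2L
  }
  s
}

# multiscale SSIM node: contrast-structure at every scale, luminance at
# the coarsest; 2x2 mean pooling between scales
ag_msssim <- function(x, y, scales = 5L, win = 11L, sigma = 1.5,
                      eps = 1e-6) {
  d <- dim(x$value)
  feasible <- msssim_max_scales(d[1], d[2], win)
  if (scales > feasible) {
    stop("image (", d[1], "x", d[2], ") supports at most ", feasible,
         " MS-SSIM scale(s) with a ", win, "x", win, " window; got ", scales)
  }
  w <- msssim_weights(scales)
  out <- NULL
  for (j in seq_len(scales)) {
    terms <- ag_ssim_terms(x, y, win, sigma)
    mj <- if (j == scales) terms$l_cs else terms$cs
    fj <- ag_pow(ag_clamp_min(mj, eps), w[j])
    out <- if (is.null(out)) fj else ag_mul(out, fj)
    if (j < scales) {
      x <- ag_avg_pool2(ag_crop_even(x))
      y <- ag_avg_pool2(ag_crop_even(y))
    }
  }
  out
}
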