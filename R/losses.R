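# Composite perceptual loss: MAE + 0.8 * (1 - MS-SSIM) + 7e-5 * Fourier-MAE,
# plus the adversarial objectives used in the GAN stage.

#' Loss configuration
#'
#' Weights and MS-SSIM settings for the composite training loss. The
#' defaults are the published weighting: the mean-absolute-error term has
#' unit weight, the multiscale-SSIM term weight 0.8, the Fourier-magnitude
#' MAE term weight 7e-5, and the adversarial term (GAN stage only) weight
#' 5e-3.
#'
#' @param w_msssim weight of the `1 - MS-SSIM` term.
#' @param w_fmae weight of the Fourier-magnitude MAE term.
#' @param w_adv weight of the `-log D(G(X))` adversarial term.
#' @param msssim_scales number of dyadic scales for MS-SSIM (max 5).
#'   Small images support fewer scales; see [msssim_loss()].
#' @param msssim_window odd Gaussian window size for (MS-)SSIM.
#' @return A list of class `octra_loss_config`.
#' @export
loss_config <- function(w_msssim = 0.8, w_fmae = 7e-5, w_adv = 5e-3,
                        msssim_scales = 5L, msssim_window = 11L) {
  stopifnot(w_msssim >= 0, w_fmae >= 0, w_adv >= 0,
            msssim_scales >= 1, msssim_window %% 2 == 1)
  structure(list(w_msssim = w_msssim, w_fmae = w_fmae, w_adv = w_adv,
                 msssim_scales = as.integer(msssim_scales),
                 msssim_window = as.integer(msssim_window)),
            class = "octra_loss_config")
}

# accept an enface image, a matrix, or an (H, W, N) stack; return 4-d tensor
as_tensor4 <- function(x) {
  if (inherits(x, "octra_enface")) x <- x$pixels
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array image")
  # internal layout is (H, W, N, C); single-channel images throughout
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d[1], d[2], d[3], 1L)
  else if (length(d) != 4L) stop("expected a 2-d, 3-d or 4-d image array")
  x
}

check_same_shape <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat))) {
    stop("shape mismatch: ", paste(dim(y), collapse = "x"), " vs ",
         paste(dim(yhat), collapse = "x"))
  }
}

## ---- node builders (used by the training loop) ------------------------

ag_mae <- function(y, yhat) ag_mean(ag_abs(ag_sub(y, yhat)))

ag_msssim_loss <- function(y, yhat, cfg) {
  ag_sub(1, ag_msssim(y, yhat, scales = cfg$msssim_scales,
                      win = cfg$msssim_window))
}

ag_combined_loss <- function(y, yhat, cfg) {
  out <- ag_mae(y, yhat)
  if (cfg$w_msssim > 0) {
    out <- ag_add(out, ag_scale(ag_msssim_loss(y, yhat, cfg), cfg$w_msssim))
  }
  if (cfg$w_fmae > 0) {
    out <- ag_add(out, ag_scale(ag_fmae_vs(y, yhat), cfg$w_fmae))
  }
  out
}

# evaluate a node-builder on plain arrays inside a throwaway graph
eval_loss <- function(builder, y, yhat, ...) {
  y <- as_tensor4(y)
  yhat <- as_tensor4(yhat)
  check_same_shape(y, yhat)
  ag_with_graph(ag_value(builder(ag_const(y), ag_const(yhat), ...)))
}

## ---- public scalar losses ---------------------------------------------

#' Mean absolute error between two angiograms
#'
#' @param y,yhat images (matrices in `[0,1]`, [enface_image()] objects, or
#'   image stacks of identical shape).
#' @return Non-negative scalar; 0 iff the images are identical.
#' @export
mae_loss <- function(y, yhat) eval_loss(ag_mae, y, yhat)

#' Multiscale-SSIM loss
#'
#' `1 - MSSSIM(y, yhat)` with contrast-structure terms on every dyadic
#' scale and the luminance term at the coarsest, standard exponents
#' (renormalized when fewer than 5 scales are used). Errors if the image
#' cannot accommodate the requested number of scales, naming the feasible
#' maximum.
#'
#' @inheritParams mae_loss
#' @param cfg an [loss_config()]; `msssim_scales` and `msssim_window` are
#'   used.
#' @return Scalar in `[0, 1]` for images in `[0, 1]`; 0 for identical images.
#' @export
msssim_loss <- function(y, yhat, cfg = loss_config()) {
  eval_loss(ag_msssim_loss, y, yhat, cfg = cfg)
}

#' Fourier-magnitude MAE loss
#'
#' Mean absolute difference between the magnitudes of the two images'
#' unnormalized, unshifted 2-D discrete Fourier transforms, divided by the
#' pixel count once. Invariant to circular translation of either image.
#'
#' @inheritParams mae_loss
#' @return Non-negative scalar; 0 for identical images.
#' @export
fmae_loss <- function(y, yhat) eval_loss(ag_fmae_vs, y, yhat)

#' Combined perceptual loss
#'
#' `MAE + w_msssim * (1 - MS-SSIM) + w_fmae * FMAE` with published default
#' weights 0.8 and 7e-5.
#'
#' @inheritParams msssim_loss
#' @return Non-negative scalar; 0 for identical images.
#' @export
combined_loss <- function(y, yhat, cfg = loss_config()) {
  eval_loss(ag_combined_loss, y, yhat, cfg = cfg)
}

.check_prob <- function(p, what) {
  if (any(p <= 0 | p >= 1)) {
    stop(what, " must lie strictly in (0, 1); got ",
         paste(signif(range(p), 4), collapse = "..."))
  }
}

#' Generator adversarial loss
#'
#' The combined perceptual loss plus `w_adv * (-log D(G(X)))` with the
#' published weight 5e-3. A stability epsilon of 1e-8 is applied inside
#' the logarithm.
#'
#' @inheritParams msssim_loss
#' @param d_out discriminator probability/ies for the reconstructed
#'   image(s), strictly in (0, 1).
#' @return Scalar loss.
#' @export
generator_adv_loss <- function(y, yhat, d_out, cfg = loss_config()) {
  .check_prob(d_out, "d_out")
  combined_loss(y, yhat, cfg) + cfg$w_adv * mean(-log(d_out + 1e-8))
}

#' Discriminator loss
#'
#' Negated inner objective of the adversarial min-max problem:
#' `-[log d_real + log(1 - d_fake)]`, averaged over the batch.
#'
#' @param d_real,d_fake discriminator probabilities for real and
#'   reconstructed images, strictly in (0, 1).
#' @return Non-negative scalar; approaches 0 as `d_real -> 1`,
#'   `d_fake -> 0`.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  .check_prob(d_real, "d_real")
  .check_prob(d_fake, "d_fake")
  -mean(log(d_real + 1e-8)) - mean(log(1 - d_fake + 1e-8))
}
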