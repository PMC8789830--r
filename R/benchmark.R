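# Desk-scale end-to-end benchmark: the synthetic analogue of the
# published sectioned-enface comparison. A small two-stage generator is
# trained on phantom pairs and compared against bicubic interpolation on
# held-out pairs, for both Deep-layer wirings, over several training
# seeds.

#' Desk-scale reconstruction benchmark on synthetic pairs
#'
#' Builds a seeded synthetic pair set (`n_train` training and `n_test`
#' held-out pairs at `size` x `size` high-resolution, ratio `r`), trains
#' a small generator for each Deep-layer wiring over `n_seeds` training
#' seeds, and reports the held-out mean SSIM of each run next to the
#' bicubic-interpolation baseline. Medians over seeds are used to damp
#' run-to-run noise.
#'
#' The defaults (200/30 pairs, 48 px, r = 2, 2-block 8-channel nets,
#' 3 epochs) are sized for a workstation CPU: each training takes on the
#' order of two minutes, and the trained dense-wiring generator should
#' clear bicubic interpolation's mean SSIM by a wide margin.
#'
#' @param seed base seed: data uses `seed`, training run `k` uses
#'   `seed + k`.
#' @param n_train,n_test training and held-out pair counts.
#' @param size high-resolution enface extent (pixels).
#' @param r enface downsampling ratio.
#' @param connections Deep-layer wirings to benchmark.
#' @param n_seeds training seeds per wiring.
#' @param n_blocks,base_channels generator size.
#' @param epochs,learning_rate,batch_size training schedule.
#' @param verbose print per-run progress.
#' @return A list with `bicubic_ssim`, `runs` (data frame: connection,
#'   seed, ssim), and `medians` (named numeric, one per connection).
#' @export
desk_scale_benchmark <- function(seed = 1L, n_train = 200L, n_test = 30L,
                                 size = 48L, r = 2L,
                                 connections = c("dense", "residual"),
                                 n_seeds = 3L, n_blocks = 2L,
                                 base_channels = 8L, epochs = 3L,
                                 learning_rate = 2e-3, batch_size = 8L,
                                 verbose = FALSE) {
  pairs <- synthetic_pair_set(n_train + n_test, size = size, r = r,
                              seed = seed + 99L)
  test <- pairs[n_train + seq_len(n_test)]
  train <- pairs[seq_len(n_train)]
  mean_ssim <- function(fn) {
    mean(vapply(test, function(p) ssim(p$hr_hq$pixels, as_pixels(fn(p))),
                numeric(1)))
  }
  bicubic <- mean_ssim(function(p) interpolate_upsample(p$lr_lq, r, "bicubic"))
  loss_cfg <- loss_config(msssim_scales = min(5L, msssim_max_scales(size, size)))
  runs <- NULL
  for (conn in connections) {
    for (k in seq_len(n_seeds)) {
      net_cfg <- net_config(connection = conn, n_blocks = n_blocks,
                            base_channels = base_channels,
                            upsample_ratio = r)
      train_cfg <- train_config(learning_rate = learning_rate,
                                batch_size = batch_size,
                                max_epochs = epochs, patience = epochs,
                                seed = seed + k)
      fit <- train_two_stage(train, net_cfg, loss_cfg, train_cfg,
                             val_fraction = 0.1)
      s <- mean_ssim(function(p) reconstruct(p$lr_lq, fit$generator))
      if (verbose) {
        message(sprintf("%s seed %d: held-out mean SSIM %.4f", conn,
                        seed + k, s))
      }
      runs <- rbind(runs, data.frame(connection = conn, seed = seed + k,
                                     ssim = s))
    }
  }
  medians <- vapply(split(runs$ssim, runs$connection), stats::median,
                    numeric(1))
  list(bicubic_ssim = bicubic, runs = runs, medians = medians)
}
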