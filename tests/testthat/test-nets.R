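test_that("pixel shuffle matches the index-formula oracle", {
  # spec case: 4 channels at 1x1 with values 0..3 -> the 2x2 plane
  x <- array(0:3, dim = c(1, 1, 4))
  out <- pixel_shuffle(x, 2)
  expect_equal(out[, , 1], rbind(c(0, 1), c(2, 3)))
  # exhaustive oracle for s in {2, 4} on random grids
  for (s in c(2L, 4L)) {
    h <- 3L; w <- 2L; co <- 2L
    x <- array(stats::rnorm(h * w * co * s^2), dim = c(h, w, co * s^2))
    out <- pixel_shuffle(x, s)
    expect_identical(dim(out), c(s * h, s * w, co))
    for (h0 in 0:(h - 1)) for (w0 in 0:(w - 1)) {
      for (a in 0:(s - 1)) for (b in 0:(s - 1)) for (c0 in 0:(co - 1)) {
        expect_identical(out[s * h0 + a + 1, s * w0 + b + 1, c0 + 1],
                         x[h0 + 1, w0 + 1, c0 * s^2 + a * s + b + 1])
      }
    }
  }
})

test_that("pixel shuffle is bijective and rejects bad channel counts", {
  x <- array(stats::rnorm(4 * 3 * 8), dim = c(4, 3, 8))
  expect_equal(pixel_unshuffle(pixel_shuffle(x, 2), 2), x)
  expect_equal(pixel_shuffle(x, 1), x)
  expect_error(pixel_shuffle(array(0, dim = c(2, 2, 3)), 2),
               "not divisible")
})

small_cfg <- function(connection = "dense", r = 2L) {
  net_config(connection = connection, n_blocks = 2L, base_channels = 4L,
             outer_kernel = 5L, inner_kernel = 3L, upsample_ratio = r)
}

test_that("generator obeys the output shape law for all ratios", {
  img <- matrix(runif(8 * 8), 8, 8)
  for (r in c(2L, 4L, 8L)) {
    G <- build_generator(small_cfg(r = r), seed = 1)
    out <- sr_forward(img, G)
    expect_identical(dim(out), c(8L * r, 8L * r))
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(net_config(upsample_ratio = 3), "power of 2")
})

test_that("forward passes are deterministic and NaN-free", {
  G <- build_generator(small_cfg(), seed = 4)
  img <- matrix(runif(12 * 12), 12, 12)
  expect_identical(sr_forward(img, G), sr_forward(img, G))
  for (conn in c("dense", "residual")) {
    Gc <- build_generator(small_cfg(conn), seed = 9)
    expect_false(any(is.na(reconstruct(img, Gc))))
  }
})

test_that("quality module preserves shape and responds to its deep layer", {
  G <- build_generator(small_cfg("residual"), seed = 2)
  img <- matrix(runif(11 * 13), 11, 13)
  out <- qe_forward(img, G)
  expect_identical(dim(out), dim(img))
  # zeroed residual blocks: deep layer becomes the identity on features
  for (blk in G$qe$blocks) {
    blk$w$value <- blk$w$value * 0
    blk$b$value <- blk$b$value * 0
  }
  feats <- array(stats::rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  expect_equal(deep_layer_forward(feats, G$qe, G$config), feats)
  # changing deep-layer weights changes the module output
  out0 <- qe_forward(img, G)
  G$qe$blocks[[1]]$w$value <- G$qe$blocks[[1]]$w$value + 0.5
  expect_false(isTRUE(all.equal(out0, qe_forward(img, G))))
})

test_that("dense fusion sees base_channels * (n_blocks + 1) channels", {
  cfg <- net_config(connection = "dense", n_blocks = 5L, base_channels = 6L,
                    upsample_ratio = 2L)
  G <- build_generator(cfg, seed = 1)
  # channel-arithmetic oracle: input + one output per block
  expect_identical(dim(G$sr$fusion$w$value)[3], 6L * (5L + 1L))
  expect_identical(dim(G$qe$fusion$w$value)[3], 6L * (5L + 1L))
  bad_cfg <- cfg
  bad_cfg$connection <- "skip"
  feats <- array(0, dim = c(4, 4, 6))
  expect_error(deep_layer_forward(feats, G$sr, bad_cfg), "unknown connection")
})

test_that("reconstruct equals the explicit two-module composition", {
  G <- build_generator(small_cfg(), seed = 6)
  img <- matrix(runif(10 * 10), 10, 10)
  expect_equal(reconstruct(img, G), qe_forward(sr_forward(img, G), G))
  # batch path preserves order
  stack <- array(runif(10 * 10 * 3), dim = c(10, 10, 3))
  outs <- reconstruct(stack, G)
  expect_identical(dim(outs), c(20L, 20L, 3L))
  for (i in 1:3) expect_equal(outs[, , i], reconstruct(stack[, , i], G))
})

test_that("discriminator outputs calibrated-range probabilities", {
  D <- build_discriminator(disc_config(base_channels = 4, n_stages = 2),
                           seed = 3)
  img <- matrix(runif(16 * 16), 16, 16)
  p <- discriminator_forward(img, D)
  expect_length(p, 1)
  expect_gt(p, 0)
  expect_lt(p, 1)
  expect_identical(p, discriminator_forward(img, D))
  # constant-black and constant-white images through one batch
  # (normalization uses batch statistics): finite and distinct
  both <- array(c(rep(0, 256), rep(1, 256)), dim = c(16, 16, 2))
  pb <- discriminator_forward(both, D)
  expect_length(pb, 2)
  expect_true(all(is.finite(pb) & pb > 0 & pb < 1))
  expect_false(pb[1] == pb[2])
})
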