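test_that("MAE loss matches its definition", {
  y <- matrix(runif(256), 16)
  expect_identical(mae_loss(y, y), 0)
  expect_equal(mae_loss(matrix(1, 8, 8), matrix(0, 8, 8)), 1)
  yhat <- matrix(runif(256), 16)
  expect_equal(mae_loss(y, yhat), sum(abs(y - yhat)) / 256)
  expect_error(mae_loss(y, matrix(0, 8, 8)), "mismatch")
})

test_that("MS-SSIM loss matches an independent reference computation", {
  y <- checkerboard64()
  yhat <- 0.5 + 0.5 * (y - 0.5)            # 0.5-contrast version
  expect_equal(msssim_loss(y, y, loss_config(msssim_scales = 3)), 0)
  # reference values from an independent multiscale-SSIM implementation
  # (valid Gaussian filtering, population statistics, renormalized
  # standard exponents), frozen to 10 decimals
  expect_equal(msssim_loss(y, yhat, loss_config(msssim_scales = 3)),
               1 - 0.8025992813, tolerance = 1e-6)
  expect_equal(msssim_loss(y, yhat, loss_config(msssim_scales = 2)),
               1 - 0.8007312868, tolerance = 1e-6)
  pert <- 0.05 * sin(outer(0:63 * 0.7, 0:63 * 1.3, "+"))
  y2 <- pmin(pmax(y + pert, 0), 1)
  expect_equal(msssim_loss(y, y2, loss_config(msssim_scales = 3)),
               1 - 0.9965119833, tolerance = 1e-6)
  # symmetry of the index
  expect_equal(msssim_loss(y, yhat, loss_config(msssim_scales = 3)),
               msssim_loss(yhat, y, loss_config(msssim_scales = 3)))
})

test_that("MS-SSIM errors name the feasible scale count", {
  y <- matrix(runif(32 * 32), 32)
  expect_error(msssim_loss(y, y, loss_config(msssim_scales = 4)),
               "at most 2")
})

test_that("Fourier-magnitude MAE matches a naive DFT oracle", {
  y <- matrix(runif(64), 8)
  expect_identical(fmae_loss(y, y), 0)
  # magnitude spectra are invariant to circular shifts
  shifted <- y[c(4:8, 1:3), c(6:8, 1:5)]
  expect_lt(fmae_loss(y, shifted), 1e-10)
  # O(N^2) DFT by definition
  naive_mag <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    out <- matrix(0, n1, n2)
    for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1)) {
      acc <- 0 + 0i
      for (a in 0:(n1 - 1)) for (b in 0:(n2 - 1)) {
        acc <- acc + m[a + 1, b + 1] *
          exp(-2i * pi * (u * a / n1 + v * b / n2))
      }
      out[u + 1, v + 1] <- Mod(acc)
    }
    out
  }
  yhat <- matrix(runif(64), 8)
  expect_equal(fmae_loss(y, yhat),
               mean(abs(naive_mag(y) - naive_mag(yhat))),
               tolerance = 1e-8)
})

test_that("combined loss is the published weighting of its terms", {
  cfg <- loss_config(msssim_scales = 2)
  y <- checkerboard64()
  yhat <- pmin(pmax(y + 0.05 * sin(outer(0:63 * 0.9, 0:63 * 0.4, "+")), 0), 1)
  expect_identical(combined_loss(y, y, cfg), 0)
  a <- mae_loss(y, yhat)
  b <- msssim_loss(y, yhat, cfg)
  c_ <- fmae_loss(y, yhat)
  expect_equal(combined_loss(y, yhat, cfg), a + 0.8 * b + 7e-5 * c_,
               tolerance = 1e-12)
})

test_that("generator adversarial loss adds the weighted log term", {
  y <- checkerboard64()
  cfg <- loss_config(msssim_scales = 2)
  expect_equal(generator_adv_loss(y, y, d_out = exp(-1), cfg), 5e-3,
               tolerance = 1e-6)
  yhat <- pmin(pmax(y + 0.03, 0), 1)
  # agreement up to the 1e-8 log-stability epsilon
  expect_equal(generator_adv_loss(y, yhat, 1 - 1e-12, cfg),
               combined_loss(y, yhat, cfg), tolerance = 1e-7)
  d <- 0.37
  expect_equal(generator_adv_loss(y, yhat, d, cfg),
               combined_loss(y, yhat, cfg) + 5e-3 * (-log(d + 1e-8)))
  expect_error(generator_adv_loss(y, yhat, 0, cfg), "strictly in")
})

test_that("discriminator loss follows the min-max objective", {
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-7)
  expect_lt(discriminator_loss(1 - 1e-9, 1e-9), 1e-6)
  dr <- c(0.9, 0.6); df <- c(0.2, 0.4)
  expect_equal(discriminator_loss(dr, df),
               -mean(log(dr + 1e-8)) - mean(log(1 - df + 1e-8)))
  expect_error(discriminator_loss(1.2, 0.5), "strictly in")
  expect_error(discriminator_loss(0.5, 0), "strictly in")
})

test_that("losses are non-negative on random image pairs", {
  set.seed(31)
  for (i in 1:5) {
    y <- matrix(runif(32 * 32), 32)
    yhat <- matrix(runif(32 * 32), 32)
    expect_gte(mae_loss(y, yhat), 0)
    expect_gte(fmae_loss(y, yhat), 0)
    expect_gte(msssim_loss(y, yhat, loss_config(msssim_scales = 2)), 0)
  }
})

test_that("autodiff loss gradients agree with central differences", {
  # 8x8 instance; a 5x5 window keeps the SSIM term feasible at this size
  set.seed(5)
  y <- matrix(runif(64) * 0.8 + 0.1, 8)
  yhat <- matrix(runif(64) * 0.8 + 0.1, 8)
  cfg <- loss_config(msssim_scales = 1, msssim_window = 5)
  res <- octra:::ag_with_graph({
    p <- octra:::ag_param(octra:::as_tensor4(yhat))
    loss <- octra:::ag_combined_loss(
      octra:::ag_const(octra:::as_tensor4(y)), p, cfg)
    octra:::ag_backward(loss)
    list(value = octra:::ag_value(loss), grad = p$grad)
  })
  ng <- num_grad(function(z) combined_loss(y, matrix(z, 8), cfg),
                 as.vector(yhat), eps = 1e-6)
  expect_true(all(is.finite(res$grad)))
  expect_lt(max(abs(as.vector(res$grad) - ng)), 1e-4)
})
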