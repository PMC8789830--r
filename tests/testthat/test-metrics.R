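test_that("PSNR follows the decibel formula", {
  y <- matrix(0, 10, 10)
  expect_equal(psnr(y, y + 0.1), 20)          # MSE 0.01
  expect_equal(psnr(y, y + 1), 0)             # MSE 1
  yhat <- matrix(runif(100), 10)
  expect_equal(psnr(y, yhat), 10 * log10(1 / mean(yhat^2)))
  expect_warning(p <- psnr(y, y), "infinite")
  expect_identical(p, Inf)
  # strictly decreasing in MSE
  expect_gt(psnr(y, y + 0.05), psnr(y, y + 0.2))
})

test_that("SSIM matches the frozen reference implementation values", {
  y <- checkerboard64()
  expect_equal(ssim(y, y), 1)
  yhat <- 0.5 + 0.5 * (y - 0.5)
  # frozen from scikit-image structural_similarity (gaussian_weights,
  # sigma 1.5, population covariance, data_range 1)
  expect_equal(ssim(y, yhat), 0.7824000716, tolerance = 1e-6)
  pert <- 0.05 * sin(outer(0:63 * 0.7, 0:63 * 1.3, "+"))
  y2 <- pmin(pmax(y + pert, 0), 1)
  expect_equal(ssim(y, y2), 0.9850530512, tolerance = 1e-6)
  expect_equal(ssim(y, y2), ssim(y2, y))
  expect_equal(ms_ssim(y, yhat, scales = 3), 0.8025992813, tolerance = 1e-6)
  expect_equal(ms_ssim(y, y, scales = 3), 1)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("RMS contrast is the population standard deviation", {
  expect_identical(rms_contrast(matrix(0.4, 5, 5)), 0)
  half <- matrix(c(rep(0, 50), rep(1, 50)), 10)
  expect_equal(rms_contrast(half), 0.5)
  img <- matrix(runif(64), 8)
  expect_equal(rms_contrast(img), sqrt(mean((img - mean(img))^2)))
})

test_that("vessel connectivity counts connected skeleton pixels", {
  img <- matrix(0, 60, 60)
  img[30, 6:55] <- 1                       # straight line, 50 pixels
  expect_equal(vessel_connectivity(img, binarize = 0.5), 1.0)
  # add 10 isolated specks away from the line (rows 3..48, never row 30)
  specks <- cbind(seq(3, 48, by = 5), rep(c(10, 50), 5))
  img2 <- img
  img2[specks] <- 1
  expect_equal(vessel_connectivity(img2, binarize = 0.5, min_component = 5),
               50 / 60, tolerance = 1e-12)
  expect_warning(v <- vessel_connectivity(matrix(0, 20, 20), binarize = 0.5),
                 "empty")
  expect_identical(v, NA_real_)
})

test_that("skeletonization thins to unit width and preserves topology", {
  img <- matrix(0, 30, 30)
  img[10:20, 5:25] <- 1                    # thick bar
  sk <- octra:::skeletonize(img > 0.5)
  expect_true(any(sk))
  expect_lt(sum(sk), sum(img))             # strictly thinner
  sizes <- octra:::component_sizes8(sk)
  expect_length(sizes, 1)                  # still one component
})

test_that("connectivity uses 8-connected components", {
  img <- matrix(0, 20, 20)
  # diagonal staircase: connected only under 8-connectivity
  for (i in 1:10) img[i + 2, i + 2] <- 1
  expect_equal(vessel_connectivity(img, binarize = 0.5, min_component = 5), 1)
})

test_that("evaluation harness aggregates per-image metrics", {
  pairs <- tiny_pairs()[1:3]
  rep_ <- evaluate_pairs(pairs, G = NULL,
                         baselines = c("nearest", "bicubic"),
                         connectivity = FALSE)
  expect_identical(nrow(rep_$per_image), 2L * 3L)
  # means equal direct recomputation from per-image rows
  bic <- rep_$per_image[rep_$per_image$method == "bicubic", ]
  srow <- rep_$summary[rep_$summary$method == "bicubic", ]
  expect_equal(srow$ssim_mean, mean(bic$ssim))
  expect_equal(srow$psnr_db_sd, stats::sd(bic$psnr_db))
  # order invariance of the summaries
  rep2 <- evaluate_pairs(rev(pairs), G = NULL,
                         baselines = c("nearest", "bicubic"),
                         connectivity = FALSE)
  s1 <- rep_$summary[order(rep_$summary$method), ]
  s2 <- rep2$summary[order(rep2$summary$method), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("ground truth scored against itself is perfect", {
  truth <- tiny_pairs()[[1]]$hr_hq$pixels
  expect_equal(ssim(truth, truth), 1)
  expect_equal(ms_ssim(truth, truth,
                       scales = octra:::msssim_max_scales(nrow(truth),
                                                          ncol(truth))), 1)
  expect_equal(rms_contrast(truth), rms_contrast(truth))
})

test_that("acquisition model reproduces the published speed-ups", {
  m <- acquisition_model()
  s22 <- acquisition_speedup(m, 2, 2)
  expect_equal(s22$speedup, 16)
  expect_equal(s22$time_s, 1.1)
  s18 <- acquisition_speedup(m, 1, 8)
  expect_equal(s18$speedup, 1)
  expect_equal(s18$time_s, 17.8)
  expect_equal(acquisition_speedup(m, 4, 2)$speedup, 64)
  expect_equal(acquisition_speedup(m, 4, 2)$time_s, 0.28)
  expect_equal(acquisition_speedup(m, 8, 2)$speedup, 256)
  expect_equal(acquisition_speedup(m, 8, 2)$time_s, 0.07)
  # unrounded invariant: speedup * time recovers the base acquisition time
  for (r in c(1, 2, 4, 8)) {
    sp <- acquisition_speedup(m, r, 2)
    expect_equal(sp$speedup * (m$base_time_s / sp$speedup), m$base_time_s)
  }
  expect_error(acquisition_speedup(m, 2, 9))
})

test_that("equivalent step size scales linearly with the ratio", {
  m <- acquisition_model()
  expect_equal(equivalent_step_size(m, 8), 80)
  expect_equal(equivalent_step_size(m, 4), 40)
  expect_equal(equivalent_step_size(m, 1), 10)
})
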