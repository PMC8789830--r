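test_that("identical repeats give an all-zero angiogram (zero-range rule)", {
  frames <- array(0.5, dim = c(4, 8, 8, 4))
  ang <- compute_angiogram(list(frames = frames))
  expect_true(all(ang$values == 0))
})

test_that("angiogram signal concentrates inside vessels", {
  series <- tiny_series()
  ang <- compute_angiogram(series)
  expect_gt(mean(ang$values[series$vessel_mask]),
            mean(ang$values[!series$vessel_mask]))
  expect_true(all(ang$values >= 0 & ang$values <= 1))
})

test_that("8-repeat estimates disperse less than 2-repeat estimates", {
  # Monte-Carlo over seeded phantoms: per-voxel sd of the raw estimate
  sd8 <- sd2 <- numeric(0)
  for (s in 1:20) {
    spec <- phantom_spec(grid_size = c(12, 12, 12), n_vessels = 3,
                         seed = 300 + s)
    series <- phantom_series(spec, n_repeats = 8)
    if (!any(series$vessel_mask)) next
    a8 <- compute_angiogram(series, 0, 8, normalize = FALSE)
    a2 <- compute_angiogram(series, 0, 2, normalize = FALSE)
    sd8 <- c(sd8, a8$values[series$vessel_mask])
    sd2 <- c(sd2, a2$values[series$vessel_mask])
  }
  # dispersion of the single-pair estimate exceeds the 7-pair average's
  expect_gt(stats::sd(sd2), stats::sd(sd8))
})

test_that("first_repeat / n_use bounds are enforced", {
  series <- tiny_series()
  expect_error(compute_angiogram(series, 0, 1), "n_use")
  expect_error(compute_angiogram(series, 7, 2), "exceeds")
})

test_that("enface downsampling is strided subsampling", {
  v <- array(0:15, dim = c(4, 4, 1))
  expect_identical(downsample_enface(v, 1), v)
  d <- downsample_enface(v, 2)
  expect_identical(dim(d), c(2L, 2L, 1L))
  # index-selection oracle: entries at (0,0), (0,2), (2,0), (2,2)
  expect_equal(as.vector(d[, , 1]), c(v[1, 1, 1], v[3, 1, 1],
                                      v[1, 3, 1], v[3, 3, 1]))
  expect_error(downsample_enface(array(0, dim = c(5, 4, 1)), 2),
               "not divisible")
})

test_that("downsampling composes multiplicatively", {
  v <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_equal(downsample_enface(downsample_enface(v, 2), 2),
               downsample_enface(v, 4))
})

test_that("pair construction is seeded, shape-consistent and lossy", {
  series <- tiny_series()
  p1 <- make_pairs(series, 2, seed = 5)
  p2 <- make_pairs(series, 2, seed = 5)
  expect_identical(p1, p2)
  expect_gt(length(p1), 0)
  for (p in p1) {
    expect_identical(dim(p$hr_lq$pixels), dim(p$hr_hq$pixels))
    expect_identical(dim(p$lr_lq$pixels) * 2L, dim(p$hr_hq$pixels))
  }
  # low-quality intermediates differ from the 8-repeat target
  s <- vapply(p1, function(p) ssim(p$hr_lq$pixels, p$hr_hq$pixels),
              numeric(1))
  expect_lt(mean(s), 1)
  short <- list(frames = series$frames[1:4, , , ])
  expect_error(make_pairs(short, 2), "at least 8 repeats")
})

test_that("maximum intensity projection takes pointwise maxima", {
  v <- array(runif(6 * 6 * 5), dim = c(6, 6, 5))
  one <- mip(v, c(2, 2))
  expect_equal(one$pixels, v[, , 3])
  expect_null(one$depth_index)
  full <- mip(v)
  for (z in 1:5) expect_true(all(full$pixels >= v[, , z]))
  toy <- array(c(0.2, 0.7), dim = c(1, 1, 2))
  expect_equal(mip(toy)$pixels[1, 1], 0.7)
  expect_error(mip(v, c(3, 2)), "empty")
})

test_that("sectioning keeps slices by vessel fraction", {
  v <- array(0, dim = c(8, 8, 4))
  v[, , 2] <- 0.9          # 100% above threshold
  v[1:2, 1, 3] <- 0.9      # 2/64 above threshold
  expect_length(section_and_filter(v, 0), 4)
  expect_length(section_and_filter(array(0, dim = c(4, 4, 3)), 0.01), 0)
  kept <- section_and_filter(v, 0.05, threshold = 0.5)
  # oracle: per-slice count of pixels above threshold
  counts <- apply(v > 0.5, 3, mean)
  expect_equal(vapply(kept, function(k) k$depth_index, integer(1)),
               which(counts >= 0.05) - 1L)
})

test_that("dataset splits are exhaustive, disjoint and 9:1 sized", {
  sp <- split_dataset(2000, c(9, 1), seed = 1)
  expect_length(sp$train, 1800)
  expect_length(sp$val, 200)
  expect_setequal(c(sp$train, sp$val), 0:1999)
  expect_length(intersect(sp$train, sp$val), 0)
  sp10 <- split_dataset(10, c(9, 1), seed = 2)
  expect_length(sp10$train, 9)
  expect_length(sp10$val, 1)
})

test_that("dihedral augmentation preserves pixels and inverts cleanly", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(augment(img, element = 0), img)
  for (e in 0:7) {
    out <- augment(img, element = e)
    expect_equal(sort(as.vector(out)), sort(as.vector(img)))
    inv <- octra:::dihedral_inverse(e)
    expect_identical(augment(out, element = inv), img)
  }
  expect_error(augment(matrix(0, 4, 5), element = 1), "square")
})

test_that("pair augmentation applies one element to all three images", {
  p <- tiny_pairs()[[1]]
  pa <- augment_pair(p, seed = 9)
  el <- withr::with_seed(9, sample.int(8L, 1L)) - 1L
  for (f in c("lr_lq", "hr_lq", "hr_hq")) {
    expect_identical(pa[[f]]$pixels, augment(p[[f]], element = el)$pixels)
  }
})
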