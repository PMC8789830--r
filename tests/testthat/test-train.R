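# Training runs here use deliberately tiny nets and epoch counts; the
# full desk-scale comparison against interpolation lives in
# test-acceptance.R.

tiny_net <- function(connection = "dense") {
  net_config(connection = connection, n_blocks = 1L, base_channels = 4L,
             outer_kernel = 5L, upsample_ratio = 2L)
}

tiny_loss <- loss_config(msssim_scales = 1L)

test_that("two-stage training reduces the validation loss", {
  pairs <- tiny_pairs()[1:20]
  tcfg <- train_config(learning_rate = 2e-3, batch_size = 4,
                       max_epochs = 4, patience = 4, seed = 2)
  fit <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                         val_fraction = 0.2)
  h <- fit$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  expect_true(all(is.finite(unlist(h[, -1]))))
  expect_s3_class(fit$generator, "octra_generator")
})

test_that("early stopping halts after patience non-improving epochs", {
  pairs <- tiny_pairs()[1:8]
  # a vanishing learning rate forces a flat validation loss
  tcfg <- train_config(learning_rate = 1e-30, batch_size = 4,
                       max_epochs = 10, patience = 1, seed = 3)
  fit <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                         val_fraction = 0.25)
  expect_identical(nrow(fit$history), 2L)
})

test_that("training histories are reproducible under a fixed seed", {
  pairs <- tiny_pairs()[1:10]
  tcfg <- train_config(learning_rate = 1e-3, batch_size = 4,
                       max_epochs = 2, patience = 2, seed = 7)
  f1 <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                        val_fraction = 0.2)
  f2 <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                        val_fraction = 0.2)
  expect_identical(f1$history, f2$history)
})

test_that("strong L2 regularization shrinks the weights", {
  pairs <- tiny_pairs()[1:8]
  tcfg <- train_config(learning_rate = 1e-3, batch_size = 4,
                       max_epochs = 2, patience = 2, seed = 4,
                       l2_weight = 5)
  G0 <- build_generator(tiny_net(), seed = tcfg$seed)
  n0 <- octra:::param_norm(c(octra:::collect_params(G0$sr),
                             octra:::collect_params(G0$qe)))
  fit <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                         val_fraction = 0.25)
  G <- fit$generator
  n1 <- octra:::param_norm(c(octra:::collect_params(G$sr),
                             octra:::collect_params(G$qe)))
  expect_lt(n1, n0)
})

test_that("ratio mismatches are rejected before training", {
  pairs <- tiny_pairs()[1:4]
  bad <- net_config(upsample_ratio = 4, n_blocks = 1, base_channels = 4)
  expect_error(train_two_stage(pairs, bad, tiny_loss, train_config()),
               "does not match")
})

test_that("the adversarial stage runs finitely and reproducibly", {
  pairs <- tiny_pairs()[1:10]
  tcfg <- train_config(learning_rate = 1e-4, batch_size = 5,
                       max_epochs = 2, patience = 5, seed = 6,
                       adv_epochs = 2)
  base <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                          val_fraction = 0.2)
  base$generator$trained <- TRUE
  dcfg <- disc_config(base_channels = 4, n_stages = 2)
  g1 <- clone_generator(base$generator)
  g2 <- clone_generator(base$generator)
  a1 <- train_adversarial(g1, pairs, tiny_loss, tcfg, dcfg,
                          val_fraction = 0.2)
  expect_true(all(is.finite(a1$history$d_loss)))
  expect_true(all(is.finite(a1$history$g_loss)))
  a2 <- train_adversarial(g2, pairs, tiny_loss, tcfg, dcfg,
                          val_fraction = 0.2)
  expect_identical(a1$history, a2$history)
})

test_that("a zero adversarial weight reduces to the perceptual objective", {
  pairs <- tiny_pairs()[1:8]
  # negligible learning rate: the first-epoch generator loss is the
  # objective itself, untouched by parameter updates
  tcfg <- train_config(learning_rate = 1e-30, batch_size = 8,
                       max_epochs = 1, patience = 5, seed = 9,
                       adv_epochs = 1)
  base <- train_two_stage(pairs, tiny_net(), tiny_loss, tcfg,
                          val_fraction = 0.25)
  base$generator$trained <- TRUE
  lc0 <- tiny_loss
  lc0$w_adv <- 0
  dcfg <- disc_config(base_channels = 4, n_stages = 2)
  a0 <- train_adversarial(clone_generator(base$generator), pairs, lc0,
                          tcfg, dcfg, val_fraction = 0.25)
  a1 <- train_adversarial(clone_generator(base$generator), pairs,
                          tiny_loss, tcfg, dcfg, val_fraction = 0.25)
  # with w_adv = 0 the generator loss equals the non-adversarial one;
  # with w_adv > 0 it exceeds it by the (positive) -log D term
  expect_gt(a1$history$g_loss[1], a0$history$g_loss[1])
  expect_equal(a0$history$val_loss[1], a1$history$val_loss[1],
               tolerance = 1e-9)
})

test_that("unseeded warning fires for an untrained generator", {
  pairs <- tiny_pairs()[1:6]
  G <- build_generator(tiny_net(), seed = 1)
  tcfg <- train_config(learning_rate = 1e-4, batch_size = 3,
                       max_epochs = 1, patience = 1, seed = 1,
                       adv_epochs = 1)
  expect_warning(
    train_adversarial(G, pairs, tiny_loss, tcfg,
                      disc_config(base_channels = 4, n_stages = 2),
                      val_fraction = 0.34),
    "pre-trained")
})
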