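# Two-staged training schedule and the subsequent adversarial stage.
#
# Per batch, three updates run in sequence: (1) the SR module minimizes
# the combined loss against the fully-sampled low-quality angiogram;
# (2) the QE module minimizes it against the high-quality target, taking
# the SR output as a detached input (no gradients flow back into SR);
# (3) the concatenated end-to-end network is finetuned at a lower
# learning rate. He-normal initialization, Adam, early stopping on the
# validation combined loss, optional L2 penalty.

#' Training configuration
#'
#' Defaults follow common super-resolution GAN practice (the published
#' hyper-parameters were selected by a random search whose values are not
#' given): Adam at `learning_rate` 1e-4, end-to-end finetuning at a tenth
#' of that, batches of 8, early-stopping patience 10, L2 weight 1e-5.
#'
#' @param learning_rate Adam step size for the module stages.
#' @param finetune_lr_factor multiplier (in (0, 1)) applied for the
#'   end-to-end finetuning step.
#' @param batch_size images per batch.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param l2_weight L2 regularization weight added to gradients.
#' @param seed seed controlling initialization, shuffling and splits.
#' @param adversarial whether [train_pipeline()] appends the GAN stage.
#' @param adv_epochs epochs of the adversarial stage.
#' @return A list of class `octra_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, finetune_lr_factor = 0.1,
                         batch_size = 8L, max_epochs = 50L, patience = 10L,
                         l2_weight = 1e-5, seed = 1L, adversarial = FALSE,
                         adv_epochs = 5L) {
  stopifnot(learning_rate > 0, finetune_lr_factor > 0, finetune_lr_factor < 1,
            batch_size >= 1, max_epochs >= 1, patience >= 1, l2_weight >= 0)
  structure(list(learning_rate = learning_rate,
                 finetune_lr_factor = finetune_lr_factor,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 l2_weight = l2_weight, seed = as.integer(seed),
                 adversarial = isTRUE(adversarial),
                 adv_epochs = as.integer(adv_epochs)),
            class = "octra_train_config")
}

# stack a field of a list of pairs into an (H, W, N, 1) tensor
stack_field <- function(pairs, field) {
  mats <- lapply(pairs, function(p) p[[field]]$pixels)
  d <- dim(mats[[1]])
  out <- array(0, dim = c(d[1], d[2], length(mats), 1L))
  for (i in seq_along(mats)) out[, , i, 1L] <- mats[[i]]
  out
}

split_pairs <- function(pairs, val_fraction, seed) {
  sp <- split_dataset(length(pairs), ratio = c(1 - val_fraction, val_fraction),
                      seed = seed)
  list(train = pairs[sp$train + 1L], val = pairs[sp$val + 1L])
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

deep_copy_values <- function(params) lapply(params, function(p) p$value)

restore_values <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(NULL)
}

param_norm <- function(params) {
  sqrt(sum(vapply(params, function(p) sum(p$value^2), numeric(1))))
}

# one optimization step on a scalar-loss graph builder
opt_step <- function(builder, params, lr, t, l2) {
  zero_grads(params)
  val <- ag_with_graph({
    loss <- builder()
    ag_backward(loss)
    ag_value(loss)
  })
  adam_step(params, lr = lr, t = t, l2 = l2)
  val
}

validation_loss <- function(pairs, G, loss_cfg, batch_size = 16L) {
  tot <- 0
  for (ix in batch_indices(length(pairs), batch_size)) {
    x <- ag_const(stack_field(pairs[ix], "lr_lq"))
    y <- ag_const(stack_field(pairs[ix], "hr_hq"))
    v <- ag_with_graph(
      ag_value(ag_combined_loss(y, qe_forward_node(sr_forward_node(x, G), G),
                                loss_cfg)))
    tot <- tot + v * length(ix)
  }
  tot / length(pairs)
}

check_ratio <- function(pairs, net_cfg) {
  r <- pairs[[1]]$ratio
  if (!is_pow2(r)) stop("pair ratio ", r, " is not a power of 2")
  if (r != net_cfg$upsample_ratio) {
    stop("pair ratio ", r, " does not match net upsample_ratio ",
         net_cfg$upsample_ratio)
  }
}

#' Train the two-stage generator
#'
#' @param pairs list of `octra_pair` training records (see
#'   [make_pairs()]); split internally into training and validation sets.
#' @param net_cfg an [net_config()].
#' @param loss_cfg an [loss_config()]; `msssim_scales` must be feasible
#'   for the pair image size.
#' @param train_cfg an [train_config()].
#' @param val_fraction fraction held out for validation monitoring.
#' @param verbose print per-epoch losses.
#' @return A list with `generator` (an `octra_generator`, best validation
#'   weights restored) and `history` (per-epoch data frame with columns
#'   `epoch`, `sr_loss`, `qe_loss`, `e2e_loss`, `val_loss`).
#' @export
train_two_stage <- function(pairs, net_cfg = net_config(),
                            loss_cfg = loss_config(),
                            train_cfg = train_config(),
                            val_fraction = 0.1, verbose = FALSE) {
  if (length(pairs) < 2L) stop("need at least 2 pairs")
  check_ratio(pairs, net_cfg)
  sp <- split_pairs(pairs, val_fraction, train_cfg$seed)
  if (length(sp$train) == 0L || length(sp$val) == 0L) {
    stop("empty train or validation split")
  }
  G <- build_generator(net_cfg, seed = train_cfg$seed)
  res <- run_two_stage(G, sp$train, sp$val, loss_cfg, train_cfg, verbose)
  list(generator = G, history = res$history)
}

run_two_stage <- function(G, train, val, loss_cfg, train_cfg,
                          verbose = FALSE) {
  p_sr <- collect_params(G$sr)
  p_qe <- collect_params(G$qe)
  p_all <- c(p_sr, p_qe)
  hist <- NULL
  best_val <- Inf
  best_w <- NULL
  wait <- 0L
  t_sr <- t_qe <- t_e2e <- 0L
  lr <- train_cfg$learning_rate
  l2 <- train_cfg$l2_weight
  withr::with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(length(train))
      s1 <- s2 <- s3 <- 0
      nb <- 0L
      for (ix in batch_indices(length(train), train_cfg$batch_size)) {
        b <- train[ord[ix]]
        x <- stack_field(b, "lr_lq")
        y_lq <- stack_field(b, "hr_lq")
        y_hq <- stack_field(b, "hr_hq")
        # (1) SR step
        t_sr <- t_sr + 1L
        sr_out <- NULL
        s1 <- s1 + opt_step(function() {
          node <- sr_forward_node(ag_const(x), G)
          sr_out <<- ag_value(node)
          ag_combined_loss(ag_const(y_lq), node, loss_cfg)
        }, p_sr, lr, t_sr, l2)
        # (2) QE step on the detached SR output
        t_qe <- t_qe + 1L
        s2 <- s2 + opt_step(function() {
          ag_combined_loss(ag_const(y_hq),
                           qe_forward_node(ag_const(sr_out), G), loss_cfg)
        }, p_qe, lr, t_qe, l2)
        # (3) end-to-end finetune at reduced learning rate
        t_e2e <- t_e2e + 1L
        s3 <- s3 + opt_step(function() {
          ag_combined_loss(
            ag_const(y_hq),
            qe_forward_node(sr_forward_node(ag_const(x), G), G), loss_cfg)
        }, p_all, lr * train_cfg$finetune_lr_factor, t_e2e, l2)
        nb <- nb + 1L
      }
      vl <- validation_loss(val, G, loss_cfg)
      hist <- rbind(hist, data.frame(epoch = epoch, sr_loss = s1 / nb,
                                     qe_loss = s2 / nb, e2e_loss = s3 / nb,
                                     val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  sr %.4f  qe %.4f  e2e %.4f  val %.4f",
                        epoch, s1 / nb, s2 / nb, s3 / nb, vl))
      }
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best_w <- deep_copy_values(p_all)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= train_cfg$patience) break
      }
    }
  })
  if (!is.null(best_w)) restore_values(p_all, best_w)
  list(history = hist)
}

#' Adversarial (GAN) stage
#'
#' Alternating per-batch updates: the discriminator minimizes
#' `-[log D(HR,HQ) + log(1 - D(G(X)))]`; the generator minimizes the
#' combined loss plus `w_adv * (-log D(G(X)))`. Early stopping monitors
#' the generator's non-adversarial validation loss.
#'
#' @param G a pre-trained `octra_generator` (a warning is given for a
#'   freshly initialized one).
#' @inheritParams train_two_stage
#' @param disc_cfg an [disc_config()].
#' @return A list with `generator`, `discriminator` and `history`
#'   (columns `epoch`, `g_loss`, `d_loss`, `val_loss`).
#' @export
train_adversarial <- function(G, pairs, loss_cfg = loss_config(),
                              train_cfg = train_config(),
                              disc_cfg = disc_config(),
                              val_fraction = 0.1, verbose = FALSE) {
  if (is.null(attr(G, "trained")) && is.null(G$trained)) {
    warning("generator does not appear to be pre-trained; ",
            "the adversarial stage assumes a converged reconstruction model")
  }
  check_ratio(pairs, G$config)
  sp <- split_pairs(pairs, val_fraction, train_cfg$seed)
  D <- build_discriminator(disc_cfg, seed = train_cfg$seed + 2L)
  p_g <- c(collect_params(G$sr), collect_params(G$qe))
  p_d <- collect_params(D[c("head", "stages", "dense")])
  hist <- NULL
  best_val <- Inf
  best_w <- NULL
  wait <- 0L
  t_g <- t_d <- 0L
  lr <- train_cfg$learning_rate
  l2 <- train_cfg$l2_weight
  eps <- 1e-8
  withr::with_seed(train_cfg$seed + 3L, {
    for (epoch in seq_len(train_cfg$adv_epochs)) {
      ord <- sample.int(length(sp$train))
      sg <- sd_ <- 0
      nb <- 0L
      for (ix in batch_indices(length(sp$train), train_cfg$batch_size)) {
        b <- sp$train[ord[ix]]
        x <- stack_field(b, "lr_lq")
        y_hq <- stack_field(b, "hr_hq")
        fake <- ag_with_graph(
          ag_value(qe_forward_node(sr_forward_node(ag_const(x), G), G)))
        # discriminator step (fake detached)
        t_d <- t_d + 1L
        sd_ <- sd_ + opt_step(function() {
          d_real <- disc_forward_node(ag_const(y_hq), D)
          d_fake <- disc_forward_node(ag_const(fake), D)
          ag_sub(0, ag_add(ag_mean(ag_log(ag_add(d_real, eps))),
                           ag_mean(ag_log(ag_sub(1 + eps, d_fake)))))
        }, p_d, lr, t_d, l2)
        # generator step through a frozen discriminator
        t_g <- t_g + 1L
        sg <- sg + opt_step(function() {
          rec <- qe_forward_node(sr_forward_node(ag_const(x), G), G)
          loss <- ag_combined_loss(ag_const(y_hq), rec, loss_cfg)
          if (loss_cfg$w_adv > 0) {
            d_out <- disc_forward_node(rec, D)
            loss <- ag_add(loss, ag_scale(
              ag_sub(0, ag_mean(ag_log(ag_add(d_out, eps)))), loss_cfg$w_adv))
          }
          loss
        }, p_g, lr, t_g, l2)
        nb <- nb + 1L
      }
      vl <- validation_loss(sp$val, G, loss_cfg)
      hist <- rbind(hist, data.frame(epoch = epoch, g_loss = sg / nb,
                                     d_loss = sd_ / nb, val_loss = vl))
      if (verbose) {
        message(sprintf("adv epoch %3d  g %.4f  d %.4f  val %.4f",
                        epoch, sg / nb, sd_ / nb, vl))
      }
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best_w <- deep_copy_values(p_g)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= train_cfg$patience) break
      }
    }
  })
  if (!is.null(best_w)) restore_values(p_g, best_w)
  list(generator = G, discriminator = D, history = hist)
}

#' Full training pipeline
#'
#' [train_two_stage()] followed, when `train_cfg$adversarial` is set, by
#' [train_adversarial()].
#'
#' @inheritParams train_two_stage
#' @inheritParams train_adversarial
#' @return As [train_adversarial()] (with `discriminator = NULL` when the
#'   GAN stage is skipped); history rows carry a `stage` column.
#' @export
train_pipeline <- function(pairs, net_cfg = net_config(),
                           loss_cfg = loss_config(),
                           train_cfg = train_config(),
                           disc_cfg = disc_config(), verbose = FALSE) {
  fit <- train_two_stage(pairs, net_cfg, loss_cfg, train_cfg,
                         verbose = verbose)
  fit$generator$trained <- TRUE
  hist <- cbind(fit$history, stage = "two_stage")
  D <- NULL
  if (train_cfg$adversarial) {
    adv <- train_adversarial(fit$generator, pairs, loss_cfg, train_cfg,
                             disc_cfg, verbose = verbose)
    D <- adv$discriminator
    h2 <- adv$history
    h2 <- data.frame(epoch = h2$epoch, sr_loss = NA, qe_loss = NA,
                     e2e_loss = h2$g_loss, val_loss = h2$val_loss,
                     stage = "adversarial")
    hist <- rbind(hist, h2)
  }
  list(generator = fit$generator, discriminator = D, history = hist)
}
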