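# Two-stage reconstruction generator and adversarial discriminator.
#
# The super-resolution (SR) stage maps an undersampled, 2-repeat enface
# angiogram to the fully-sampled grid: a 9x9 low-level convolution, a
# Deep layer of 3x3 convolution blocks with PReLU (dense or residual
# inter-block wiring), element-wise merge of low- and high-level
# features, then log2(r) pixel-shuffle x2 upsampling stages and a 9x9
# output convolution. The quality-enhancement (QE) stage is the same
# pipeline without upsampling, preserving shape. Outputs are clipped to
# [0, 1].

#' Network configuration
#'
#' @param connection inter-block wiring of the Deep layer: `"dense"`
#'   (each block sees the concatenation of the layer input and all
#'   previous block outputs, with a 1x1 fusion convolution restoring
#'   `base_channels`) or `"residual"` (each block output added to its
#'   input).
#' @param n_blocks number of 3x3 convolution blocks in the Deep layer
#'   (published architecture: 5).
#' @param base_channels feature width of both modules (default 64,
#'   SRGAN-family sizing).
#' @param outer_kernel odd kernel size of the low-level and output
#'   convolutions (published: 9).
#' @param inner_kernel odd kernel size inside the Deep layer (published: 3).
#' @param upsample_ratio enface upsampling ratio, a power of 2 in
#'   `{2, 4, 8}`.
#' @return A list of class `octra_net_config`.
#' @export
net_config <- function(connection = c("dense", "residual"), n_blocks = 5L,
                       base_channels = 64L, outer_kernel = 9L,
                       inner_kernel = 3L, upsample_ratio = 2L) {
  connection <- match.arg(connection)
  stopifnot(n_blocks >= 1, base_channels >= 1,
            outer_kernel %% 2 == 1, inner_kernel %% 2 == 1)
  if (!is_pow2(upsample_ratio) || upsample_ratio < 2) {
    stop("upsample_ratio must be a power of 2 (2, 4 or 8); got ",
         upsample_ratio)
  }
  structure(list(connection = connection, n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 outer_kernel = as.integer(outer_kernel),
                 inner_kernel = as.integer(inner_kernel),
                 upsample_ratio = as.integer(upsample_ratio)),
            class = "octra_net_config")
}

is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

#' Pixel shuffle (sub-pixel rearrangement)
#'
#' Exact periodic rearrangement of an `(H, W, C * s^2)` feature array into
#' `(s * H, s * W, C)`: `out[s*h + a, s*w + b, c] =
#' in[h, w, c*s^2 + a*s + b]` (0-based). Bijective, so learned upsampling
#' introduces no checkerboard artifacts.
#'
#' @param features numeric array `(H, W, C)` with `C` divisible by `s^2`.
#' @param s integer upscaling factor.
#' @return Array `(s * H, s * W, C / s^2)`.
#' @export
pixel_shuffle <- function(features, s) {
  d <- dim(features)
  stopifnot(length(d) == 3L)
  x <- features
  dim(x) <- c(d[1], d[2], 1L, d[3])
  out <- ag_with_graph(ag_value(ag_pixel_shuffle(ag_const(x), s)))
  dim(out) <- dim(out)[c(1, 2, 4)]
  out
}

#' Inverse pixel shuffle
#'
#' @param features array `(s * H, s * W, C)`.
#' @param s integer factor dividing both spatial dimensions.
#' @return Array `(H, W, C * s^2)` such that
#'   `pixel_shuffle(pixel_unshuffle(x, s), s)` is the identity.
#' @export
pixel_unshuffle <- function(features, s) {
  d <- dim(features)
  stopifnot(length(d) == 3L, d[1] %% s == 0L, d[2] %% s == 0L)
  x <- features
  dim(x) <- c(s, d[1] %/% s, s, d[2] %/% s, d[3], 1L)
  x <- aperm(x, c(2, 4, 3, 1, 5, 6))
  dim(x) <- c(d[1] %/% s, d[2] %/% s, s * s * d[3])
  x
}

## ---- layer constructors -----------------------------------------------

# He-normal initialized convolution parameters
new_conv <- function(k, cin, cout, kw = NULL) {
  if (is.null(kw)) kw <- k
  w <- array(stats::rnorm(k * kw * cin * cout, sd = sqrt(2 / (k * kw * cin))),
             dim = c(k, kw, cin, cout))
  list(w = ag_param(w), b = ag_param(numeric(cout)))
}

new_prelu <- function(c) ag_param(rep(0.25, c))

# one reconstruction module (shared by SR and QE): low-level conv,
# Deep layer, optional upsampling stages, output conv
new_module <- function(cfg, upsample = FALSE) {
  C <- cfg$base_channels
  k_in <- cfg$inner_kernel
  blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
    cin <- if (cfg$connection == "dense") C * i else C
    c(new_conv(k_in, cin, C), list(a = new_prelu(C)))
  })
  fusion <- if (cfg$connection == "dense") {
    new_conv(1L, C * (cfg$n_blocks + 1L), C)
  }
  ups <- if (upsample) {
    lapply(seq_len(log2(cfg$upsample_ratio)), function(i) {
      c(new_conv(3L, C, 4L * C), list(a = new_prelu(C)))
    })
  }
  list(low = c(new_conv(cfg$outer_kernel, 1L, C), list(a = new_prelu(C))),
       blocks = blocks, fusion = fusion, ups = ups,
       out = new_conv(cfg$outer_kernel, C, 1L))
}

#' Build the two-stage reconstruction generator
#'
#' @param cfg an [net_config()].
#' @param seed integer seed for He-normal initialization.
#' @return A list of class `octra_generator` with `sr` and `qe` module
#'   parameter sets and `config`.
#' @export
build_generator <- function(cfg = net_config(), seed = 1L) {
  withr::with_seed(seed, {
    structure(list(sr = new_module(cfg, upsample = TRUE),
                   qe = new_module(cfg, upsample = FALSE),
                   config = cfg),
              class = "octra_generator")
  })
}

## ---- forward graphs ---------------------------------------------------

conv_fwd <- function(x, layer, stride = 1L, pad = NULL) {
  ag_conv2d(x, layer$w, layer$b, stride = stride, pad = pad)
}

# Deep layer forward on an ag node with base_channels channels
deep_forward_node <- function(x, module, cfg) {
  if (cfg$connection == "dense") {
    feats <- list(x)
    for (blk in module$blocks) {
      inp <- if (length(feats) == 1L) feats[[1]] else ag_concat_c(feats)
      feats[[length(feats) + 1L]] <- ag_prelu(conv_fwd(inp, blk), blk$a)
    }
    conv_fwd(ag_concat_c(feats), module$fusion)
  } else {
    h <- x
    for (blk in module$blocks) {
      h <- ag_add(h, ag_prelu(conv_fwd(h, blk), blk$a))
    }
    h
  }
}

module_forward_node <- function(x, module, cfg) {
  low <- ag_prelu(conv_fwd(x, module$low), module$low$a)
  deep <- deep_forward_node(low, module, cfg)
  h <- ag_add(deep, low)
  for (up in module$ups %||% list()) {
    h <- ag_prelu(ag_pixel_shuffle(conv_fwd(h, up), 2L), up$a)
  }
  ag_clamp_st(conv_fwd(h, module$out), 0, 1)
}

#' Deep layer forward pass
#'
#' Runs the inter-block Deep layer of a module on a feature array. With
#' dense wiring, block `k` receives the channel concatenation of the
#' layer input and all previous block outputs and a final 1x1 fusion
#' convolution restores `base_channels`; with residual wiring each block
#' output is added to its input. Spatial shape is unchanged.
#'
#' @param features numeric array `(H, W, C)` with `C = base_channels`.
#' @param module one of the generator's module parameter sets (e.g.
#'   `G$sr` or `G$qe`).
#' @param cfg the generator's [net_config()].
#' @return Feature array of identical shape.
#' @export
deep_layer_forward <- function(features, module, cfg) {
  if (!cfg$connection %in% c("dense", "residual")) {
    stop("unknown connection kind: ", cfg$connection)
  }
  d <- dim(features)
  stopifnot(length(d) == 3L, d[3] == cfg$base_channels)
  x <- features
  dim(x) <- c(d[1], d[2], 1L, d[3])
  out <- ag_with_graph(ag_value(deep_forward_node(ag_const(x), module, cfg)))
  dim(out) <- dim(out)[c(1, 2, 4)]
  out
}

sr_forward_node <- function(x, G) module_forward_node(x, G$sr, G$config)
qe_forward_node <- function(x, G) module_forward_node(x, G$qe, G$config)

# run a module on a matrix / (H, W, N) stack / enface image
run_module <- function(img, fwd) {
  was_enface <- inherits(img, "octra_enface")
  x <- as_tensor4(img)
  if (any(x < 0) || any(x > 1)) stop("input image must lie in [0, 1]")
  out <- ag_with_graph(ag_value(fwd(ag_const(x))))
  d <- dim(out)
  out <- if (d[3] == 1L) matrix(out, d[1], d[2]) else {
    o <- out
    dim(o) <- c(d[1], d[2], d[3])
    o
  }
  if (was_enface && is.matrix(out)) {
    enface_image(out, img$kind, img$depth_index)
  } else out
}

#' Super-resolution module forward pass
#'
#' @param img input enface angiogram in `[0, 1]` ([enface_image()],
#'   matrix, or `(H, W, N)` stack).
#' @param G an `octra_generator` from [build_generator()] or
#'   [train_two_stage()].
#' @return The upsampled image (`r` times each enface axis), clipped to
#'   `[0, 1]`, same container type as the input.
#' @export
sr_forward <- function(img, G) run_module(img, function(x) sr_forward_node(x, G))

#' Quality-enhancement module forward pass (shape preserving)
#'
#' @inheritParams sr_forward
#' @return Image of identical shape, clipped to `[0, 1]`.
#' @export
qe_forward <- function(img, G) run_module(img, function(x) qe_forward_node(x, G))

#' End-to-end reconstruction
#'
#' `qe_forward(sr_forward(img))`: maps an undersampled low-quality
#' angiogram to the fully-sampled high-quality estimate.
#'
#' @inheritParams sr_forward
#' @return Reconstructed image at `r` times the input resolution.
#' @export
reconstruct <- function(img, G) {
  run_module(img, function(x) qe_forward_node(sr_forward_node(x, G), G))
}

#' Deep-copy a generator
#'
#' Parameters are reference objects updated in place by training; use a
#' clone to train variants from a common starting point.
#'
#' @param G an `octra_generator`.
#' @return An independent copy with identical weights.
#' @export
clone_generator <- function(G) {
  copy_params <- function(x) {
    if (is_ag_node(x)) {
      return(if (isTRUE(x$is_param)) ag_param(x$value) else x)
    }
    if (is.list(x)) return(lapply(x, copy_params))
    x
  }
  out <- copy_params(unclass(G))
  class(out) <- class(G)
  out
}

## ---- discriminator ----------------------------------------------------

#' Discriminator configuration
#'
#' Strided convolution stack with leaky-ReLU activations and batch
#' normalization, global average pooling and a sigmoid output. Channels
#' double at each stride-2 stage from `base_channels` up to
#' `max_channels` (the published figure's supplementary widths are not
#' available; 64 doubling to 512 is standard SRGAN-family sizing).
#'
#' @param base_channels first-stage width.
#' @param n_stages number of stride-2 stages.
#' @param max_channels channel ceiling.
#' @param lrelu_alpha leaky-ReLU slope.
#' @return A list of class `octra_disc_config`.
#' @export
disc_config <- function(base_channels = 64L, n_stages = 4L,
                        max_channels = 512L, lrelu_alpha = 0.2) {
  stopifnot(base_channels >= 1, n_stages >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 n_stages = as.integer(n_stages),
                 max_channels = as.integer(max_channels),
                 lrelu_alpha = lrelu_alpha),
            class = "octra_disc_config")
}

#' Build the discriminator network
#'
#' @param cfg an [disc_config()].
#' @param seed seed for He-normal initialization.
#' @return A list of class `octra_discriminator`.
#' @export
build_discriminator <- function(cfg = disc_config(), seed = 1L) {
  withr::with_seed(seed, {
    C <- cfg$base_channels
    head <- new_conv(3L, 1L, C)
    stages <- list()
    cin <- C
    for (i in seq_len(cfg$n_stages)) {
      cout <- min(2L * cin, cfg$max_channels)
      stages[[i]] <- c(new_conv(3L, cin, cout),
                       list(gamma = ag_param(rep(1, cout)),
                            beta = ag_param(numeric(cout))))
      cin <- cout
    }
    dense <- list(w = ag_param(matrix(stats::rnorm(cin, sd = sqrt(2 / cin)),
                                      cin, 1L)),
                  b = ag_param(0))
    structure(list(head = head, stages = stages, dense = dense, config = cfg),
              class = "octra_discriminator")
  })
}

disc_forward_node <- function(x, D) {
  a <- D$config$lrelu_alpha
  h <- ag_lrelu(conv_fwd(x, D$head), a)
  for (st in D$stages) {
    h <- conv_fwd(h, st, stride = 2L)
    h <- ag_lrelu(ag_batchnorm(h, st$gamma, st$beta), a)
  }
  pooled <- ag_global_mean_hw(h)
  ag_sigmoid(ag_dense(pooled, D$dense$w, D$dense$b))
}

#' Discriminator forward pass
#'
#' @param img image at the high-resolution shape (matrix, enface image,
#'   or `(H, W, N)` stack).
#' @param D an `octra_discriminator`.
#' @return Probability in (0, 1) per image that it is a real
#'   high-quality angiogram.
#' @export
discriminator_forward <- function(img, D) {
  x <- as_tensor4(img)
  as.vector(ag_with_graph(ag_value(disc_forward_node(ag_const(x), D))))
}
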