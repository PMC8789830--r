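# Reverse-mode automatic differentiation on a per-forward tape.
#
# Tensors are numeric arrays laid out (H, W, C, N); scalars are length-1
# numerics. Each operation computes its value eagerly and records a
# backward closure on the active graph. Parameters live outside any graph
# and accumulate gradients across a backward pass.

.ag <- new.env(parent = emptyenv())
.ag$graph <- NULL

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 256L)
  g$n <- 0L
  g
}

#' @noRd
ag_with_graph <- function(expr) {
  old <- .ag$graph
  .ag$graph <- ag_graph()
  on.exit(.ag$graph <- old)
  expr
}

new_ag_node <- function(value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  nd$needs_grad <- any(vapply(parents, function(p) isTRUE(p$needs_grad), logical(1)))
  g <- .ag$graph
  if (is.null(g)) stop("no active autodiff graph; wrap the computation in ag_with_graph()")
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) length(g$nodes) <- 2L * length(g$nodes)
  g$nodes[[g$n]] <- nd
  class(nd) <- "ag_node"
  nd
}

#' @noRd
ag_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$needs_grad <- TRUE
  nd$is_param <- TRUE
  class(nd) <- "ag_node"
  nd
}

#' @noRd
ag_const <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$needs_grad <- FALSE
  class(nd) <- "ag_node"
  nd
}

is_ag_node <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag_node(x)) x else ag_const(x)

#' @noRd
ag_value <- function(nd) nd$value

# Run backward from a scalar loss node over the active graph.
#' @noRd
ag_backward <- function(loss, graph = .ag$graph) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(graph$n, 1L)) {
    nd <- graph$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    needs <- vapply(nd$parents, function(p) isTRUE(p$needs_grad), logical(1))
    gs <- nd$backward(nd$grad, needs)
    for (j in seq_along(nd$parents)) {
      if (!needs[j] || is.null(gs[[j]])) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL
  }
  invisible(NULL)
}

# reduce a gradient to a scalar parent's shape if needed
.bw_fit <- function(g, v) {
  if (length(v) == 1L) sum(g) else g
}

keep_dim <- function(x, ref) {
  if (!is.null(dim(ref)) && is.null(dim(x))) dim(x) <- dim(ref)
  x
}

## ---- elementwise ops --------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag_node(a$value + b$value, list(a, b), function(g, needs) {
    list(if (needs[1]) .bw_fit(g, a$value),
         if (needs[2]) .bw_fit(g, b$value))
  })
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag_node(a$value - b$value, list(a, b), function(g, needs) {
    list(if (needs[1]) .bw_fit(g, a$value),
         if (needs[2]) .bw_fit(-g, b$value))
  })
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  va <- a$value; vb <- b$value
  new_ag_node(va * vb, list(a, b), function(g, needs) {
    list(if (needs[1]) .bw_fit(keep_dim(g * vb, va), va),
         if (needs[2]) .bw_fit(keep_dim(g * va, vb), vb))
  })
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  va <- a$value; vb <- b$value
  new_ag_node(va / vb, list(a, b), function(g, needs) {
    list(if (needs[1]) .bw_fit(keep_dim(g / vb, va), va),
         if (needs[2]) .bw_fit(keep_dim(-g * va / (vb * vb), vb), vb))
  })
}

ag_scale <- function(a, k) {
  a <- as_ag(a)
  new_ag_node(k * a$value, list(a), function(g, needs) list(k * g))
}

ag_mean <- function(x) {
  x <- as_ag(x)
  n <- length(x$value)
  d <- dim(x$value)
  new_ag_node(mean(x$value), list(x), function(g, needs) {
    gv <- array(g / n, dim = if (is.null(d)) n else d)
    list(gv)
  })
}

ag_sum <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); n <- length(x$value)
  new_ag_node(sum(x$value), list(x), function(g, needs) {
    list(array(g, dim = if (is.null(d)) n else d))
  })
}

ag_abs <- function(x) {
  x <- as_ag(x)
  sg <- sign(x$value)
  new_ag_node(abs(x$value), list(x), function(g, needs) list(keep_dim(g * sg, sg)))
}

ag_log <- function(x) {
  x <- as_ag(x)
  v <- x$value
  new_ag_node(log(v), list(x), function(g, needs) list(keep_dim(g / v, v)))
}

ag_sigmoid <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$value))
  new_ag_node(s, list(x), function(g, needs) list(keep_dim(g * s * (1 - s), s)))
}

ag_pow <- function(x, p) {
  x <- as_ag(x)
  v <- x$value
  new_ag_node(v^p, list(x), function(g, needs) list(keep_dim(g * p * v^(p - 1), v)))
}

# clamp with zero gradient outside the open interval
ag_clamp <- function(x, lo, hi) {
  x <- as_ag(x)
  v <- x$value
  mask <- (v > lo) & (v < hi)
  out <- pmin(pmax(v, lo), hi)
  new_ag_node(out, list(x), function(g, needs) list(keep_dim(g * mask, v)))
}

# straight-through clamp: value is clipped, gradient passes unchanged.
# Used at module exits so that saturated output pixels (common right
# after initialization) still receive a learning signal.
ag_clamp_st <- function(x, lo, hi) {
  x <- as_ag(x)
  v <- x$value
  out <- pmin(pmax(v, lo), hi)
  new_ag_node(out, list(x), function(g, needs) list(g))
}

ag_clamp_min <- function(x, lo) {
  x <- as_ag(x)
  v <- x$value
  mask <- v > lo
  new_ag_node(pmax(v, lo), list(x), function(g, needs) list(keep_dim(g * mask, v)))
}

## ---- activations ------------------------------------------------------

# PReLU with a per-channel trainable leakage vector `a` (length C);
# x is (H, W, N, C).
ag_prelu <- function(x, a) {
  x <- as_ag(x); a <- as_ag(a)
  v <- x$value
  d <- dim(v)
  avec <- rep(a$value, each = d[1] * d[2] * d[3])
  pos <- v > 0
  neg <- pmin(v, 0)
  out <- pmax(v, 0) + avec * neg
  dim(out) <- d
  new_ag_node(out, list(x, a), function(g, needs) {
    dx <- NULL
    if (needs[1]) {
      dx <- g * (pos + (!pos) * avec)
      dim(dx) <- d
    }
    da <- NULL
    if (needs[2]) {
      gn <- g * neg
      dim(gn) <- c(d[1] * d[2] * d[3], d[4])
      da <- colSums(gn)
    }
    list(dx, da)
  })
}

ag_lrelu <- function(x, alpha = 0.2) {
  x <- as_ag(x)
  v <- x$value
  mask <- v > 0
  out <- keep_dim(ifelse(mask, v, alpha * v), v)
  new_ag_node(out, list(x), function(g, needs) {
    list(keep_dim(g * ifelse(mask, 1, alpha), v))
  })
}

## ---- structural ops ---------------------------------------------------

# concatenate along the channel dimension (4th; layout (H, W, N, C))
ag_concat_c <- function(nodes) {
  nodes <- lapply(nodes, as_ag)
  dims <- lapply(nodes, function(nd) dim(nd$value))
  d1 <- dims[[1]]
  cs <- vapply(dims, function(d) d[4], numeric(1))
  ctot <- sum(cs)
  out <- array(0, dim = c(d1[1], d1[2], d1[3], ctot))
  at <- 0L
  for (i in seq_along(nodes)) {
    out[, , , at + seq_len(cs[i])] <- nodes[[i]]$value
    at <- at + cs[i]
  }
  offs <- cumsum(c(0, cs))
  new_ag_node(out, nodes, function(g, needs) {
    dim(g) <- c(d1[1], d1[2], d1[3], ctot)
    lapply(seq_along(nodes), function(i) {
      if (!needs[i]) return(NULL)
      g[, , , offs[i] + seq_len(cs[i]), drop = FALSE]
    })
  })
}

# pixel shuffle: (H, W, N, C) -> (sH, sW, N, C/s^2)
# out[s*h0 + a, s*w0 + b, ., c0] = in[h0, w0, ., c0*s^2 + a*s + b]  (0-based)
ag_pixel_shuffle <- function(x, s) {
  x <- as_ag(x)
  d <- dim(x$value)
  if (d[4] %% (s * s) != 0L) {
    stop("pixel shuffle: channel count ", d[4], " not divisible by s^2 = ", s * s)
  }
  co <- d[4] %/% (s * s)
  v <- x$value
  dim(v) <- c(d[1], d[2], d[3], s, s, co)     # (h, w, n, b, a, c)
  v <- aperm(v, c(5, 1, 4, 2, 3, 6))          # (a, h, b, w, n, c)
  dim(v) <- c(s * d[1], s * d[2], d[3], co)
  new_ag_node(v, list(x), function(g, needs) {
    dim(g) <- c(s, d[1], s, d[2], d[3], co)
    g <- aperm(g, c(2, 4, 5, 3, 1, 6))
    dim(g) <- d
    list(g)
  })
}

# 2x2 average pooling, stride 2; H and W must be even
ag_avg_pool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  v <- x$value
  dim(v) <- c(2, d[1] %/% 2, 2, d[2] %/% 2, d[3], d[4])
  out <- (v[1, , 1, , , , drop = FALSE] + v[2, , 1, , , , drop = FALSE] +
          v[1, , 2, , , , drop = FALSE] + v[2, , 2, , , , drop = FALSE]) / 4
  dim(out) <- c(d[1] %/% 2, d[2] %/% 2, d[3], d[4])
  new_ag_node(out, list(x), function(g, needs) {
    dim(g) <- c(1, d[1] %/% 2, 1, d[2] %/% 2, d[3], d[4])
    gg <- array(0, dim = c(2, d[1] %/% 2, 2, d[2] %/% 2, d[3], d[4]))
    gg[1, , 1, , , ] <- g / 4
    gg[2, , 1, , , ] <- g / 4
    gg[1, , 2, , , ] <- g / 4
    gg[2, , 2, , , ] <- g / 4
    dim(gg) <- d
    list(gg)
  })
}

# crop (H, W) to even sizes (drop last row/col when odd)
ag_crop_even <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  he <- d[1] - d[1] %% 2L
  we <- d[2] - d[2] %% 2L
  if (he == d[1] && we == d[2]) return(x)
  out <- x$value[seq_len(he), seq_len(we), , , drop = FALSE]
  new_ag_node(out, list(x), function(g, needs) {
    gg <- array(0, dim = d)
    gg[seq_len(he), seq_len(we), , ] <- g
    list(gg)
  })
}

# global mean over (H, W): (H, W, N, C) -> (C, N)
ag_global_mean_hw <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  v <- x$value
  dim(v) <- c(d[1] * d[2], d[3] * d[4])
  out <- t(matrix(colMeans(v), nrow = d[3]))
  new_ag_node(out, list(x), function(g, needs) {
    gg <- array(rep(as.vector(t(g)), each = d[1] * d[2]) / (d[1] * d[2]),
                dim = d)
    list(gg)
  })
}

# fully connected: x (C, N), w (C, Out), b (Out) -> (Out, N)
ag_dense <- function(x, w, b) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  out <- crossprod(w$value, x$value) + b$value
  new_ag_node(out, list(x, w, b), function(g, needs) {
    list(if (needs[1]) w$value %*% g,
         if (needs[2]) x$value %*% t(g),
         if (needs[3]) rowSums(g))
  })
}

## ---- convolution ------------------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

# gather-index matrix for batched im2col on a padded (Hp, Wp, N, C) block:
# rows run over (output position, image), columns over (di, dj, channel)
conv_indices <- function(Hp, Wp, N, C, kh, kw, stride) {
  key <- paste(Hp, Wp, N, C, kh, kw, stride, sep = "x")
  idx <- .conv_cache[[key]]
  if (!is.null(idx)) return(idx)
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  oi <- rep.int(seq.int(0L, by = stride, length.out = Ho), Wo)
  oj <- rep(seq.int(0L, by = stride, length.out = Wo), each = Ho)
  base <- oi + Hp * oj
  basen <- rep(base, N) + rep((seq_len(N) - 1L) * Hp * Wp, each = Ho * Wo)
  eg <- expand.grid(di = seq_len(kh) - 1L, dj = seq_len(kw) - 1L,
                    c = seq_len(C) - 1L)
  fo <- eg$di + Hp * eg$dj + Hp * Wp * N * eg$c
  I <- outer(basen, fo, "+") + 1L
  idx <- list(I = as.vector(I), Ho = Ho, Wo = Wo)
  .conv_cache[[key]] <- idx
  idx
}

pad_hw <- function(v, ph, pw) {
  if (ph == 0L && pw == 0L) return(v)
  d <- dim(v)
  out <- array(0, dim = c(d[1] + 2L * ph, d[2] + 2L * pw, d[3], d[4]))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- v
  out
}

# value-level convolution used by both the forward pass and the
# transposed-convolution input gradient; returns Y and the patch matrix
conv_value <- function(xv, wv, bv, stride, ph, pw, want_patches = FALSE) {
  d <- dim(xv)
  dw <- dim(wv)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  xp <- pad_hw(xv, ph, pw)
  dp <- dim(xp)
  ci <- conv_indices(dp[1], dp[2], d[3], cin, kh, kw, stride)
  P <- xp[ci$I]
  dim(P) <- c(ci$Ho * ci$Wo * d[3], kh * kw * cin)
  wm <- wv; dim(wm) <- c(kh * kw * cin, cout)
  Y <- P %*% wm
  if (!is.null(bv)) Y <- Y + rep(bv, each = ci$Ho * ci$Wo * d[3])
  dim(Y) <- c(ci$Ho, ci$Wo, d[3], cout)
  list(Y = Y, P = if (want_patches) P, Ho = ci$Ho, Wo = ci$Wo,
       I = ci$I, dp = dp)
}

# keep forward patch matrices for the weight gradient when modest in size
.conv_patch_cache_limit <- 8e6

# 2-D convolution ("same" for stride 1 via pad = (k-1)/2, or explicit pad).
# x: (H, W, N, Cin); w: (kh, kw, Cin, Cout); b: length Cout or NULL.
# pad may be a single value or (ph, pw).
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_ag(x); w <- as_ag(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_ag(b)
  d <- dim(x$value)
  dw <- dim(w$value)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  stopifnot(d[4] == cin)
  if (is.null(pad)) pad <- c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  if (length(pad) == 1L) pad <- c(pad, pad)
  small <- d[1] * d[2] * d[3] * kh * kw * cin <= .conv_patch_cache_limit
  cv <- conv_value(x$value, w$value, if (has_b) b$value, stride,
                   pad[1], pad[2], want_patches = small && w$needs_grad)
  Y <- cv$Y
  Ho <- cv$Ho; Wo <- cv$Wo
  n <- d[3]
  parents <- if (has_b) list(x, w, b) else list(x, w)
  new_ag_node(Y, parents, function(g, needs) {
    g2 <- g
    dim(g2) <- c(Ho * Wo * n, cout)
    dx <- dw_ <- db <- NULL
    if (needs[2]) {
      P <- cv$P
      if (is.null(P)) {
        # recompute the patch matrix (gather) when it was too large to keep
        xp <- pad_hw(x$value, pad[1], pad[2])
        ci <- conv_indices(dim(xp)[1], dim(xp)[2], n, cin, kh, kw, stride)
        P <- xp[ci$I]
        dim(P) <- c(Ho * Wo * n, kh * kw * cin)
      }
      dwm <- crossprod(P, g2)
      dim(dwm) <- c(kh, kw, cin, cout)
      dw_ <- dwm
    }
    if (has_b && needs[3]) db <- colSums(g2)
    if (needs[1]) {
      if (stride == 1L) {
        # transposed convolution: correlate the upstream gradient with the
        # spatially flipped kernel (channels swapped), full-ish padding
        wf <- w$value[kh:1, kw:1, , , drop = FALSE]
        wf <- aperm(wf, c(1, 2, 4, 3))
        g4 <- g
        dim(g4) <- c(Ho, Wo, n, cout)
        dx <- conv_value(g4, wf, NULL, 1L,
                         kh - 1L - pad[1], kw - 1L - pad[2])$Y
      } else {
        wm <- w$value; dim(wm) <- c(kh * kw * cin, cout)
        dP <- g2 %*% t(wm)
        xp_dim <- c(d[1] + 2L * pad[1], d[2] + 2L * pad[2], d[3], d[4])
        ci <- conv_indices(xp_dim[1], xp_dim[2], n, cin, kh, kw, stride)
        rs <- rowsum(as.vector(dP), group = as.vector(ci$I))
        dxp <- numeric(prod(xp_dim))
        dxp[as.integer(rownames(rs))] <- rs
        dim(dxp) <- xp_dim
        dx <- dxp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), , ,
                  drop = FALSE]
      }
    }
    if (has_b) list(dx, dw_, db) else list(dx, dw_)
  })
}

# spatial batch normalization over (H, W, N) per channel, batch statistics
ag_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$value)
  m <- d[1] * d[2] * d[3]
  v <- x$value
  dim(v) <- c(m, d[4])
  mu <- colMeans(v)
  xc <- sweep(v, 2, mu)
  var_ <- colMeans(xc * xc)
  istd <- 1 / sqrt(var_ + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  dim(y) <- d
  new_ag_node(y, list(x, gamma, beta), function(g, needs) {
    gp <- g
    dim(gp) <- c(m, d[4])
    dgamma <- if (needs[2]) colSums(gp * xhat)
    dbeta <- if (needs[3]) colSums(gp)
    dx <- NULL
    if (needs[1]) {
      gxh <- sweep(gp, 2, gamma$value, `*`)     # dL/dxhat
      t1 <- sweep(gxh, 2, colMeans(gxh))
      t2 <- sweep(xhat, 2, colMeans(gxh * xhat), `*`)
      dx <- sweep(t1 - t2, 2, istd, `*`)
      dim(dx) <- d
    }
    list(dx, dgamma, dbeta)
  })
}

## ---- Fourier-magnitude MAE custom op ----------------------------------

# mean over images of (1/Npix) * sum | |F(Y)| - |F(Yhat)| |,
# unnormalized forward DFT, unshifted grid. Y is a constant target.
ag_fmae_vs <- function(y, yhat, eps = 1e-12) {
  y <- as_ag(y); yhat <- as_ag(yhat)
  d <- dim(yhat$value)
  npix <- d[1] * d[2]
  nimg <- d[3] * d[4]
  total <- 0
  Zs <- vector("list", nimg)
  Ts <- vector("list", nimg)
  vy <- y$value; vh <- yhat$value
  dim(vy) <- c(d[1], d[2], nimg)
  dim(vh) <- c(d[1], d[2], nimg)
  for (i in seq_len(nimg)) {
    Tm <- Mod(stats::fft(vy[, , i]))
    Z <- stats::fft(vh[, , i])
    Zs[[i]] <- Z
    Ts[[i]] <- Tm
    total <- total + sum(abs(Tm - Mod(Z))) / npix
  }
  new_ag_node(total / nimg, list(y, yhat), function(g, needs) {
    dyh <- NULL
    if (needs[2]) {
      dyh <- array(0, dim = d)
      dim(dyh) <- c(d[1], d[2], nimg)
      for (i in seq_len(nimg)) {
        A <- Mod(Zs[[i]])
        s <- -sign(Ts[[i]] - A)                 # dL/d|Z|
        gc_ <- s * Zs[[i]] / pmax(A, eps)
        dyh[, , i] <- Re(stats::fft(gc_, inverse = TRUE)) * (g / (npix * nimg))
      }
      dim(dyh) <- d
    }
    list(NULL, dyh)
  })
}

## ---- parameter utilities ----------------------------------------------

# collect ag_param nodes from an arbitrarily nested list
collect_params <- function(x) {
  if (is_ag_node(x)) {
    if (isTRUE(x$is_param)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(unlist(lapply(x, collect_params), recursive = FALSE))
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Adam with optional L2 penalty added to the gradient
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      l2 = 0) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (l2 > 0) g <- g + l2 * p$value
    if (is.null(p$m)) {
      p$m <- g * 0
      p$v <- g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / b1t) / (sqrt(p$v / b2t) + eps)
  }
  invisible(NULL)
}
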