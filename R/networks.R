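# The three networks of the two-stage inpainting GAN.
#
# Coarse repair network: U-Net with a 4-layer encoder (two Conv3x3-BN-LReLU
# modules + 2x2 max pool per layer), a 2-module transition, and a 4-layer
# decoder (nearest-neighbour upsample + plain Concat skip + two modules),
# closed by a 1x1 convolution and a sigmoid.
#
# Fine repair network: 5-layer encoder whose first layer is a single
# Conv3x3-BN-LReLU and whose remaining four layers are MRBs, each followed
# by a max pool; a transition; and a 5-layer decoder where upsampling is a
# 1x1 convolution combined with nearest-neighbour interpolation and the
# skip merge is the DACC (default), a plain Concat, or an SA-gated concat.
#
# Discriminator (critic): six 5x5 stride-2 convolutions with LReLU (no BN,
# as required for a WGAN-GP critic), a 3x3 convolution + LReLU, global
# average pooling to 1x1 and a linear fully connected layer producing one
# unbounded score per image.  Its forward, backward, input-gradient and
# gradient-penalty double-backward passes are written as one explicit chain.

coarse_net_fwd <- function(tp, x, P, net, train, sts) {
  sl <- net$lrelu_slope
  skips <- list()
  h <- x
  for (i in 1:4) {
    h <- tb_cbl(tp, h, P, paste0("e", i, "a"), 3L, train, sts, sl)
    h <- tb_cbl(tp, h, P, paste0("e", i, "b"), 3L, train, sts, sl)
    skips[[i]] <- h
    h <- t_maxpool(tp, h)
  }
  h <- tb_cbl(tp, h, P, "ta", 3L, train, sts, sl)
  h <- tb_cbl(tp, h, P, "tb", 3L, train, sts, sl)
  tp$bottleneck <- c(h$H, h$W)
  for (i in 4:1) {
    h <- t_upnn(tp, h)
    h <- t_concat(tp, h, skips[[i]])
    h <- tb_cbl(tp, h, P, paste0("d", i, "a"), 3L, train, sts, sl)
    h <- tb_cbl(tp, h, P, paste0("d", i, "b"), 3L, train, sts, sl)
  }
  h <- tb_conv(tp, h, P, "out", 1L)
  t_out_act(tp, h, net)
}

fine_net_fwd <- function(tp, x, P, net, train, sts,
                         skip_mode = c("dacc", "concat", "sa_only")) {
  skip_mode <- match.arg(skip_mode)
  sl <- net$lrelu_slope
  skips <- list()
  h <- tb_cbl(tp, x, P, "e1", 3L, train, sts, sl)
  skips[[1]] <- h
  h <- t_maxpool(tp, h)
  for (i in 2:5) {
    h <- tb_mrb(tp, h, P, paste0("r", i), train, sts, sl)
    skips[[i]] <- h
    h <- t_maxpool(tp, h)
  }
  h <- tb_cbl(tp, h, P, "ta", 3L, train, sts, sl)
  h <- tb_cbl(tp, h, P, "tb", 3L, train, sts, sl)
  tp$bottleneck <- c(h$H, h$W)
  for (i in 5:1) {
    # upsampling = Conv1x1-BN-LReLU + nearest-neighbour interpolation
    h <- tb_cbl(tp, h, P, paste0("u", i), 1L, train, sts, sl)
    h <- t_upnn(tp, h)
    h <- switch(skip_mode,
      dacc = tb_dacc(tp, skips[[i]], h, P, paste0("s", i), train, sts, sl),
      concat = t_concat(tp, skips[[i]], h),
      sa_only = {
        gains <- tb_sa(tp, skips[[i]], P, paste0("s", i))
        t_concat(tp, t_mul_spatial(tp, skips[[i]], gains), h)
      })
    h <- tb_cbl(tp, h, P, paste0("d", i), 3L, train, sts, sl)
  }
  h <- tb_conv(tp, h, P, "out", 1L)
  t_out_act(tp, h, net)
}

# generator output activation: clamped-linear head (default) or sigmoid;
# both restrict outputs to [0,1]
t_out_act <- function(tp, h, net) {
  if (identical(net$out_act, "sigmoid")) t_sigmoid(tp, h) else t_clamp01(tp, h)
}

check_div <- function(H, W, f, what) {
  if (H %% f != 0L || W %% f != 0L)
    stop(what, " requires spatial size divisible by ", f, ", got ", H, "x", W)
}

#' Generator forward passes
#'
#' \code{coarse_forward} runs the coarse repair network, which locates the
#' damaged region and produces the contour and rough texture;
#' \code{fine_forward} runs the fine repair network, which refines the
#' coarse output into detailed iris texture.  Both map an image (or list of
#' images) in [0,1] to an output of identical size and channel count, via a
#' final 1x1 convolution and the output head selected at
#' \code{\link{init_params}} (clamped-linear by default).
#'
#' @param image H x W matrix, H x W x C array, or list of them (a batch).
#' @param net a \code{tsgan_params} object of the matching architecture.
#' @param training use batch BN statistics and update running moments.
#' @param skip_mode skip-connection variant of the fine network:
#'   \code{"dacc"} (dual attention computing connection, the default),
#'   \code{"concat"} (plain skip), or \code{"sa_only"} (encoder features
#'   gated by spatial attention before the concat).
#' @return image(s) of the same shape as the input, values in [0,1].
#' @export
coarse_forward <- function(image, net, training = FALSE) {
  stopifnot(inherits(net, "tsgan_params"), net$arch == "coarse")
  b <- img_batch(image)
  check_div(b$H, b$W, 16L, "coarse network")
  tp <- new_tape()
  out <- coarse_net_fwd(tp, new_node(b$mat, b$H, b$W, b$N, b$C),
                        p_nodes(net$params), net, training, stats_env(net))
  batch_imgs(out$v, out$H, out$W, out$N, out$C, b$single, b$chan_dim)
}

#' @rdname coarse_forward
#' @export
fine_forward <- function(image, net, skip_mode = c("dacc", "concat", "sa_only"),
                         training = FALSE) {
  stopifnot(inherits(net, "tsgan_params"), net$arch == "fine")
  b <- img_batch(image)
  check_div(b$H, b$W, 32L, "fine network")
  tp <- new_tape()
  out <- fine_net_fwd(tp, new_node(b$mat, b$H, b$W, b$N, b$C),
                      p_nodes(net$params), net, training, stats_env(net),
                      match.arg(skip_mode))
  batch_imgs(out$v, out$H, out$W, out$N, out$C, b$single, b$chan_dim)
}

## ---- discriminator: explicit chain -------------------------------------

# Forward pass keeping every pre- and post-activation; x is the internal
# batch matrix.
disc_fwd_raw <- function(x, H, W, N, p, slope) {
  z <- list(); h <- list(); hcur <- x
  Hs <- integer(7); Ws <- integer(7)
  Hc <- H; Wc <- W
  for (i in 1:6) {
    nm <- paste0("c", i)
    zi <- conv_fwd_raw(hcur, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                       Hc, Wc, N, 5L, 2L)
    g <- conv_geom(Hc, Wc, N, 5L, 2L)
    Hc <- g$Ho; Wc <- g$Wo
    z[[i]] <- zi
    hcur <- zi * (slope + (1 - slope) * (zi > 0))
    h[[i]] <- hcur
    Hs[i] <- Hc; Ws[i] <- Wc
  }
  z7 <- conv_fwd_raw(hcur, p[["c7.W"]], p[["c7.b"]], Hc, Wc, N, 3L, 1L)
  z[[7]] <- z7
  a7 <- z7 * (slope + (1 - slope) * (z7 > 0))
  Hs[7] <- Hc; Ws[7] <- Wc
  HW7 <- Hc * Wc
  grp <- grp_geom(N, HW7)
  gapv <- rowsum(a7, grp) / HW7                    # N x C7
  score <- as.vector(gapv %*% p[["fc.W"]] + p[["fc.b"]])
  list(score = score, z = z, h = h, a7 = a7, gapv = gapv,
       Hs = Hs, Ws = Ws, x = x, H = H, W = W, N = N)
}

# lrelu derivative masks
dmask <- function(z, slope) slope + (1 - slope) * (z > 0)

# Parameter gradients for a given dscore (length N); optionally also dx.
disc_bwd_raw <- function(cache, p, dscore, slope, need_dx = FALSE) {
  N <- cache$N
  HW7 <- cache$Hs[7] * cache$Ws[7]
  grp <- grp_geom(N, HW7)
  gr <- list()
  ds <- matrix(dscore, ncol = 1L)
  gr[["fc.W"]] <- crossprod(cache$gapv, ds)
  gr[["fc.b"]] <- sum(ds)
  dgap <- ds %*% t(p[["fc.W"]])                    # N x C7
  da7 <- dgap[grp, , drop = FALSE] / HW7
  dz7 <- da7 * dmask(cache$z[[7]], slope)
  r <- conv_bwd_core(dz7, p[["c7.W"]], cache$Hs[6], cache$Ws[6], N, 3L, 1L,
                     x = cache$h[[6]])
  gr[["c7.W"]] <- r$dW; gr[["c7.b"]] <- r$db
  dh <- r$dx
  for (i in 6:1) {
    dz <- dh * dmask(cache$z[[i]], slope)
    Hin <- if (i == 1L) cache$H else cache$Hs[i - 1]
    Win <- if (i == 1L) cache$W else cache$Ws[i - 1]
    r <- conv_bwd_core(dz, p[[paste0("c", i, ".W")]], Hin, Win, N, 5L, 2L,
                       x = if (i == 1L) cache$x else cache$h[[i - 1]],
                       need_dx = (i > 1L) || need_dx)
    gr[[paste0("c", i, ".W")]] <- r$dW
    gr[[paste0("c", i, ".b")]] <- r$db
    dh <- r$dx
  }
  list(grads = gr, dx = dh)
}

# Input gradient g = d score / d x for unit dscore, keeping the backward
# chain (u_i before masking, v_i after) for the double-backward pass.
disc_input_grad <- function(cache, p, slope, dscore = rep(1, cache$N)) {
  N <- cache$N
  HW7 <- cache$Hs[7] * cache$Ws[7]
  grp <- grp_geom(N, HW7)
  dgap <- matrix(dscore, ncol = 1L) %*% t(p[["fc.W"]])
  u <- vector("list", 7L); v <- vector("list", 7L)
  u[[7]] <- dgap[grp, , drop = FALSE] / HW7
  v[[7]] <- u[[7]] * dmask(cache$z[[7]], slope)
  r <- conv_bwd_core(v[[7]], p[["c7.W"]], cache$Hs[6], cache$Ws[6], N, 3L, 1L,
                     need_dw = FALSE)
  u[[6]] <- r$dx
  for (i in 6:1) {
    v[[i]] <- u[[i]] * dmask(cache$z[[i]], slope)
    Hin <- if (i == 1L) cache$H else cache$Hs[i - 1]
    Win <- if (i == 1L) cache$W else cache$Ws[i - 1]
    r <- conv_bwd_core(v[[i]], p[[paste0("c", i, ".W")]], Hin, Win, N, 5L, 2L,
                       need_dw = FALSE)
    if (i > 1L) u[[i - 1]] <- r$dx else gx <- r$dx
  }
  list(g = gx, u = u, v = v)
}

# Double-backward: gradients of a scalar P w.r.t. the critic weights, where
# P depends on the input gradient g through sg = dP/dg.  The backward chain
# that produced g is itself differentiated: conv-transposes become forward
# convolutions of the sensitivities, and each weight receives the
# correlation of its sensitivity input with the chain value it multiplied.
# Activation masks are piecewise constant and carry no gradient.
disc_gp_bwd <- function(cache, chain, p, slope, sg) {
  N <- cache$N
  gr <- list()
  su <- sg
  for (i in 1:6) {
    Hin <- if (i == 1L) cache$H else cache$Hs[i - 1]
    Win <- if (i == 1L) cache$W else cache$Ws[i - 1]
    Wm <- p[[paste0("c", i, ".W")]]
    sv <- conv_fwd_raw(su, Wm, NULL, Hin, Win, N, 5L, 2L)
    r <- conv_bwd_core(chain$v[[i]], Wm, Hin, Win, N, 5L, 2L, x = su,
                       need_dx = FALSE)
    gr[[paste0("c", i, ".W")]] <- r$dW
    su <- sv * dmask(cache$z[[i]], slope)
  }
  sv7 <- conv_fwd_raw(su, p[["c7.W"]], NULL, cache$Hs[6], cache$Ws[6], N, 3L, 1L)
  r <- conv_bwd_core(chain$v[[7]], p[["c7.W"]], cache$Hs[6], cache$Ws[6],
                     N, 3L, 1L, x = su, need_dx = FALSE)
  gr[["c7.W"]] <- r$dW
  su7 <- sv7 * dmask(cache$z[[7]], slope)
  HW7 <- cache$Hs[7] * cache$Ws[7]
  grp <- grp_geom(N, HW7)
  gr[["fc.W"]] <- t(rowsum(su7, grp)) %*% matrix(1, N, 1L) / HW7
  gr
}

#' Discriminator forward pass
#'
#' Scores an image (or batch) with the WGAN-GP critic: six 5x5 stride-2
#' convolutions with leaky ReLU (no batch normalization), a 3x3
#' convolution + leaky ReLU, global average pooling to 1x1 and a linear
#' fully connected layer.  Higher scores mean "more like a real image".
#'
#' @inheritParams coarse_forward
#' @return numeric vector with one unbounded score per input image.
#' @export
discriminator_forward <- function(image, net) {
  stopifnot(inherits(net, "tsgan_params"), net$arch == "discriminator")
  b <- img_batch(image)
  check_div(b$H, b$W, 64L, "discriminator")
  fw <- disc_fwd_raw(b$mat, b$H, b$W, b$N, net$params, net$lrelu_slope)
  fw$score
}
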