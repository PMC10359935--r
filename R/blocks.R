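# Building blocks of the fine repair network: Conv-BN-LReLU modules, the
# modified residual block (MRB), squeeze-and-excitation (SE) channel
# attention, spatial attention (SA), and the dual attention computing
# connection (DACC) that fuses encoder and decoder features at each skip.

# conv(k) -> BN -> LReLU, parameters under `name` in the flat list of nodes P
tb_cbl <- function(tp, x, P, name, k, train, sts, slope, stride = 1L) {
  y <- t_conv(tp, x, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]], k, stride)
  y <- t_bn(tp, y, P[[paste0(name, ".g")]], P[[paste0(name, ".be")]],
            train, sts, name)
  t_lrelu(tp, y, slope)
}

tb_conv <- function(tp, x, P, name, k, stride = 1L) {
  t_conv(tp, x, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]], k, stride)
}

tb_bn <- function(tp, x, P, name, train, sts) {
  t_bn(tp, x, P[[paste0(name, ".g")]], P[[paste0(name, ".be")]], train, sts, name)
}

# Modified residual block: two Conv1x1-BN-LReLU / Conv3x3-BN-LReLU module
# pairs; y1 = modules 1-2 applied to the input, y2 = modules 3-4 applied to
# y1 (the internal shortcut reuses y1 both directly and through the second
# pair); output = Concat(y1, y2) + identity branch.  y1 and y2 each carry
# out_channels/2 so the Concat matches the identity branch, which is a 1x1
# projection whenever in/out channel counts differ.
tb_mrb <- function(tp, x, P, prefix, train, sts, slope) {
  x1 <- tb_cbl(tp, x, P, paste0(prefix, "m1"), 1L, train, sts, slope)
  y1 <- tb_cbl(tp, x1, P, paste0(prefix, "m2"), 3L, train, sts, slope)
  x3 <- tb_cbl(tp, y1, P, paste0(prefix, "m3"), 1L, train, sts, slope)
  y2 <- tb_cbl(tp, x3, P, paste0(prefix, "m4"), 3L, train, sts, slope)
  cat12 <- t_concat(tp, y1, y2)
  idb <- if (!is.null(P[[paste0(prefix, "p.W")]]))
    tb_conv(tp, x, P, paste0(prefix, "p"), 1L) else x
  stopifnot(cat12$C == idb$C)
  t_add(tp, cat12, idb)
}

# SE channel gains: sigmoid(W2 %*% lrelu(W1 %*% GAP(x_en))), one gain per
# channel per sample, in (0,1).
tb_se <- function(tp, x_en, P, prefix, slope) {
  h <- t_gap(tp, x_en)
  h <- t_fc(tp, h, P[[paste0(prefix, "w1.W")]])
  h <- t_lrelu(tp, h, slope)
  h <- t_fc(tp, h, P[[paste0(prefix, "w2.W")]])
  t_sigmoid(tp, h)
}

# SA per-pixel gains: sigmoid(Conv7x7(Concat(channel-mean, channel-max))),
# one gain per spatial location, in (0,1); the gains are returned without
# being multiplied into x_en.
tb_sa <- function(tp, x_en, P, prefix) {
  mn <- t_chan_mean(tp, x_en)
  mx <- t_chan_max(tp, x_en)
  h <- t_concat(tp, mn, mx)
  h <- tb_conv(tp, h, P, paste0(prefix, "sa"), 7L)
  t_sigmoid(tp, h)
}

# DACC skip fusion:
#   out = Concat( LReLU(BN(x_de * Xsa)),  Xse * sigmoid(BN(x_de)) )
# Xsa is the spatial-attention gain map of the encoder features (one value
# per pixel, broadcast over channels, NOT pre-multiplied into x_en); Xse is
# the standard squeeze-and-excitation output on the encoder features, i.e.
# the encoder feature map rescaled by its per-channel gains, so the second
# branch carries (gated) encoder content into the decoder.  Both products
# are elementwise feature-map multiplications; output has twice the
# channels of the decoder input.
tb_dacc <- function(tp, x_en, x_de, P, prefix, train, sts, slope) {
  stopifnot(x_en$H == x_de$H, x_en$W == x_de$W)
  xsa <- tb_sa(tp, x_en, P, prefix)
  xse <- t_mul_channel(tp, x_en, tb_se(tp, x_en, P, prefix, slope))
  b1 <- t_mul_spatial(tp, x_de, xsa)
  b1 <- tb_bn(tp, b1, P, paste0(prefix, "bna"), train, sts)
  b1 <- t_lrelu(tp, b1, slope)
  b2 <- tb_bn(tp, x_de, P, paste0(prefix, "bnb"), train, sts)
  b2 <- t_sigmoid(tp, b2)
  b2 <- t_hadamard(tp, xse, b2)
  t_concat(tp, b1, b2)
}

## ---- exported standalone block interfaces ------------------------------

# wrap a flat list of parameter arrays into value nodes
p_nodes <- function(params) lapply(params, new_node)

stats_env <- function(net) {
  e <- new.env(parent = emptyenv())
  e$s <- net$stats
  e
}

block_prep <- function(x) {
  b <- img_batch(x)
  nd <- new_node(b$mat, b$H, b$W, b$N, b$C)
  list(b = b, nd = nd)
}

#' Standalone block parameter collections
#'
#' Build seeded He-initialized parameter lists for a single modified
#' residual block or a single DACC skip module, for use with
#' \code{\link{mrb_forward}}, \code{\link{se_forward}},
#' \code{\link{sa_forward}} and \code{\link{dacc_forward}}.
#'
#' @param in_channels,out_channels MRB input/output channel counts.
#' @param channels DACC channel count (encoder and decoder features alike).
#' @param identity_proj include the 1x1 projection on the identity branch;
#'   required (and forced) whenever \code{in_channels != out_channels}.
#' @param se_r SE reduction ratio.
#' @param seed integer seed.
#' @return flat named list of parameter arrays plus an attribute
#'   \code{"stats"} holding batch-norm running moments.
#' @export
mrb_params <- function(in_channels, out_channels, identity_proj = TRUE,
                       seed = 1L) {
  h <- max(1L, out_channels %/% 2L)
  if (in_channels != out_channels) identity_proj <- TRUE
  spec <- list(cv("m1", in_channels, h, 1L), cv("m2", h, h, 3L),
               cv("m3", h, h, 1L), cv("m4", h, h, 3L))
  if (identity_proj)
    spec <- c(spec, list(cv("p", in_channels, 2L * h, 1L, bn = FALSE)))
  build_block_params(spec, seed)
}

#' @rdname mrb_params
#' @export
dacc_params <- function(channels, se_r = 16L, seed = 1L) {
  hi <- max(1L, channels %/% se_r)
  spec <- list(
    list(name = "w1", type = "fc", cin = channels, cout = hi, bias = FALSE),
    list(name = "w2", type = "fc", cin = hi, cout = channels, bias = FALSE),
    cv("sa", 2L, 1L, 7L, bn = FALSE),
    list(name = "bna", type = "bn", cout = channels),
    list(name = "bnb", type = "bn", cout = channels))
  build_block_params(spec, seed)
}

build_block_params <- function(spec, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  params <- list(); stats <- list()
  for (m in spec) {
    if (m$type == "conv") {
      fan_in <- m$k^2 * m$cin
      params[[paste0(m$name, ".W")]] <-
        matrix(stats::rnorm(fan_in * m$cout, sd = sqrt(2 / fan_in)), fan_in, m$cout)
      if (isTRUE(m$bias)) params[[paste0(m$name, ".b")]] <- numeric(m$cout)
      if (isTRUE(m$bn)) {
        params[[paste0(m$name, ".g")]] <- rep(1, m$cout)
        params[[paste0(m$name, ".be")]] <- numeric(m$cout)
        stats[[paste0(m$name, ".rm")]] <- numeric(m$cout)
        stats[[paste0(m$name, ".rv")]] <- rep(1, m$cout)
      }
    } else if (m$type == "fc") {
      params[[paste0(m$name, ".W")]] <-
        matrix(stats::rnorm(m$cin * m$cout, sd = sqrt(2 / m$cin)), m$cin, m$cout)
    } else if (m$type == "bn") {
      params[[paste0(m$name, ".g")]] <- rep(1, m$cout)
      params[[paste0(m$name, ".be")]] <- numeric(m$cout)
      stats[[paste0(m$name, ".rm")]] <- numeric(m$cout)
      stats[[paste0(m$name, ".rv")]] <- rep(1, m$cout)
    }
  }
  attr(params, "stats") <- stats
  params
}

blk_stats_env <- function(p) {
  e <- new.env(parent = emptyenv())
  e$s <- attr(p, "stats")
  e
}

#' Modified residual block forward pass
#'
#' Applies one MRB to a feature map: two Conv1x1-BN-LReLU /
#' Conv3x3-BN-LReLU module pairs whose half-width outputs \code{y1} and
#' \code{y2} are concatenated and added to an identity branch (a plain pass
#' or a 1x1 projection).  Spatial size is preserved.
#'
#' @param x feature map, an H x W x C array (or H x W matrix for C = 1).
#' @param p parameter list from \code{\link{mrb_params}}.
#' @param training use batch statistics in BN (TRUE) or running statistics.
#' @param slope leaky ReLU negative slope.
#' @return feature map array of the block's output channel count.
#' @export
mrb_forward <- function(x, p, training = FALSE, slope = 0.2) {
  bp <- block_prep(x)
  cin <- ncol(p[["m1.W"]])
  if (bp$b$C != nrow(p[["m1.W"]]))
    stop("input has ", bp$b$C, " channels but MRB expects ", nrow(p[["m1.W"]]))
  tp <- new_tape()
  out <- tb_mrb(tp, bp$nd, p_nodes(p), "", training, blk_stats_env(p), slope)
  batch_imgs(out$v, out$H, out$W, out$N, out$C, single = bp$b$single,
             chan_dim = TRUE)
}

#' Attention block forward passes
#'
#' \code{se_forward} computes squeeze-and-excitation channel gains
#' \code{sigmoid(W2 lrelu(W1 GAP(x)))}: one value in (0,1) per channel.
#' \code{sa_forward} computes spatial attention gains: the channel-axis mean
#' and max maps are concatenated, passed through a 7x7 convolution and a
#' sigmoid, giving one value in (0,1) per pixel.  Neither is pre-multiplied
#' into the input.  \code{dacc_forward} fuses an encoder feature map
#' \code{x_en} and a decoder feature map \code{x_de} of equal shape into
#' \code{Concat(LReLU(BN(x_de * Xsa)), Xse * sigmoid(BN(x_de)))}, where
#' \code{Xsa} is the SA gain map and \code{Xse = x_en * se_forward(x_en)}
#' is the SE-rescaled encoder feature map, doubling the channel count:
#' the first branch spatially gates the decoder features, the second
#' carries channel-reweighted encoder content gated by the decoder.
#'
#' @param x_en encoder feature map (H x W x C array).
#' @param x_de decoder feature map of the same shape.
#' @param p parameter list from \code{\link{dacc_params}}.
#' @param training BN mode, as in \code{\link{mrb_forward}}.
#' @param slope leaky ReLU negative slope.
#' @return \code{se_forward}: numeric vector of C gains; \code{sa_forward}:
#'   H x W matrix of gains; \code{dacc_forward}: H x W x 2C array.
#' @export
se_forward <- function(x_en, p, slope = 0.2) {
  bp <- block_prep(x_en)
  tp <- new_tape()
  out <- tb_se(tp, bp$nd, p_nodes(p), "", slope)
  if (bp$b$single) as.vector(out$v) else out$v
}

#' @rdname se_forward
#' @export
sa_forward <- function(x_en, p) {
  bp <- block_prep(x_en)
  tp <- new_tape()
  out <- tb_sa(tp, bp$nd, p_nodes(p), "")
  batch_imgs(out$v, out$H, out$W, out$N, 1L, single = bp$b$single,
             chan_dim = FALSE)
}

#' @rdname se_forward
#' @export
dacc_forward <- function(x_en, x_de, p, training = FALSE, slope = 0.2) {
  be <- block_prep(x_en)
  bd <- block_prep(x_de)
  if (be$b$H != bd$b$H || be$b$W != bd$b$W)
    stop("encoder and decoder feature maps must share spatial size")
  tp <- new_tape()
  out <- tb_dacc(tp, be$nd, bd$nd, p_nodes(p), "", training,
                 blk_stats_env(p), slope)
  batch_imgs(out$v, out$H, out$W, out$N, out$C, single = be$b$single,
             chan_dim = TRUE)
}
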