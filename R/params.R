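#' Initialize network parameters
#'
#' Creates a seeded, serializable parameter collection for one of the three
#' networks: the coarse repair network, the fine repair network, or the
#' WGAN-GP discriminator (critic).  All convolution and fully connected
#' weights use He initialization (zero-mean Gaussian with standard deviation
#' \code{sqrt(2 / fan_in)}, the scaling suited to rectifier activations),
#' biases start at zero and batch-normalization layers at gain 1 / bias 0.
#' The collection is a pure function of its arguments: the same seed always
#' reproduces the same weights.
#'
#' Channel widths default to standard U-Net / DCGAN progressions at 256x256
#' input (coarse encoder 64/128/256/512; fine encoder 64/128/256/512/512;
#' discriminator 64/128/256/256/512/512) and can be scaled down uniformly
#' with \code{width_div} for miniature CPU-scale experiments.
#'
#' @param arch one of \code{"coarse"}, \code{"fine"}, \code{"discriminator"}.
#' @param in_channels number of image channels (1 for NIR iris imagery).
#' @param width_div divide all default channel widths by this factor.
#' @param widths optional explicit integer vector of channel widths,
#'   overriding the defaults (length 4 coarse, 5 fine, 6 discriminator).
#' @param seed integer seed fully determining the initial weights.
#' @param lrelu_slope negative slope of every leaky ReLU.
#' @param se_r squeeze-and-excitation reduction ratio (channel attention
#'   bottleneck \code{C / se_r}, at least 1).
#' @param out_act generator output activation mapping to [0,1]:
#'   \code{"clamp"} (clamped-linear head, the default) or
#'   \code{"sigmoid"}; ignored for the discriminator.  On iris imagery,
#'   whose targets are mostly exact-zero background, the sigmoid head
#'   converges far more slowly (its gradient vanishes over most of the
#'   output range and exact black is unreachable).
#' @return an object of class \code{tsgan_params}: a list with the
#'   architecture description, the flat named list \code{$params} of weight
#'   arrays, and \code{$stats} of batch-norm running moments.
#' @examples
#' p <- init_params("discriminator", width_div = 8, seed = 1)
#' length(p$params)
#' @export
init_params <- function(arch = c("coarse", "fine", "discriminator"),
                        in_channels = 1L, width_div = 1L, widths = NULL,
                        seed = 1L, lrelu_slope = 0.2, se_r = 16L,
                        out_act = c("clamp", "sigmoid")) {
  arch <- match.arg(arch)
  out_act <- match.arg(out_act)
  defw <- switch(arch,
    coarse = c(64L, 128L, 256L, 512L),
    fine = c(64L, 128L, 256L, 512L, 512L),
    discriminator = c(64L, 128L, 256L, 256L, 512L, 512L))
  if (is.null(widths)) widths <- pmax(as.integer(defw / width_div), 2L)
  stopifnot(length(widths) == length(defw), all(widths >= 1))
  spec <- switch(arch,
    coarse = coarse_spec(in_channels, widths),
    fine = fine_spec(in_channels, widths, se_r),
    discriminator = disc_spec(in_channels, widths))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  params <- list()
  stats <- list()
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
      if (!isFALSE(m$bias)) params[[paste0(m$name, ".b")]] <- numeric(m$cout)
    } else if (m$type == "bn") {
      params[[paste0(m$name, ".g")]] <- rep(1, m$cout)
      params[[paste0(m$name, ".be")]] <- numeric(m$cout)
      stats[[paste0(m$name, ".rm")]] <- numeric(m$cout)
      stats[[paste0(m$name, ".rv")]] <- rep(1, m$cout)
    }
  }
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 widths = as.integer(widths), seed = as.integer(seed),
                 lrelu_slope = lrelu_slope, se_r = as.integer(se_r),
                 out_act = out_act, params = params, stats = stats),
            class = "tsgan_params")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# conv module descriptor; modules followed by BN carry no bias (the batch
# mean subtraction makes a preceding bias a zero-gradient direction)
cv <- function(name, cin, cout, k, bn = TRUE) {
  list(name = name, type = "conv", cin = cin, cout = cout, k = k, bn = bn,
       bias = !bn)
}

coarse_spec <- function(C, w) {
  s <- list()
  cins <- c(C, w[1:3])
  for (i in 1:4) {
    s <- c(s, list(cv(paste0("e", i, "a"), cins[i], w[i], 3L),
                   cv(paste0("e", i, "b"), w[i], w[i], 3L)))
  }
  s <- c(s, list(cv("ta", w[4], w[4], 3L), cv("tb", w[4], w[4], 3L)))
  prev <- w[4]
  for (i in 4:1) {
    s <- c(s, list(cv(paste0("d", i, "a"), prev + w[i], w[i], 3L),
                   cv(paste0("d", i, "b"), w[i], w[i], 3L)))
    prev <- w[i]
  }
  c(s, list(cv("out", w[1], C, 1L, bn = FALSE)))
}

fine_spec <- function(C, f, se_r) {
  s <- list(cv("e1", C, f[1], 3L))
  for (i in 2:5) {
    fin <- f[i - 1]; fout <- f[i]; h <- max(1L, fout %/% 2L)
    s <- c(s, list(cv(paste0("r", i, "m1"), fin, h, 1L),
                   cv(paste0("r", i, "m2"), h, h, 3L),
                   cv(paste0("r", i, "m3"), h, h, 1L),
                   cv(paste0("r", i, "m4"), h, h, 3L),
                   cv(paste0("r", i, "p"), fin, 2L * h, 1L, bn = FALSE)))
  }
  s <- c(s, list(cv("ta", f[5], f[5], 3L), cv("tb", f[5], f[5], 3L)))
  prev <- f[5]
  for (i in 5:1) {
    hi <- max(1L, f[i] %/% se_r)
    s <- c(s, list(
      cv(paste0("u", i), prev, f[i], 1L),
      list(name = paste0("s", i, "w1"), type = "fc", cin = f[i], cout = hi, bias = FALSE),
      list(name = paste0("s", i, "w2"), type = "fc", cin = hi, cout = f[i], bias = FALSE),
      cv(paste0("s", i, "sa"), 2L, 1L, 7L, bn = FALSE),
      list(name = paste0("s", i, "bna"), type = "bn", cout = f[i]),
      list(name = paste0("s", i, "bnb"), type = "bn", cout = f[i]),
      cv(paste0("d", i), 2L * f[i], f[i], 3L)))
    prev <- f[i]
  }
  c(s, list(cv("out", f[1], C, 1L, bn = FALSE)))
}

disc_spec <- function(C, d) {
  s <- list()
  cins <- c(C, d[1:5])
  for (i in 1:6) s <- c(s, list(cv(paste0("c", i), cins[i], d[i], 5L, bn = FALSE)))
  c(s, list(cv("c7", d[6], d[6], 3L, bn = FALSE),
            list(name = "fc", type = "fc", cin = d[6], cout = 1L)))
}

#' Save / load network checkpoints
#'
#' Checkpoints hold one or more \code{tsgan_params} objects (weights plus
#' batch-norm running statistics) and round-trip bit-exactly.
#'
#' @param nets a named list of \code{tsgan_params} objects (for example
#'   \code{list(coarse = ..., fine = ..., disc = ...)}).
#' @param path file path of the checkpoint.
#' @return \code{load_checkpoint} returns the named list of networks.
#' @export
save_checkpoint <- function(nets, path) {
  stopifnot(all(vapply(nets, inherits, TRUE, "tsgan_params")))
  saveRDS(nets, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

## ---- image <-> batch-matrix conversion ---------------------------------

# Accepts a single image (H x W matrix or H x W x C array) or a list of
# identically shaped images; returns the internal batch representation.
img_batch <- function(x) {
  single <- !is.list(x)
  imgs <- if (single) list(x) else x
  a1 <- imgs[[1]]
  d <- dim(a1)
  stopifnot(length(d) %in% c(2L, 3L))
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  N <- length(imgs)
  mat <- matrix(0, N * H * W, C)
  for (n in seq_len(N)) {
    a <- imgs[[n]]
    stopifnot(identical(dim(a)[1:2], c(H, W)))
    rows <- ((n - 1L) * H * W + 1L):(n * H * W)
    if (length(dim(a)) == 3L) {
      for (ch in seq_len(C)) mat[rows, ch] <- as.vector(a[, , ch])
    } else {
      mat[rows, 1L] <- as.vector(a)
    }
  }
  list(mat = mat, H = H, W = W, N = N, C = C, single = single,
       chan_dim = length(d) == 3L)
}

batch_imgs <- function(mat, H, W, N, C, single = FALSE, chan_dim = C > 1L) {
  out <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * H * W + 1L):(n * H * W)
    a <- if (chan_dim) array(mat[rows, ], dim = c(H, W, C))
         else matrix(mat[rows, 1L], H, W)
    out[[n]] <- a
  }
  if (single) out[[1]] else out
}
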