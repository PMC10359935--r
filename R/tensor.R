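# Low-level feature-map machinery: batched feature maps are stored as plain
# (N*H*W) x C matrices, sample-major, column-major within each H x W plane
# (row index fastest).  Convolutions are implemented as per-offset row
# gathers followed by BLAS matrix products; gradients reuse the same index
# maps.  A minimal reverse-mode tape on top of these primitives provides the
# gradients needed for training.

.tsg_cache <- new.env(parent = emptyenv())

#' @noRd
cache_get <- function(key, builder) {
  if (is.null(.tsg_cache[[key]])) .tsg_cache[[key]] <- builder()
  .tsg_cache[[key]]
}

# Same-padding convolution geometry: for each of the k*k kernel offsets,
# the (injective) map from valid output rows to input rows, replicated
# across the batch.
conv_geom <- function(H, W, N, k, stride) {
  key <- paste("cg", H, W, N, k, stride, sep = "_")
  cache_get(key, function() {
    Ho <- as.integer(ceiling(H / stride))
    Wo <- as.integer(ceiling(W / stride))
    pad_h <- max((Ho - 1L) * stride + k - H, 0L)
    pad_w <- max((Wo - 1L) * stride + k - W, 0L)
    pbh <- pad_h %/% 2L
    pbw <- pad_w %/% 2L
    HWo <- Ho * Wo
    HW <- H * W
    offs <- vector("list", k * k)
    o <- 0L
    for (kj in 0:(k - 1L)) {
      for (ki in 0:(k - 1L)) {
        o <- o + 1L
        iy <- (0:(Ho - 1L)) * stride - pbh + ki
        ix <- (0:(Wo - 1L)) * stride - pbw + kj
        vy <- iy >= 0L & iy < H
        vx <- ix >= 0L & ix < W
        vmat <- outer(vy, vx, "&")
        ro <- which(vmat)                       # valid output rows (one image)
        ri <- outer(iy, ix * H, "+")[vmat] + 1L # their input rows (one image)
        full <- length(ro) == HWo
        if (N > 1L) {
          ro <- as.vector(outer(ro, (0:(N - 1L)) * HWo, "+"))
          ri <- as.vector(outer(ri, (0:(N - 1L)) * HW, "+"))
        }
        ro <- as.integer(ro); ri <- as.integer(ri)
        # run-length encode maximal segments where both maps advance by 1,
        # so the C++ kernels can memcpy / vector-add contiguous blocks
        n <- length(ro)
        br <- if (n > 1L) which(diff(ri) != 1L | diff(ro) != 1L) else integer(0)
        starts <- c(1L, br + 1L)
        ends <- c(br, n)
        offs[[o]] <- list(ro = if (full) NULL else ro, ri = ri,
                          runs = cbind(dstart = ro[starts], sstart = ri[starts],
                                       len = ends - starts + 1L))
      }
    }
    list(Ho = Ho, Wo = Wo, offs = offs, k = k)
  })
}

# x: (N*H*W) x Cin.  Wm: (k^2*Cin) x Cout, offset-major blocks.  bias: Cout or NULL.
conv_fwd_raw <- function(x, Wm, bias, H, W, N, k, stride) {
  if (k == 1L && stride == 1L) {
    y <- x %*% Wm
  } else {
    g <- conv_geom(H, W, N, k, stride)
    y <- cpp_conv_fwd(x, Wm, g$offs, N * g$Ho * g$Wo)
  }
  if (!is.null(bias)) y <- sweep2(y, bias)
  y
}

# Gradients of conv_fwd_raw; `x` (the layer input) is needed for dW.
conv_bwd_core <- function(dy, Wm, H, W, N, k, stride, x = NULL,
                          need_dx = TRUE, need_dw = TRUE) {
  if (k == 1L && stride == 1L) {
    return(list(dx = if (need_dx) dy %*% t(Wm) else NULL,
                dW = if (need_dw) crossprod(x, dy) else NULL,
                db = colSums(dy)))
  }
  g <- conv_geom(H, W, N, k, stride)
  list(dx = if (need_dx) cpp_conv_dx(dy, Wm, g$offs, N * H * W) else NULL,
       dW = if (need_dw) cpp_conv_dw(x, dy, g$offs) else NULL,
       db = colSums(dy))
}

conv_bwd_raw <- function(dy, x, Wm, H, W, N, k, stride,
                         need_dx = TRUE, need_dw = TRUE) {
  conv_bwd_core(dy, Wm, H, W, N, k, stride, x = x,
                need_dx = need_dx, need_dw = need_dw)
}

# add a bias (length Cout) to every row
sweep2 <- function(y, bias) cpp_colscale(y, rep(1, length(bias)), bias)

pool_geom <- function(H, W, N) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  key <- paste("pg", H, W, N, sep = "_")
  cache_get(key, function() {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    oy <- (0:(Ho - 1L)) * 2L
    ox <- (0:(Wo - 1L)) * 2L
    idx <- vector("list", 4L)
    o <- 0L
    for (kj in 0:1) for (ki in 0:1) {
      o <- o + 1L
      ii <- as.vector(outer(oy + ki, (ox + kj) * H, "+")) + 1L
      if (N > 1L) ii <- as.vector(outer(ii, (0:(N - 1L)) * H * W, "+"))
      idx[[o]] <- as.integer(ii)
    }
    list(Ho = Ho, Wo = Wo, idx = idx,
         idx4 = cbind(idx[[1]], idx[[2]], idx[[3]], idx[[4]]))
  })
}

up_geom <- function(H, W, N) {
  key <- paste("ug", H, W, N, sep = "_")
  cache_get(key, function() {
    Ho <- 2L * H; Wo <- 2L * W
    sy <- rep(0:(H - 1L), each = 2L)       # source row per output row
    sx <- rep(0:(W - 1L), each = 2L)
    ii <- as.vector(outer(sy, sx * H, "+")) + 1L
    if (N > 1L) ii <- as.vector(outer(ii, (0:(N - 1L)) * H * W, "+"))
    list(Ho = Ho, Wo = Wo, idx = ii)
  })
}

grp_geom <- function(N, HW) {
  key <- paste("gg", N, HW, sep = "_")
  cache_get(key, function() rep(seq_len(N), each = HW))
}

## ---- reverse-mode tape -------------------------------------------------

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- vector("list", 256L)
  tp$n <- 0L
  tp
}

new_node <- function(v, H = NA_integer_, W = NA_integer_, N = 1L, C = NCOL(v)) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$grad <- NULL
  nd$H <- H; nd$W <- W; nd$N <- N; nd$C <- C
  nd
}

tp_push <- function(tp, out, ins, bwd) {
  n <- tp$n + 1L
  if (n > length(tp$ops)) tp$ops <- c(tp$ops, vector("list", length(tp$ops)))
  tp$ops[[n]] <- list(out = out, ins = ins, bwd = bwd)
  tp$n <- n
  out
}

acc_grad <- function(nd, g) {
  if (is.null(g)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Reverse sweep.  If `loss` is NULL the caller must have seeded output grads.
tp_backward <- function(tp, loss = NULL, seed = 1) {
  if (!is.null(loss)) loss$grad <- matrix(seed, 1L, 1L)
  for (i in rev(seq_len(tp$n))) {
    op <- tp$ops[[i]]
    d <- op$out$grad
    if (is.null(d)) next
    gs <- op$bwd(d)
    for (j in seq_along(op$ins)) acc_grad(op$ins[[j]], gs[[j]])
  }
  invisible(NULL)
}

## ---- tape primitives ---------------------------------------------------

t_conv <- function(tp, x, Wn, bn, k, stride = 1L) {
  H <- x$H; W <- x$W; N <- x$N
  y <- conv_fwd_raw(x$v, Wn$v, if (is.null(bn)) NULL else bn$v,
                    H, W, N, k, stride)
  g <- conv_geom(H, W, N, k, stride)
  out <- new_node(y, g$Ho, g$Wo, N)
  xv <- x$v; Wv <- Wn$v
  tp_push(tp, out, if (is.null(bn)) list(x, Wn) else list(x, Wn, bn),
          function(d) {
    r <- conv_bwd_core(d, Wv, H, W, N, k, stride, x = xv)
    gs <- list(r$dx, r$dW)
    if (!is.null(bn)) gs <- c(gs, list(r$db))
    gs
  })
}

t_bn <- function(tp, x, gn, bn, train, sts = NULL, key = NULL,
                 momentum = 0.1, eps = 1e-5) {
  xv <- x$v; R <- nrow(xv)
  if (train) {
    st <- cpp_colstats(xv)
    mu <- st$mu; va <- st$va
    istd <- 1 / sqrt(va + eps)
    xh <- cpp_colscale(xv, istd, -mu * istd)
    y <- cpp_colscale(xh, gn$v, bn$v)
    if (!is.null(sts)) {
      sts$s[[paste0(key, ".rm")]] <- (1 - momentum) * sts$s[[paste0(key, ".rm")]] + momentum * mu
      sts$s[[paste0(key, ".rv")]] <- (1 - momentum) * sts$s[[paste0(key, ".rv")]] + momentum * va
    }
    out <- new_node(y, x$H, x$W, x$N)
    gv <- gn$v
    tp_push(tp, out, list(x, gn, bn), function(d) {
      r <- cpp_bn_bwd(d, xh, gv, istd)
      list(r$dx, r$dg, r$db)
    })
  } else {
    rm <- sts$s[[paste0(key, ".rm")]]
    rv <- sts$s[[paste0(key, ".rv")]]
    istd <- 1 / sqrt(rv + eps)
    sc <- gn$v * istd
    y <- xv * rep(sc, each = R) + rep(bn$v - rm * sc, each = R)
    out <- new_node(y, x$H, x$W, x$N)
    tp_push(tp, out, list(x, gn, bn), function(d) {
      list(d * rep(sc, each = R),
           colSums(d * (xv - rep(rm, each = R)) * rep(istd, each = R)),
           colSums(d))
    })
  }
}

t_lrelu <- function(tp, x, slope = 0.2) {
  xv <- x$v
  out <- new_node(cpp_lrelu(xv, slope), x$H, x$W, x$N)
  tp_push(tp, out, list(x), function(d) list(cpp_lrelu_bwd(d, xv, slope)))
}

# clamp to [0,1]; gradient passes only on the open interval
t_clamp01 <- function(tp, x) {
  xv <- x$v
  y <- pmin(pmax(xv, 0), 1)
  out <- new_node(y, x$H, x$W, x$N)
  tp_push(tp, out, list(x), function(d) list(d * (xv > 0 & xv < 1)))
}

t_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$v))
  out <- new_node(y, x$H, x$W, x$N)
  tp_push(tp, out, list(x), function(d) list(d * y * (1 - y)))
}

t_maxpool <- function(tp, x) {
  g <- pool_geom(x$H, x$W, x$N)
  r <- cpp_maxpool(x$v, g$idx4)
  out <- new_node(r$y, g$Ho, g$Wo, x$N)
  R <- nrow(x$v)
  tp_push(tp, out, list(x), function(d) list(cpp_maxpool_bwd(d, r$win, R)))
}

t_upnn <- function(tp, x) {
  g <- up_geom(x$H, x$W, x$N)
  y <- x$v[g$idx, , drop = FALSE]
  out <- new_node(y, g$Ho, g$Wo, x$N)
  tp_push(tp, out, list(x), function(d) list(rowsum(d, g$idx)))
}

t_concat <- function(tp, a, b) {
  stopifnot(a$H == b$H, a$W == b$W, a$N == b$N)
  out <- new_node(cbind(a$v, b$v), a$H, a$W, a$N)
  Ca <- a$C
  tp_push(tp, out, list(a, b), function(d)
    list(d[, seq_len(Ca), drop = FALSE], d[, -seq_len(Ca), drop = FALSE]))
}

t_add <- function(tp, a, b) {
  out <- new_node(a$v + b$v, a$H, a$W, a$N)
  tp_push(tp, out, list(a, b), function(d) list(d, d))
}

# multiply feature map by a per-pixel gain (R x 1), broadcast over channels
t_mul_spatial <- function(tp, x, s) {
  sv <- as.vector(s$v)
  y <- x$v * sv
  out <- new_node(y, x$H, x$W, x$N)
  xv <- x$v
  tp_push(tp, out, list(x, s), function(d)
    list(d * sv, matrix(rowSums(d * xv), ncol = 1L)))
}

# multiply feature map by per-sample per-channel gains (N x C), broadcast over space
t_mul_channel <- function(tp, x, g) {
  grp <- grp_geom(x$N, x$H * x$W)
  G <- g$v[grp, , drop = FALSE]
  y <- x$v * G
  out <- new_node(y, x$H, x$W, x$N)
  xv <- x$v
  tp_push(tp, out, list(x, g), function(d)
    list(d * G, rowsum(d * xv, grp)))
}

# elementwise product of two same-shaped feature maps
t_hadamard <- function(tp, a, b) {
  av <- a$v; bv <- b$v
  out <- new_node(av * bv, a$H, a$W, a$N)
  tp_push(tp, out, list(a, b), function(d) list(d * bv, d * av))
}

# spatial global average pool -> N x C
t_gap <- function(tp, x) {
  HW <- x$H * x$W
  grp <- grp_geom(x$N, HW)
  y <- rowsum(x$v, grp) / HW
  out <- new_node(y, 1L, 1L, x$N)
  tp_push(tp, out, list(x), function(d) list(d[grp, , drop = FALSE] / HW))
}

t_fc <- function(tp, h, Wn, bn = NULL) {
  y <- h$v %*% Wn$v
  if (!is.null(bn)) y <- sweep2(y, bn$v)
  out <- new_node(y, h$H, h$W, h$N)
  hv <- h$v; Wv <- Wn$v
  ins <- if (is.null(bn)) list(h, Wn) else list(h, Wn, bn)
  tp_push(tp, out, ins, function(d) {
    gs <- list(d %*% t(Wv), crossprod(hv, d))
    if (!is.null(bn)) gs <- c(gs, list(colSums(d)))
    gs
  })
}

# channel-axis mean / max maps -> R x 1
t_chan_mean <- function(tp, x) {
  C <- x$C
  y <- matrix(rowMeans(x$v), ncol = 1L)
  out <- new_node(y, x$H, x$W, x$N)
  tp_push(tp, out, list(x), function(d) list(matrix(as.vector(d) / C, nrow(x$v), C)))
}

t_chan_max <- function(tp, x) {
  j <- max.col(x$v, ties.method = "first")
  R <- nrow(x$v)
  y <- matrix(x$v[cbind(seq_len(R), j)], ncol = 1L)
  out <- new_node(y, x$H, x$W, x$N)
  C <- x$C
  tp_push(tp, out, list(x), function(d) {
    dx <- matrix(0, R, C)
    dx[cbind(seq_len(R), j)] <- as.vector(d)
    list(dx)
  })
}

# mean absolute difference against a fixed target matrix -> scalar node
t_l1 <- function(tp, a, target) {
  diff <- a$v - target
  y <- matrix(mean(abs(diff)), 1L, 1L)
  out <- new_node(y, 1L, 1L, 1L)
  n <- length(diff)
  tp_push(tp, out, list(a), function(d) list(sign(diff) * (as.numeric(d) / n)))
}

t_scale <- function(tp, x, c) {
  out <- new_node(x$v * c, x$H, x$W, x$N)
  tp_push(tp, out, list(x), function(d) list(d * c))
}
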