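# Independent oracles used across the suite.  Each one is written against
# the mathematical definition, not against the package's code paths.

ns <- asNamespace("irisinpaint")
int <- function(name) get(name, envir = ns)

lrelu_ref <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# rasterized annulus mask by per-pixel radius scan
annulus_mask <- function(n, center, rp, ri) {
  m <- matrix(0, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    rad <- sqrt((r - center[1])^2 + (c - center[2])^2)
    if (rad >= rp && rad <= ri) m[r, c] <- 1
  }
  m
}

# naive same-padding convolution by nested loops (offset-major weights)
naive_conv <- function(img, Wm, b, k, stride) {
  H <- dim(img)[1]; W <- dim(img)[2]; Cin <- dim(img)[3]; Cout <- ncol(Wm)
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  pbh <- max((Ho - 1) * stride + k - H, 0) %/% 2
  pbw <- max((Wo - 1) * stride + k - W, 0) %/% 2
  out <- array(0, c(Ho, Wo, Cout))
  for (oy in 1:Ho) for (ox in 1:Wo) for (co in 1:Cout) {
    s <- if (is.null(b)) 0 else b[co]
    o <- 0
    for (kj in 0:(k - 1)) for (ki in 0:(k - 1)) {
      o <- o + 1
      iy <- (oy - 1) * stride - pbh + ki + 1
      ix <- (ox - 1) * stride - pbw + kj + 1
      if (iy >= 1 && iy <= H && ix >= 1 && ix <= W)
        s <- s + sum(img[iy, ix, ] * Wm[((o - 1) * Cin + 1):(o * Cin), co])
    }
    out[oy, ox, co] <- s
  }
  out
}

# center-offset weight block of a k x k kernel matrix (for 1x1 inputs,
# where same-padding convolution degenerates to this matrix product)
center_block <- function(Wm, k, cin) {
  oc <- (k %/% 2) * k + (k %/% 2) + 1   # offset index of (ki = kj = k%/%2)
  Wm[((oc - 1) * cin + 1):(oc * cin), , drop = FALSE]
}

# make the running-statistics BN of a block parameter list an exact
# identity (eps = 1e-5 inside the BN)
bn_identity <- function(p) {
  st <- attr(p, "stats")
  for (nm in grep("\\.rv$", names(st), value = TRUE)) st[[nm]][] <- 1 - 1e-5
  for (nm in grep("\\.rm$", names(st), value = TRUE)) st[[nm]][] <- 0
  attr(p, "stats") <- st
  p
}

# brute-force ROC point enumeration over all distinct thresholds
roc_enum <- function(genuine, impostor) {
  th <- c(Inf, sort(unique(c(genuine, impostor)), decreasing = TRUE), -Inf)
  t(vapply(th, function(tt)
    c(far = mean(impostor >= tt), tar = mean(genuine >= tt)), numeric(2)))
}

# EER by brute-force sweep + linear interpolation in (FAR, FRR) space
eer_enum <- function(genuine, impostor) {
  pts <- roc_enum(genuine, impostor)
  far <- pts[, "far"]; frr <- 1 - pts[, "tar"]
  k <- which(far - frr >= 0)[1]
  if (k == 1) return(100 * far[1])
  f1 <- far[k - 1]; f2 <- far[k]; r1 <- frr[k - 1]; r2 <- frr[k]
  den <- (r1 - f1) - (r2 - f2)
  a <- if (abs(den) < 1e-15) 0.5 else (r1 - f1) / den
  100 * (f1 + a * (f2 - f1))
}

# TAR at a given FAR by enumeration + linear interpolation along the curve
tar_enum <- function(genuine, impostor, far0) {
  pts <- roc_enum(genuine, impostor)
  o <- order(pts[, "far"], pts[, "tar"])
  f <- pts[o, "far"]; tt <- pts[o, "tar"]
  if (far0 >= max(f)) return(100)
  if (far0 <= f[1]) return(100 * tt[1])
  100 * stats::approx(f, tt, xout = far0, ties = max)$y
}

# Finite-difference gradient check through a generator network, filtering
# out parameter coordinates whose +/- h evaluations land on different
# linear pieces (leaky-ReLU sign or pooling argmax switches): central
# differences are meaningless across those measure-zero kinks.
fd_gradcheck <- function(net, builder, xmat, H, W, N, C,
                         nsample = 10, h = 1e-5, sample_seed = 1) {
  new_tape <- int("new_tape"); new_node <- int("new_node")
  p_nodes <- int("p_nodes"); stats_env <- int("stats_env")
  tp_backward <- int("tp_backward"); node_grads <- int("node_grads")
  run <- function(p) {
    net2 <- net; net2$params <- p
    tp <- new_tape()
    out <- builder(tp, new_node(xmat, H, W, N, C), p_nodes(p), net2, TRUE,
                   stats_env(net2))
    sig <- lapply(seq_len(tp$n), function(i) sign(tp$ops[[i]]$out$v))
    list(loss = sum(out$v^2), sig = sig)
  }
  tp <- new_tape()
  pn <- p_nodes(net$params)
  out <- builder(tp, new_node(xmat, H, W, N, C), pn, net, TRUE, stats_env(net))
  out$grad <- 2 * out$v
  tp_backward(tp, NULL)
  gr <- node_grads(pn)
  set.seed(sample_seed)
  rel <- c(); tried <- 0
  nms <- names(net$params)
  while (length(rel) < nsample && tried < 8 * nsample) {
    tried <- tried + 1
    nm <- sample(nms, 1)
    if (is.null(gr[[nm]])) next
    i <- sample(length(net$params[[nm]]), 1)
    pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - h
    rp <- run(pp); rm_ <- run(pm)
    if (!identical(rp$sig, rm_$sig)) next   # crossed a kink
    fd <- (rp$loss - rm_$loss) / (2 * h)
    an <- gr[[nm]][i]
    rel <- c(rel, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
  }
  rel
}
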