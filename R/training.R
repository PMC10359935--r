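# Losses and the two-stage training loop.  The coarse network minimises an
# L1 reconstruction loss against the ground truth; the fine network is
# trained adversarially with the WGAN-GP objective (plus an L1 anchor, see
# train_config), with gd_ratio critic updates per generator update.

#' Training losses
#'
#' \code{l1_loss} is the mean absolute pixel difference between two images
#' or batches.  \code{wgan_d_loss} is the critic objective
#' \code{mean(fake) - mean(real) + lambda * gp}; \code{wgan_g_loss} is the
#' generator objective \code{-mean(fake)}.
#'
#' @param a,b images (H x W (x C) arrays) or lists of images of equal shape.
#' @param real_scores,fake_scores numeric critic score vectors.
#' @param gp scalar gradient penalty.
#' @param lambda gradient-penalty weight.
#' @return a scalar.
#' @export
l1_loss <- function(a, b) {
  ba <- img_batch(a); bb <- img_batch(b)
  if (!identical(dim(ba$mat), dim(bb$mat)))
    stop("l1_loss: shape mismatch")
  mean(abs(ba$mat - bb$mat))
}

#' @rdname l1_loss
#' @export
wgan_d_loss <- function(real_scores, fake_scores, gp = 0, lambda = 10)
  mean(fake_scores) - mean(real_scores) + lambda * gp

#' @rdname l1_loss
#' @export
wgan_g_loss <- function(fake_scores) -mean(fake_scores)

#' Smoothed WGAN-GP gradient penalty
#'
#' For interpolates \code{xhat = eps * real + (1 - eps) * fake} with
#' per-sample \code{eps ~ U(0,1)}, computes
#' \code{mean((sqrt(sum(g^2) + C) - 1)^2)} where \code{g} is the critic's
#' gradient with respect to \code{xhat}.  The smoothing constant \code{C}
#' keeps the penalty differentiable when the gradient vanishes; \code{C = 0}
#' recovers the unsmoothed penalty, whose parameter gradient is NaN on a
#' zero-gradient batch.
#'
#' @param critic a \code{tsgan_params} discriminator, or a function mapping
#'   an image array to a scalar score (then \code{critic_grad} must be given).
#' @param real,fake image or list of images (equal shapes).
#' @param C smoothing constant (the paper's value is 1e-8).
#' @param critic_grad for function critics: function mapping an image array
#'   to the array of score gradients.
#' @param eps optional per-sample interpolation weights (otherwise drawn
#'   from the current RNG stream).
#' @param return_grads if TRUE and \code{critic} is a \code{tsgan_params}
#'   object, also return the penalty's gradients w.r.t. the critic weights.
#' @return the scalar penalty, or a list \code{(value, grads)} when
#'   \code{return_grads = TRUE}.
#' @export
gradient_penalty <- function(critic, real, fake, C = 1e-8,
                             critic_grad = NULL, eps = NULL,
                             return_grads = FALSE) {
  br <- img_batch(real); bf <- img_batch(fake)
  if (!identical(dim(br$mat), dim(bf$mat)))
    stop("gradient_penalty: real/fake shape mismatch")
  N <- br$N; HW <- br$H * br$W
  if (is.null(eps)) eps <- stats::runif(N)
  er <- eps[grp_geom(N, HW)]
  xh <- er * br$mat + (1 - er) * bf$mat
  if (inherits(critic, "tsgan_params")) {
    r <- gp_internal_net(critic$params, critic$lrelu_slope, xh,
                         br$H, br$W, N, C)
    if (return_grads) return(list(value = r$value, grads = r$grads))
    return(r$value)
  }
  stopifnot(is.function(critic), is.function(critic_grad))
  imgs <- batch_imgs(xh, br$H, br$W, N, br$C, single = FALSE, br$chan_dim)
  pen <- vapply(imgs, function(im) {
    g <- critic_grad(im)
    (sqrt(sum(g^2) + C) - 1)^2
  }, numeric(1))
  mean(pen)
}

#' Training configuration
#'
#' Defaults follow the reported experimental settings: learning rates 5e-4
#' for coarse network, fine network and discriminator; first-moment decay
#' 0.5; batch size 8; 100 epochs; 5 critic updates per generator update;
#' gradient-penalty weight 10 and smoothing constant 1e-8.  The
#' second-moment decay (0.9) and the fine-stage L1 anchor weight
#' \code{rec_weight} are configurable choices of this implementation;
#' \code{rec_weight = 0} trains the fine stage purely adversarially.
#'
#' @param lr_coarse,lr_fine,lr_disc Adam learning rates.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size images per update.
#' @param epochs passes over the dataset (ignored when \code{steps} given).
#' @param gd_ratio discriminator updates per generator update.
#' @param gp_lambda gradient-penalty weight.
#' @param gp_smooth_C gradient-penalty smoothing constant.
#' @param rec_weight weight of the fine-stage L1 reconstruction term.
#' @param adv_weight weight of the fine-stage adversarial term.  The
#'   gradient penalty drives the critic toward unit input-gradient norm
#'   per image, i.e. a per-pixel adversarial gradient of about
#'   1/sqrt(H*W), which at small image sizes overwhelms the L1 anchor's
#'   per-pixel gradient; the default keeps the reconstruction gradient
#'   dominant by roughly an order of magnitude at 64x64 so the
#'   adversarial term refines texture rather than overriding fidelity.
#' @param steps optional explicit number of training cycles, overriding
#'   \code{epochs}; one cycle = 1 coarse update + \code{gd_ratio} critic
#'   updates + 1 fine-generator update.
#' @param seed integer seed for batch sampling and interpolation draws.
#' @return a \code{train_config} list.
#' @export
train_config <- function(lr_coarse = 5e-4, lr_fine = 5e-4, lr_disc = 5e-4,
                         beta1 = 0.5, batch_size = 8L, epochs = 100L,
                         gd_ratio = 5L, gp_lambda = 10, gp_smooth_C = 1e-8,
                         rec_weight = 100, adv_weight = 0.02, steps = NULL,
                         beta2 = 0.9, seed = 1L) {
  structure(list(lr_coarse = lr_coarse, lr_fine = lr_fine, lr_disc = lr_disc,
                 beta1 = beta1, beta2 = beta2, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), gd_ratio = as.integer(gd_ratio),
                 gp_lambda = gp_lambda, gp_smooth_C = gp_smooth_C,
                 rec_weight = rec_weight, adv_weight = adv_weight,
                 steps = if (is.null(steps)) NULL else as.integer(steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- params[[nm]] * 0
      st$v[[nm]] <- params[[nm]] * 0
    }
    # m and v are updated in place inside the kernel
    params[[nm]] <- cpp_adam(params[[nm]], g, st$m[[nm]], st$v[[nm]],
                             lr, b1, b2, bc1, bc2, eps)
  }
  params
}

node_grads <- function(pnodes) lapply(pnodes, function(nd) nd$grad)

add_grads <- function(a, b, wb = 1) {
  for (nm in names(b)) {
    if (is.null(b[[nm]])) next
    a[[nm]] <- if (is.null(a[[nm]])) wb * b[[nm]] else a[[nm]] + wb * b[[nm]]
  }
  a
}

#' Train the two-stage inpainting GAN
#'
#' Runs the two-stage training procedure on a dataset of training triplets
#' (occluded input, unoccluded target, occlusion mask).  Every cycle: the
#' coarse network is updated on the L1 loss between its output and the
#' target; the coarse output (detached, no adversarial gradient reaches the
#' coarse network) becomes the fine network's input; the critic is updated
#' \code{gd_ratio} times on the WGAN-GP loss between targets and fine
#' outputs; and the fine network takes one generator update on
#' \code{adv_weight * wgan_g_loss + rec_weight * L1}.  All optimizers are
#' Adam.  The run
#' is fully determined by the dataset and \code{config$seed}.
#'
#' @param dataset a list of triplets as produced by
#'   \code{\link{build_dataset}} (each a list with \code{occluded},
#'   \code{target}, \code{mask}), or such an object's \code{$triplets}.
#' @param config a \code{\link{train_config}}.
#' @param coarse,fine,disc \code{tsgan_params} objects (freshly initialized
#'   or resumed).
#' @param skip_mode fine-network skip variant (see \code{\link{fine_forward}}).
#' @param verbose print a progress line every 25 cycles.
#' @return a list with the trained networks (\code{coarse}, \code{fine},
#'   \code{disc}), the per-cycle loss \code{history} data frame, and the
#'   update \code{counters}.
#' @export
train <- function(dataset, config, coarse, fine, disc,
                  skip_mode = "dacc", verbose = FALSE) {
  if (!is.null(dataset$triplets)) dataset <- dataset$triplets
  n <- length(dataset)
  if (n == 0L) stop("empty dataset")
  stopifnot(inherits(config, "train_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)

  bs <- min(config$batch_size, n)
  n_steps <- if (!is.null(config$steps)) config$steps
             else config$epochs * max(1L, n %/% bs)
  sts_c <- stats_env(coarse); sts_f <- stats_env(fine)
  ad_c <- adam_new(); ad_f <- adam_new(); ad_d <- adam_new()
  pc <- coarse$params; pf <- fine$params; pd <- disc$params
  slope_d <- disc$lrelu_slope
  counters <- c(coarse = 0L, disc = 0L, gen = 0L)
  hist <- vector("list", n_steps)

  d1 <- img_batch(dataset[[1]]$target)
  H <- d1$H; W <- d1$W; Cch <- d1$C; HW <- H * W

  for (step in seq_len(n_steps)) {
    idx <- sample.int(n, bs, replace = bs > n)
    occ <- img_batch(lapply(dataset[idx], `[[`, "occluded"))$mat
    tgt <- img_batch(lapply(dataset[idx], `[[`, "target"))$mat

    ## -- coarse update: L1 against ground truth --
    tpc <- new_tape()
    pnc <- p_nodes(pc)
    xin <- new_node(occ, H, W, bs, Cch)
    cout <- coarse_net_fwd(tpc, xin, pnc, coarse, TRUE, sts_c)
    lc <- t_l1(tpc, cout, tgt)
    tp_backward(tpc, lc)
    pc <- adam_step(pc, node_grads(pnc), ad_c, config$lr_coarse,
                    config$beta1, config$beta2)
    counters["coarse"] <- counters["coarse"] + 1L
    coarse_out <- cout$v                     # detached fine-stage input

    ## -- fine forward (single tape reused for the generator update) --
    tpf <- new_tape()
    pnf <- p_nodes(pf)
    fin <- new_node(coarse_out, H, W, bs, Cch)
    fout <- fine_net_fwd(tpf, fin, pnf, fine, TRUE, sts_f, skip_mode)
    fake <- fout$v

    ## -- critic updates --
    d_loss <- gp_val <- NA_real_
    for (j in seq_len(config$gd_ratio)) {
      cr <- disc_fwd_raw(tgt, H, W, bs, pd, slope_d)
      cf <- disc_fwd_raw(fake, H, W, bs, pd, slope_d)
      gr <- disc_bwd_raw(cr, pd, rep(-1 / bs, bs), slope_d)$grads
      gf <- disc_bwd_raw(cf, pd, rep(1 / bs, bs), slope_d)$grads
      eps <- stats::runif(bs)
      xh <- eps[grp_geom(bs, HW)] * tgt + (1 - eps[grp_geom(bs, HW)]) * fake
      gp <- gp_internal_net(pd, slope_d, xh, H, W, bs, config$gp_smooth_C)
      gd <- add_grads(add_grads(gr, gf), gp$grads, config$gp_lambda)
      d_loss <- mean(cf$score) - mean(cr$score) + config$gp_lambda * gp$value
      gp_val <- gp$value
      if (!is.finite(d_loss))
        stop("non-finite discriminator loss at cycle ", step)
      pd <- adam_step(pd, gd, ad_d, config$lr_disc, config$beta1, config$beta2)
      counters["disc"] <- counters["disc"] + 1L
    }

    ## -- generator (fine) update --
    cf <- disc_fwd_raw(fake, H, W, bs, pd, slope_d)
    g_adv <- -mean(cf$score)
    dadv <- disc_bwd_raw(cf, pd, rep(-1 / bs, bs), slope_d, need_dx = TRUE)$dx
    diff <- fake - tgt
    g_rec <- mean(abs(diff))
    dfake <- config$adv_weight * dadv +
      config$rec_weight * sign(diff) / length(diff)
    fout$grad <- dfake
    tp_backward(tpf, NULL)
    pf <- adam_step(pf, node_grads(pnf), ad_f, config$lr_fine,
                    config$beta1, config$beta2)
    counters["gen"] <- counters["gen"] + 1L

    coarse_l1 <- lc$v[1, 1]
    g_total <- config$adv_weight * g_adv + config$rec_weight * g_rec
    if (!all(is.finite(c(coarse_l1, g_total))))
      stop("non-finite generator loss at cycle ", step)
    hist[[step]] <- c(step = step, coarse_l1 = coarse_l1, d_loss = d_loss,
                      gp = gp_val, g_adv = g_adv, g_rec = g_rec,
                      g_total = g_total)
    if (verbose && step %% 25L == 0L)
      message(sprintf("cycle %d: coarse L1 %.4f  d %.4f  g %.4f",
                      step, coarse_l1, d_loss, g_total))
  }

  coarse$params <- pc; coarse$stats <- sts_c$s
  fine$params <- pf; fine$stats <- sts_f$s
  disc$params <- pd
  list(coarse = coarse, fine = fine, disc = disc,
       history = as.data.frame(do.call(rbind, hist)),
       counters = counters)
}

# gp_internal taking raw params (avoids rebuilding the net object per call)
gp_internal_net <- function(p, slope, xh, H, W, N, C) {
  cx <- disc_fwd_raw(xh, H, W, N, p, slope)
  ig <- disc_input_grad(cx, p, slope)
  grp <- grp_geom(N, H * W)
  gn2 <- as.vector(rowsum(matrix(rowSums(ig$g^2)), grp))
  s <- sqrt(gn2 + C)
  fac <- (2 * (s - 1) / s) / N
  sg <- ig$g * fac[grp]
  list(value = mean((s - 1)^2), grads = disc_gp_bwd(cx, ig, p, slope, sg))
}
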