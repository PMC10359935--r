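# Objective evaluation: PSNR for reconstruction fidelity, the Frechet
# distance between Gaussian summaries of embedded image sets (FID with a
# pluggable embedding), and biometric verification metrics (ROC, EER,
# TAR at a fixed FAR) computed from genuine/impostor score sets.

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peak^2 / MSE)} between a reference image and a test
#' image.  Identical images give \code{Inf}.  For images in [0,1] use
#' \code{peak = 1}; for 8-bit integer scales use \code{peak = 255}.
#'
#' @param reference,test images (or lists of images) of identical shape.
#' @param peak maximum intensity of the scale.
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, test, peak = 1) {
  a <- img_batch(reference); b <- img_batch(test)
  if (!identical(dim(a$mat), dim(b$mat))) stop("psnr: shape mismatch")
  mse <- mean((a$mat - b$mat)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Gaussian summary of an embedded sample
#'
#' Mean vector and covariance matrix (unbiased, denominator n-1) of a set
#' of embedding vectors, the sufficient statistics compared by the
#' Frechet distance.
#'
#' @param x numeric matrix, one embedding vector per row.
#' @return a \code{gaussian_stats} list with \code{mean} and \code{cov}.
#' @export
gaussian_stats <- function(x) {
  x <- as.matrix(x)
  structure(list(mean = colMeans(x), cov = stats::cov(x)),
            class = "gaussian_stats")
}

#' Frechet distance between two Gaussian summaries
#'
#' \code{||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^(1/2))}, computed
#' through eigendecompositions of symmetrized matrices; small negative
#' eigenvalues (numerical PSD drift) are clipped at \code{-tol}, larger
#' ones raise an error.
#'
#' @param a,b \code{gaussian_stats} objects of equal dimension.
#' @param tol PSD tolerance for eigenvalue clipping.
#' @return nonnegative scalar, symmetric in its arguments.
#' @export
frechet_distance <- function(a, b, tol = 1e-8) {
  stopifnot(inherits(a, "gaussian_stats"), inherits(b, "gaussian_stats"),
            length(a$mean) == length(b$mean))
  Sa <- psd_check(a$cov, tol)
  Sb <- psd_check(b$cov, tol)
  A <- sqrtm_psd(Sa, tol)
  M <- A %*% Sb %*% A
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  sum((a$mean - b$mean)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * tr_sqrt
}

psd_check <- function(S, tol) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -tol * scale * 10) stop("covariance is not positive semidefinite")
  S
}

sqrtm_psd <- function(S, tol) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two image sets (FID)
#'
#' Embeds both image sets, summarizes each embedding cloud as a Gaussian,
#' and returns their Frechet distance.  The embedding is pluggable: the
#' default is a fixed-seed random-projection convolution stack (two
#' He-initialized 3x3 stride-2 convolutions with leaky ReLU and global
#' average pooling), suitable for relative comparisons without any
#' pre-trained weights; an Inception-grade extractor can be supplied
#' through \code{embed}.
#'
#' @param images_a,images_b lists of images (at least 2 each).
#' @param embed function mapping a list of images to an n x d matrix of
#'   embeddings; defaults to \code{default_embedding()}.
#' @return nonnegative scalar; 0 for identical sets.
#' @export
fid <- function(images_a, images_b, embed = default_embedding()) {
  stopifnot(length(images_a) >= 2L, length(images_b) >= 2L)
  frechet_distance(gaussian_stats(embed(images_a)),
                   gaussian_stats(embed(images_b)))
}

#' @rdname fid
#' @param channels image channels the embedding expects.
#' @param dim embedding dimension.
#' @param seed seed of the fixed random projection.
#' @export
default_embedding <- function(channels = 1L, dim = 16L, seed = 1234L) {
  old <- get0(".Random.seed", envir = globalenv())
  f1 <- 9L * channels
  f2 <- 9L * 8L
  set.seed(seed)
  W1 <- matrix(stats::rnorm(f1 * 8L, sd = sqrt(2 / f1)), f1, 8L)
  W2 <- matrix(stats::rnorm(f2 * dim, sd = sqrt(2 / f2)), f2, dim)
  restore_seed(old)
  function(images) {
    emb <- lapply(images, function(im) {
      b <- img_batch(im)
      h <- conv_fwd_raw(b$mat, W1, NULL, b$H, b$W, 1L, 3L, 2L)
      g1 <- conv_geom(b$H, b$W, 1L, 3L, 2L)
      h <- h * (0.2 + 0.8 * (h > 0))
      h <- conv_fwd_raw(h, W2, NULL, g1$Ho, g1$Wo, 1L, 3L, 2L)
      h <- h * (0.2 + 0.8 * (h > 0))
      colMeans(h)
    })
    do.call(rbind, emb)
  }
}

#' Genuine/impostor score sets
#'
#' Container for biometric verification scores: similarity scores of
#' same-identity pairs (genuine) and different-identity pairs (impostor).
#' Higher scores mean "more likely genuine".
#'
#' @param genuine,impostor numeric score vectors (both nonempty).
#' @return a \code{score_set}.
#' @export
score_set <- function(genuine, impostor) {
  stopifnot(length(genuine) > 0L, length(impostor) > 0L,
            all(is.finite(genuine)), all(is.finite(impostor)))
  structure(list(genuine = as.numeric(genuine),
                 impostor = as.numeric(impostor)), class = "score_set")
}

#' ROC curve, equal error rate and TAR at fixed FAR
#'
#' \code{roc} sweeps the decision threshold over all distinct scores; at
#' threshold t, FAR is the fraction of impostor scores >= t and TAR the
#' fraction of genuine scores >= t.  \code{eer} returns the rate (in
#' percent) where FAR equals FRR = 1 - TAR, linearly interpolated between
#' adjacent sweep points in (FAR, FRR) space, so it is invariant under
#' strictly monotone score transforms.  \code{tar_at_far} returns TAR (in
#' percent) at the requested FAR, linearly interpolated along the curve.
#'
#' @param scores a \code{\link{score_set}}.
#' @param far target false accept rate (fraction, default 0.001 = 0.1\%).
#' @return \code{roc}: data frame with threshold, far, tar;
#'   \code{eer}, \code{tar_at_far}: percentages.
#' @export
roc <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  th <- c(Inf, sort(unique(c(scores$genuine, scores$impostor)),
                    decreasing = TRUE), -Inf)
  far <- vapply(th, function(t) mean(scores$impostor >= t), numeric(1))
  tar <- vapply(th, function(t) mean(scores$genuine >= t), numeric(1))
  data.frame(threshold = th, far = far, tar = tar)
}

#' @rdname roc
#' @export
eer <- function(scores) {
  rc <- roc(scores)
  far <- rc$far; frr <- 1 - rc$tar
  dif <- far - frr                    # increasing along the sweep
  k <- which(dif >= 0)[1]
  if (k == 1L) return(100 * far[1])
  f1 <- far[k - 1]; f2 <- far[k]; r1 <- frr[k - 1]; r2 <- frr[k]
  den <- (r1 - f1) - (r2 - f2)
  a <- if (abs(den) < 1e-15) 0.5 else (r1 - f1) / den
  100 * (f1 + a * (f2 - f1))
}

#' @rdname roc
#' @export
tar_at_far <- function(scores, far = 0.001) {
  rc <- roc(scores)
  o <- order(rc$far, rc$tar)
  f <- rc$far[o]; t <- rc$tar[o]
  if (far >= max(f)) return(100)
  if (far <= f[1]) return(100 * t[1])
  100 * stats::approx(f, t, xout = far, ties = max)$y
}
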