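# Seeded synthetic eye-image generation: annular iris textures with the
# biological orientation pattern (radially arranged fibres near the pupil,
# circumferential furrows toward the periphery), ground-truth annulus
# masks, and the three kinds of eyelid/eyelash occlusion masks used to
# build training triplets.

#' Synthetic iris specification
#'
#' Describes one synthetic iris image: geometry (square image, annulus
#' center and radii), the texture seed, the band limit of the polar noise,
#' and \code{radial_blend}, the fraction in [0,1] controlling how strongly
#' the texture orientation interpolates from radial spokes at the pupil
#' boundary to circumferential rings at the periphery
#' (\code{radial_blend = 0} gives purely circumferential texture).
#'
#' @param image_size side length in pixels.
#' @param center (row, col) of the annulus center; defaults to the image
#'   center.
#' @param pupil_radius,iris_radius inner/outer annulus radii in pixels;
#'   defaults scale the canonical 40/100 at size 256.
#' @param texture_seed integer seed; same spec and seed give bit-identical
#'   output.
#' @param texture_scale dimensionless band limit of the polar noise.
#' @param radial_blend radial-vs-circumferential mixing fraction in [0,1].
#' @param channels 1 (NIR grayscale, default) or 3.
#' @return an \code{iris_spec} list.
#' @export
iris_spec <- function(image_size = 256L, center = NULL,
                      pupil_radius = NULL, iris_radius = NULL,
                      texture_seed = 1L, texture_scale = 8L,
                      radial_blend = 1, channels = 1L) {
  if (is.null(pupil_radius)) pupil_radius <- round(image_size * 40 / 256)
  if (is.null(iris_radius)) iris_radius <- round(image_size * 100 / 256)
  if (is.null(center)) center <- rep((image_size + 1) / 2, 2L)
  spec <- list(image_size = as.integer(image_size), center = center,
               pupil_radius = pupil_radius, iris_radius = iris_radius,
               texture_seed = as.integer(texture_seed),
               texture_scale = as.integer(texture_scale),
               radial_blend = radial_blend, channels = as.integer(channels))
  validate_iris_spec(spec)
  structure(spec, class = "iris_spec")
}

validate_iris_spec <- function(s) {
  if (!(s$pupil_radius > 0 && s$pupil_radius < s$iris_radius))
    stop("invalid radii: need 0 < pupil_radius < iris_radius")
  if (s$center[1] - s$iris_radius < 1 || s$center[1] + s$iris_radius > s$image_size ||
      s$center[2] - s$iris_radius < 1 || s$center[2] + s$iris_radius > s$image_size)
    stop("annulus does not fit inside the image")
  if (s$radial_blend < 0 || s$radial_blend > 1)
    stop("radial_blend must lie in [0,1]")
  invisible(s)
}

#' Generate a synthetic iris image and its ground-truth mask
#'
#' Band-limited noise is synthesized in polar coordinates around the
#' annulus center: a radial profile (rings, constant along circles) and an
#' angular profile (spokes, constant along rays) are mixed with a weight
#' that moves from spokes at the pupil to rings at the periphery, scaled by
#' \code{radial_blend}.  The texture is nonzero exactly on the annulus
#' \code{pupil_radius <= r <= iris_radius}; everything else (pupil, sclera)
#' is black, emulating a ground-truth-segmented, preprocessed iris image.
#'
#' @param spec an \code{\link{iris_spec}}.
#' @return list with \code{image} (H x W matrix, or H x W x 3 array, in
#'   [0,1]) and \code{mask} (H x W binary matrix: the annulus).
#' @export
generate_iris <- function(spec) {
  validate_iris_spec(spec)
  n <- spec$image_size
  rr <- matrix(seq_len(n) - spec$center[1], n, n)
  cc <- matrix(seq_len(n) - spec$center[2], n, n, byrow = TRUE)
  r <- sqrt(rr^2 + cc^2)
  th <- atan2(cc, rr)
  mask <- (r >= spec$pupil_radius & r <= spec$iris_radius) + 0
  t01 <- pmin(pmax((r - spec$pupil_radius) /
                     (spec$iris_radius - spec$pupil_radius), 0), 1)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$texture_seed)
  J <- max(1L, spec$texture_scale)
  a <- stats::rnorm(J); pha <- stats::runif(J, 0, 2 * pi)
  b <- stats::rnorm(3L * J); phb <- stats::runif(3L * J, 0, 2 * pi)

  f <- matrix(0, n, n)                       # rings: function of radius only
  for (j in seq_len(J)) f <- f + a[j] * cos(2 * pi * j * t01 + pha[j])
  g <- matrix(0, n, n)                       # spokes: function of angle only
  for (j in seq_len(3L * J)) g <- g + b[j] * cos(j * th + phb[j])

  inside <- mask > 0
  nrm <- function(z) {
    s <- stats::sd(z[inside])
    if (s < 1e-12) z else z / s
  }
  f <- nrm(f); g <- nrm(g)
  w <- spec$radial_blend * (1 - t01)         # spoke weight, fades outward
  tex <- w * g + (1 - w) * f
  img <- pmin(pmax(0.5 + 0.17 * tex, 0.03), 0.97) * mask
  if (spec$channels == 3L) img <- array(rep(img, 3L), dim = c(n, n, 3L))
  list(image = img, mask = mask)
}

#' Occlusion mask specification
#'
#' Describes one of the three occlusion kinds applied to training images:
#' an upper-eyelid arc entering from the top edge, a lower-eyelid arc
#' entering from the bottom edge, or a bundle of thin curved eyelash
#' strokes.  The realized fraction of the ground-truth iris area that the
#' mask occludes is driven into \code{coverage_range} by a bisection on the
#' mask's depth (eyelids) or stroke length (eyelashes).
#'
#' @param kind one of \code{"eyelid_upper"}, \code{"eyelid_lower"},
#'   \code{"eyelash_strokes"}.
#' @param coverage_range (lo, hi) target fraction of iris area occluded.
#' @param stroke_count number of eyelash strokes.
#' @param arc_curvature eyelid arc curvature in [0,1): 0 is a straight
#'   edge, larger values bow the arc toward the image center.
#' @param seed integer seed for the mask shape.
#' @return a \code{mask_spec} list.
#' @export
mask_spec <- function(kind = c("eyelid_upper", "eyelid_lower", "eyelash_strokes"),
                      coverage_range = c(0.1, 0.3), stroke_count = 25L,
                      arc_curvature = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(coverage_range) == 2L,
            coverage_range[1] >= 0, coverage_range[2] <= 1,
            coverage_range[1] <= coverage_range[2])
  structure(list(kind = kind, coverage_range = coverage_range,
                 stroke_count = as.integer(stroke_count),
                 arc_curvature = arc_curvature, seed = as.integer(seed)),
            class = "mask_spec")
}

#' Generate an occlusion mask over a ground-truth iris mask
#'
#' @param spec a \code{\link{mask_spec}}.
#' @param gt binary ground-truth iris mask (H x W).
#' @return binary H x W mask whose overlap fraction with \code{gt} lies in
#'   \code{spec$coverage_range}.
#' @export
generate_mask <- function(spec, gt) {
  stopifnot(inherits(spec, "mask_spec"))
  if (sum(gt) == 0) stop("ground-truth mask is empty")
  H <- nrow(gt); W <- ncol(gt)
  lo <- spec$coverage_range[1]; hi <- spec$coverage_range[2]
  if (hi == 0) return(matrix(0, H, W))
  target <- (lo + hi) / 2
  area <- sum(gt)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  if (spec$kind %in% c("eyelid_upper", "eyelid_lower")) {
    curv <- spec$arc_curvature * stats::runif(1, 0.8, 1.2)
    xoff <- stats::runif(1, -0.1, 0.1) * W
    ncol_ <- (seq_len(W) - (W + 1) / 2 - xoff) / (W / 2)
    shape <- pmax(1 - curv * ncol_^2, 0)
    build <- function(depth) {
      b <- depth * shape
      rows <- matrix(seq_len(H), H, W)
      bm <- matrix(b, H, W, byrow = TRUE)
      if (spec$kind == "eyelid_upper") (rows <= bm) + 0 else (rows > H - bm) + 0
    }
    cov_of <- function(depth) sum(build(depth) * gt) / area
    m <- bisect_coverage(cov_of, c(0, 2 * H), target)
    mask <- build(m)
  } else {
    x0 <- stats::runif(spec$stroke_count, 0.08 * W, 0.92 * W)
    d1 <- stats::rnorm(spec$stroke_count, 0, 0.35)
    q2 <- stats::rnorm(spec$stroke_count, 0, 2 / H)
    build <- function(frac) {
      mask <- matrix(0, H, W)
      L <- frac * H
      if (L < 1) return(mask)
      tt <- seq(0, L, by = 0.5)
      for (k in seq_len(spec$stroke_count)) {
        x <- x0[k] + d1[k] * tt + q2[k] * tt^2
        y <- 1 + tt
        ok <- y >= 1 & y <= H & x >= 1 & x <= W
        ri <- round(y[ok]); ci <- round(x[ok])
        mask[cbind(ri, ci)] <- 1
        ci2 <- pmin(ci + 1L, W)
        mask[cbind(ri, ci2)] <- 1
      }
      mask
    }
    cov_of <- function(frac) sum(build(frac) * gt) / area
    m <- bisect_coverage(cov_of, c(0, 1.5), target)
    mask <- build(m)
  }
  cov <- sum(mask * gt) / area
  if (cov < lo || cov > hi)
    stop(sprintf("coverage_range (%.3g, %.3g) infeasible for this mask shape (closest %.3g)",
                 lo, hi, cov))
  mask
}

# monotone bisection of cov_of(x) toward `target`
bisect_coverage <- function(cov_of, range, target, iters = 50L) {
  loX <- range[1]; hiX <- range[2]
  if (cov_of(hiX) < target) return(hiX)
  for (i in seq_len(iters)) {
    mid <- (loX + hiX) / 2
    if (cov_of(mid) < target) loX <- mid else hiX <- mid
  }
  hiX
}

#' Apply an occlusion mask to a target image
#'
#' Logical combination of image and binary mask: the output equals the
#' target wherever the mask is 0 and is black (0) wherever the mask is 1.
#'
#' @param target image (H x W matrix or H x W x C array) in [0,1].
#' @param mask binary H x W occlusion mask.
#' @return occluded image of the same shape.
#' @export
apply_occlusion <- function(target, mask) {
  d <- dim(target)
  if (!identical(as.integer(d[1:2]), as.integer(dim(mask))))
    stop("apply_occlusion: shape mismatch")
  keep <- 1 - mask
  if (length(d) == 3L) {
    out <- target
    for (ch in seq_len(d[3])) out[, , ch] <- target[, , ch] * keep
    out
  } else target * keep
}

#' Deterministic 8-fold augmentation
#'
#' The eight expansion modes applied to each base image: clockwise and
#' counterclockwise rotation (default +/- 10 degrees, bilinear, zeros
#' outside), horizontal flip, shift-with-crop toward each of up / down /
#' left / right (a window displaced by \code{shift} of the side length,
#' resized back), and a center crop at \code{crop_ratio} resized back.
#' Every mode returns an image of the input's size.
#'
#' @param image H x W matrix or H x W x C array.
#' @param mode integer 1..8 or one of \code{"rot_cw"}, \code{"rot_ccw"},
#'   \code{"hflip"}, \code{"shift_up"}, \code{"shift_down"},
#'   \code{"shift_left"}, \code{"shift_right"}, \code{"center_crop"}.
#' @param angle rotation magnitude in degrees for the two rotation modes.
#' @param shift shift fraction of the side length.
#' @param crop_ratio center-crop window fraction.
#' @param binary threshold the interpolated result at 0.5 (for masks).
#' @return augmented image of identical shape.
#' @export
augment <- function(image, mode, angle = 10, shift = 0.1, crop_ratio = 0.9,
                    binary = FALSE) {
  modes <- c("rot_cw", "rot_ccw", "hflip", "shift_up", "shift_down",
             "shift_left", "shift_right", "center_crop")
  if (is.numeric(mode)) {
    if (!(mode %in% 1:8)) stop("mode must be in 1..8")
    mode <- modes[mode]
  } else mode <- match.arg(mode, modes)
  f <- function(m) augment_plane(m, mode, angle, shift, crop_ratio)
  out <- apply_planes(image, f)
  if (binary) out <- round_binary(out)
  out
}

apply_planes <- function(image, f) {
  d <- dim(image)
  if (length(d) == 3L) {
    planes <- lapply(seq_len(d[3]), function(ch) f(image[, , ch]))
    array(unlist(planes), dim = c(dim(planes[[1]]), d[3]))
  } else f(image)
}

round_binary <- function(x) (x >= 0.5) + 0

augment_plane <- function(m, mode, angle, shift, crop_ratio) {
  H <- nrow(m); W <- ncol(m)
  s <- max(1L, round(shift * H))
  switch(mode,
    rot_cw = rotate_bilinear(m, -angle),
    rot_ccw = rotate_bilinear(m, angle),
    hflip = m[, W:1, drop = FALSE],
    shift_up = resize_plane(m[(s + 1):H, , drop = FALSE], H, W),
    shift_down = resize_plane(m[1:(H - s), , drop = FALSE], H, W),
    shift_left = resize_plane(m[, (s + 1):W, drop = FALSE], H, W),
    shift_right = resize_plane(m[, 1:(W - s), drop = FALSE], H, W),
    center_crop = {
      h2 <- round(H * crop_ratio); w2 <- round(W * crop_ratio)
      r0 <- (H - h2) %/% 2L; c0 <- (W - w2) %/% 2L
      resize_plane(m[(r0 + 1):(r0 + h2), (c0 + 1):(c0 + w2), drop = FALSE], H, W)
    })
}

# rotation about the image center, bilinear sampling, zeros outside
rotate_bilinear <- function(m, angle_deg) {
  H <- nrow(m); W <- ncol(m)
  a <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gr <- matrix(seq_len(H) - cy, H, W)
  gc <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  sr <- cos(a) * gr + sin(a) * gc + cy      # inverse rotation
  sc <- -sin(a) * gr + cos(a) * gc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) + (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) + fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, H, W)
}

#' Build a triplet dataset with the 8 x 3 expansion scheme
#'
#' From \code{n_base} seeded synthetic irises, applies the 8 augmentation
#' modes and the 3 occlusion-mask kinds, yielding exactly \code{24 *
#' n_base} training triplets (occluded input, unoccluded target, occlusion
#' mask).  Fully deterministic given \code{seed}.
#'
#' @param n_base number of base iris images.
#' @param image_size side length in pixels.
#' @param seed master seed; per-image and per-mask seeds are derived from it.
#' @param coverage_range occlusion coverage range passed to
#'   \code{\link{mask_spec}}.
#' @param radial_blend,texture_scale passed to \code{\link{iris_spec}}.
#' @param channels image channels.
#' @return an \code{iris_dataset}: list with \code{triplets} (each a list
#'   \code{occluded}, \code{target}, \code{mask}, plus provenance fields)
#'   and a \code{manifest} data frame.
#' @export
build_dataset <- function(n_base = 4L, image_size = 64L, seed = 1L,
                          coverage_range = c(0.1, 0.3), radial_blend = 1,
                          texture_scale = 8L, channels = 1L) {
  kinds <- c("eyelid_upper", "eyelid_lower", "eyelash_strokes")
  triplets <- list()
  rows <- list()
  id <- 0L
  for (i in seq_len(n_base)) {
    sp <- iris_spec(image_size, texture_seed = seed * 1000L + i,
                    texture_scale = texture_scale,
                    radial_blend = radial_blend, channels = channels)
    base <- generate_iris(sp)
    for (m in 1:8) {
      img_a <- augment(base$image, m)
      gt_a <- augment(base$mask, m, binary = TRUE)
      for (kk in seq_along(kinds)) {
        id <- id + 1L
        mseed <- seed * 100000L + i * 1000L + m * 10L + kk
        msk <- generate_mask(mask_spec(kinds[kk], coverage_range,
                                       seed = mseed), gt_a)
        triplets[[id]] <- list(occluded = apply_occlusion(img_a, msk),
                               target = img_a, mask = msk, gt = gt_a,
                               id = id, mask_kind = kinds[kk],
                               augmentation_mode = m, seed = mseed)
        rows[[id]] <- data.frame(id = id, mask_kind = kinds[kk],
                                 augmentation_mode = m, seed = mseed)
      }
    }
  }
  structure(list(triplets = triplets, manifest = do.call(rbind, rows),
                 image_size = as.integer(image_size)),
            class = "iris_dataset")
}
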