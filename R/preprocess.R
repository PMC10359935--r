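# Iris image preprocessing: ground-truth-guided segmentation, non-iris
# crop, four-direction extent measurement, centering pad, and resize.
# The aim is to place the pupil at the image center and raise the iris
# foreground proportion before inpainting.

#' Segment an acquired image by its ground-truth mask
#'
#' Pixel-wise logical combination: the acquired intensity is kept where
#' the binary ground-truth iris mask is 1 and zeroed elsewhere, giving an
#' iris-only image on a black background.
#'
#' @param acquired H x W matrix or H x W x C array in [0,1].
#' @param gt binary H x W mask.
#' @return image of the same shape as \code{acquired}.
#' @export
segment_by_gt <- function(acquired, gt) {
  d <- dim(acquired)
  if (!identical(as.integer(d[1:2]), as.integer(dim(gt))))
    stop("segment_by_gt: shape mismatch")
  apply_planes(acquired, function(m) m * gt)
}

#' Crop away the non-iris border
#'
#' Crops image and mask to the tight bounding box of the mask's nonzero
#' pixels.
#'
#' @inheritParams segment_by_gt
#' @return list with cropped \code{image} and \code{mask}.
#' @export
crop_noniris <- function(image, gt) {
  if (sum(gt) == 0) stop("crop_noniris: empty ground-truth mask")
  rs <- range(which(rowSums(gt) > 0))
  cs <- range(which(colSums(gt) > 0))
  list(image = apply_planes(image, function(m) m[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]),
       mask = gt[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE])
}

#' Measure iris extents in the four directions
#'
#' Finds the pupil (the interior hole of the annulus-like mask) and walks
#' the horizontal and vertical rays through its centroid.  In each
#' direction i (top, bottom, left, right), \code{d[i]} counts the mask
#' pixels along the ray — the iris annulus width — and \code{x[i]} is the
#' distance from the inner iris border crossing to the image border.
#'
#' @param gt binary mask containing an annulus-like region with an
#'   interior hole.
#' @return an \code{iris_extents} object: list with \code{d}, \code{x}
#'   (named numeric vectors over top/bottom/left/right) and the hole
#'   \code{center} (row, col).
#' @export
measure_extents <- function(gt) {
  H <- nrow(gt); W <- ncol(gt)
  bg <- EBImage::bwlabel(EBImage::Image(t(1 - gt)))
  lab <- t(EBImage::imageData(bg))
  border_labels <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  hole <- lab > 0 & !(lab %in% border_labels)
  if (!any(hole)) stop("no interior hole detectable in mask")
  idx <- which(hole, arr.ind = TRUE)
  r0 <- round(mean(idx[, 1])); c0 <- round(mean(idx[, 2]))
  ray <- function(vals) {
    # vals: mask values from the center outward to the border
    d <- sum(vals == 1)
    k <- which(vals == 1)[1]
    x <- if (is.na(k)) 0 else length(vals) - k + 1
    c(d, x)
  }
  up <- ray(gt[r0:1, c0])
  down <- ray(gt[r0:H, c0])
  left <- ray(gt[r0, c0:1])
  right <- ray(gt[r0, c0:W])
  structure(list(d = c(top = up[1], bottom = down[1],
                       left = left[1], right = right[1]),
                 x = c(top = up[2], bottom = down[2],
                       left = left[2], right = right[2]),
                 center = c(row = r0, col = c0)),
            class = "iris_extents")
}

#' Pad the background to center the pupil
#'
#' Adds \code{max(d) - x + c} black background pixels on each of the four
#' sides (clamped at zero), which equalizes the distance from the inner
#' iris border to the image border in all directions and hence centers the
#' pupil up to rasterization.
#'
#' @param image image to pad.
#' @param extents an \code{iris_extents} from \code{\link{measure_extents}}.
#' @param c constant extra margin in pixels (default 20).
#' @return padded image.
#' @export
center_pad <- function(image, extents, c = 20) {
  stopifnot(inherits(extents, "iris_extents"))
  M <- max(extents$d)
  p <- pmax(round(M - extents$x + c), 0)     # top, bottom, left, right
  apply_planes(image, function(m) {
    out <- matrix(0, nrow(m) + p[1] + p[2], ncol(m) + p[3] + p[4])
    out[(p[1] + 1):(p[1] + nrow(m)), (p[3] + 1):(p[3] + ncol(m))] <- m
    out
  })
}

#' Resize to the network input size
#'
#' Bilinear resize to a square \code{out_size} (default 256), the unified
#' input size of the repair networks.
#'
#' @param image image to resize.
#' @param out_size output side length.
#' @return resized image.
#' @export
standardize <- function(image, out_size = 256L) {
  resize_image(image, out_size, out_size)
}

#' Full preprocessing pipeline
#'
#' Composition of \code{\link{segment_by_gt}}, \code{\link{crop_noniris}},
#' \code{\link{measure_extents}}, \code{\link{center_pad}} and
#' \code{\link{standardize}}, applied consistently to the acquired image
#' and its ground-truth mask.  The result is a pupil-centered, iris-only
#' square image with its matching mask.
#'
#' @inheritParams segment_by_gt
#' @param c centering-pad margin in pixels.
#' @param out_size output side length.
#' @return list with \code{image}, \code{mask} (binary, thresholded after
#'   the bilinear resize) and the measured \code{extents}.
#' @export
preprocess_pipeline <- function(acquired, gt, c = 20, out_size = 256L) {
  seg <- segment_by_gt(acquired, gt)
  cr <- crop_noniris(seg, gt)
  ext <- measure_extents(cr$mask)
  img_p <- center_pad(cr$image, ext, c)
  msk_p <- center_pad(cr$mask, ext, c)
  list(image = standardize(img_p, out_size),
       mask = round_binary(standardize(msk_p, out_size)),
       extents = ext)
}
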