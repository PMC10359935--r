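# Image and dataset I/O.  Images live in memory as H x W matrices (or
# H x W x C arrays) of intensities in [0,1] and on disk as 8-bit PNG.
# EBImage stores images transposed (x, y), so every call is wrapped.

#' Read / write images and masks
#'
#' 8-bit PNG I/O for images in [0,1] and binary masks.  Multi-channel PNGs
#' are read as H x W x C arrays (an alpha channel is dropped);
#' \code{read_mask} thresholds at 0.5.
#'
#' @param path PNG file path.
#' @param image H x W matrix or H x W x C array in [0,1].
#' @param mask binary H x W matrix.
#' @return \code{read_image}: matrix/array in [0,1]; \code{read_mask}:
#'   binary matrix.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  a
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) round_binary(read_image(path))

#' @rdname read_image
#' @export
write_mask <- function(mask, path) write_image(mask, path)

# bilinear resize of one plane to target size
resize_plane <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  r <- EBImage::resize(EBImage::Image(t(m)), w = W, h = H)
  t(EBImage::imageData(r))
}

resize_image <- function(image, H, W) apply_planes(image, function(m) resize_plane(m, H, W))

#' Write / read a triplet dataset as a directory tree
#'
#' Lays out an \code{iris_dataset} as \code{occluded/}, \code{target/} and
#' \code{mask/} PNG directories plus a tab-separated \code{manifest.tsv}
#' with columns id, mask_kind, augmentation_mode, seed.
#'
#' @param ds an \code{iris_dataset} from \code{\link{build_dataset}}.
#' @param dir output directory (created if missing).
#' @return \code{read_dataset} returns an \code{iris_dataset}.
#' @export
write_dataset <- function(ds, dir) {
  for (sub in c("occluded", "target", "mask"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (tr in ds$triplets) {
    fn <- sprintf("%05d.png", tr$id)
    write_image(tr$occluded, file.path(dir, "occluded", fn))
    write_image(tr$target, file.path(dir, "target", fn))
    write_mask(tr$mask, file.path(dir, "mask", fn))
  }
  utils::write.table(ds$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  triplets <- lapply(seq_len(nrow(man)), function(i) {
    fn <- sprintf("%05d.png", man$id[i])
    list(occluded = read_image(file.path(dir, "occluded", fn)),
         target = read_image(file.path(dir, "target", fn)),
         mask = read_mask(file.path(dir, "mask", fn)),
         id = man$id[i], mask_kind = man$mask_kind[i],
         augmentation_mode = man$augmentation_mode[i], seed = man$seed[i])
  })
  sz <- nrow(triplets[[1]]$target)
  structure(list(triplets = triplets, manifest = man, image_size = sz),
            class = "iris_dataset")
}

#' Run configuration files
#'
#' A run configuration merges training settings with synthetic-data
#' defaults, paths and the global seed, and round-trips through YAML
#' bit-exactly for reproducible command-line runs.
#'
#' @param path YAML file path.
#' @param config a named list (e.g. from \code{\link{default_run_config}}).
#' @return \code{read_run_config}: the merged configuration list.
#' @export
default_run_config <- function() {
  tr <- unclass(train_config())
  tr <- tr[!vapply(tr, is.null, TRUE)]      # YAML cannot carry NULL fields
  list(seed = 1L,
       train = tr,
       data = list(n_base = 4L, image_size = 64L,
                   coverage_range = c(0.1, 0.3), radial_blend = 1,
                   texture_scale = 8L, channels = 1L),
       net = list(width_div = 4L, skip_mode = "dacc", lrelu_slope = 0.2,
                  se_r = 16L))
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  cfg$train <- utils::modifyList(base$train, cfg$train %||% list())
  cfg$data <- utils::modifyList(base$data, cfg$data %||% list())
  cfg$net <- utils::modifyList(base$net, cfg$net %||% list())
  cfg$seed <- cfg$seed %||% base$seed
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
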