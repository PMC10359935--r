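test_that("segmentation by ground truth masks the acquired image", {
  img <- matrix(0.7, 32, 32)
  ann <- annulus_mask(32, c(16, 16), 5, 12)
  expect_identical(segment_by_gt(img, matrix(1, 32, 32)), img)
  seg <- segment_by_gt(img, ann)
  expect_true(all(seg[ann == 1] == 0.7) && all(seg[ann == 0] == 0))
  expect_identical(segment_by_gt(img, matrix(0, 32, 32)), matrix(0, 32, 32))
  expect_error(segment_by_gt(img, matrix(1, 8, 8)), "shape")
})

test_that("cropping matches the brute-force bounding box of the mask", {
  gt <- annulus_mask(256, c(129, 129), 40, 100)
  img <- matrix(runif(256^2), 256, 256)
  # oracle bounding box by pixel scan
  nz <- which(gt == 1, arr.ind = TRUE)
  bb <- c(diff(range(nz[, 1])) + 1, diff(range(nz[, 2])) + 1)
  cr <- crop_noniris(img, gt)
  expect_identical(dim(cr$mask), as.integer(bb))
  expect_identical(dim(cr$mask), c(201L, 201L))
  full <- matrix(1, 16, 16)
  expect_identical(crop_noniris(full, full)$mask, full)
  single <- matrix(0, 16, 16); single[5, 9] <- 1
  expect_identical(dim(crop_noniris(single, single)$mask), c(1L, 1L))
  expect_error(crop_noniris(img, matrix(0, 256, 256)), "empty")
})

# independent ray-walk oracle from a given center
ray_oracle <- function(gt, r0, c0) {
  H <- nrow(gt); W <- ncol(gt)
  walk <- function(vals) {
    d <- sum(vals == 1)
    k <- which(vals == 1)[1]
    c(d, if (is.na(k)) 0 else length(vals) - k + 1)
  }
  rbind(top = walk(gt[r0:1, c0]), bottom = walk(gt[r0:H, c0]),
        left = walk(gt[r0, c0:1]), right = walk(gt[r0, c0:W]))
}

test_that("extent measurement matches the ray-walk oracle", {
  gt <- crop_noniris(annulus_mask(256, c(129, 129), 40, 100),
                     annulus_mask(256, c(129, 129), 40, 100))$mask
  ext <- measure_extents(gt)
  orc <- ray_oracle(gt, 101, 101)
  expect_true(all(abs(ext$d - orc[, 1]) <= 1))
  expect_true(all(abs(ext$x - orc[, 2]) <= 1))
  expect_true(all(abs(ext$d - 60) <= 1) && all(abs(ext$x - 60) <= 1))
})

test_that("a shifted pupil is reflected in the directional extents", {
  gt <- matrix(0, 256, 256)
  for (r in 1:256) for (c in 1:256) {
    ro <- sqrt((r - 129)^2 + (c - 129)^2)
    rp <- sqrt((r - 119)^2 + (c - 129)^2)     # pupil shifted up 10 px
    if (ro <= 100 && rp > 40) gt[r, c] <- 1
  }
  ext <- measure_extents(crop_noniris(gt, gt)$mask)
  expect_lt(abs(ext$d["top"] - 50), 2)
  expect_lt(abs(ext$d["bottom"] - 70), 2)
  expect_lt(abs(ext$d["left"] - 60), 2)
  expect_lt(abs(ext$d["right"] - 60), 2)
  expect_error(measure_extents(matrix(1, 32, 32)), "hole")
})

test_that("center_pad follows max(d) - x + c on each side", {
  ext <- structure(list(d = c(top = 50, bottom = 70, left = 60, right = 60),
                        x = c(top = 50, bottom = 70, left = 60, right = 60),
                        center = c(row = 1, col = 1)),
                   class = "iris_extents")
  img <- matrix(1, 10, 10)
  out <- center_pad(img, ext, c = 20)
  # pads: 70-50+20, 70-70+20, 70-60+20, 70-60+20 = (40, 20, 30, 30)
  expect_identical(dim(out), c(10L + 40L + 20L, 10L + 30L + 30L))
  expect_identical(out[41:50, 31:40], img)
  ext0 <- structure(list(d = c(top = 60, bottom = 60, left = 60, right = 60),
                         x = c(top = 60, bottom = 60, left = 60, right = 60),
                         center = c(row = 1, col = 1)),
                    class = "iris_extents")
  expect_identical(center_pad(img, ext0, c = 0), img)
  out20 <- center_pad(img, ext0, c = 20)
  expect_identical(dim(out20), c(50L, 50L))
})

test_that("standardize resizes to the unified square size", {
  img <- matrix(runif(201 * 201), 201, 201)
  expect_identical(dim(standardize(img)), c(256L, 256L))
  cst <- matrix(0.25, 77, 33)
  expect_lt(max(abs(standardize(cst, 64) - 0.25)), 1e-9)
})

test_that("the full pipeline centers the pupil and standardizes the size", {
  for (ctr in list(c(120, 135), c(129, 129))) {
    sp <- iris_spec(256, center = ctr, pupil_radius = 35, iris_radius = 95,
                    texture_seed = 4)
    g <- generate_iris(sp)
    pp <- preprocess_pipeline(g$image, g$mask, c = 20)
    expect_identical(dim(pp$image), c(256L, 256L))
    ctr2 <- unname(measure_extents(pp$mask)$center)
    expect_true(all(abs(ctr2 - 128.5) <= 2))
  }
})

test_that("pipeline geometry converges under reapplication; foreground grows", {
  sp <- iris_spec(256, pupil_radius = 30, iris_radius = 80, texture_seed = 8)
  g <- generate_iris(sp)
  p1 <- preprocess_pipeline(g$image, g$mask, c = 20)
  p2 <- preprocess_pipeline(p1$image, p1$mask, c = 20)
  p3 <- preprocess_pipeline(p2$image, p2$mask, c = 20)
  # reapplication contracts the geometry toward the rescale fixed point:
  # each pass moves the annulus widths less than the one before, and by
  # the third pass the change is within rasterization tolerance
  e1 <- measure_extents(p1$mask); e2 <- measure_extents(p2$mask)
  e3 <- measure_extents(p3$mask)
  expect_lt(max(abs(e3$d - e2$d)), max(abs(e2$d - e1$d)))
  expect_true(all(abs(e3$d - e2$d) <= 2))
  expect_true(all(abs(e3$x - e2$x) <= 2))
  # margin around the iris is ~48 px > c = 20, so foreground must grow
  expect_gt(mean(p1$mask), mean(g$mask))
})
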