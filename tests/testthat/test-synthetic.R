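test_that("iris generation is deterministic and validates its geometry", {
  sp <- iris_spec(128, texture_seed = 11)
  expect_identical(generate_iris(sp), generate_iris(sp))
  expect_error(iris_spec(128, pupil_radius = 50, iris_radius = 40), "radii")
  expect_error(iris_spec(128, pupil_radius = 10, iris_radius = 70), "fit")
})

test_that("annulus mask equals the per-pixel radius scan", {
  sp <- iris_spec(256, center = c(129, 129), pupil_radius = 40,
                  iris_radius = 100, texture_seed = 5)
  g <- generate_iris(sp)
  oracle <- annulus_mask(256, c(129, 129), 40, 100)
  expect_identical(g$mask, oracle)
  # texture strictly inside the annulus, zero outside
  expect_true(all(g$image[oracle == 0] == 0))
  expect_true(all(g$image[oracle == 1] > 0))
})

test_that("radial_blend = 0 gives circumferential texture", {
  sp <- iris_spec(256, center = c(129, 129), pupil_radius = 40,
                  iris_radius = 100, texture_seed = 3, radial_blend = 0)
  img <- generate_iris(sp)$image
  set.seed(42)
  vc <- vr <- numeric(100)
  for (k in 1:100) {
    ang <- seq(0, 2 * pi, length.out = 200)
    rad <- runif(1, 45, 95)
    vc[k] <- var(img[cbind(round(129 + rad * cos(ang)),
                           round(129 + rad * sin(ang)))])
    th <- runif(1, 0, 2 * pi)
    rads <- seq(45, 95, length.out = 200)
    vr[k] <- var(img[cbind(round(129 + rads * cos(th)),
                           round(129 + rads * sin(th)))])
  }
  expect_lt(mean(vc), mean(vr))
})

test_that("occlusion masks hit their coverage range for every kind and seed", {
  gt <- generate_iris(iris_spec(128, texture_seed = 1))$mask
  for (kind in c("eyelid_upper", "eyelid_lower", "eyelash_strokes")) {
    covs <- vapply(1:50, function(s) {
      m <- generate_mask(mask_spec(kind, c(0.1, 0.3), seed = s), gt)
      sum(m * gt) / sum(gt)
    }, numeric(1))
    expect_true(all(covs >= 0.1 & covs <= 0.3), label = kind)
  }
})

test_that("eyelid masks enter from their edge; degenerate ranges behave", {
  gt <- generate_iris(iris_spec(128, texture_seed = 2))$mask
  up <- generate_mask(mask_spec("eyelid_upper", c(0.1, 0.3), seed = 3), gt)
  occ_rows <- which(rowSums(up) > 0)
  expect_identical(occ_rows, seq_len(max(occ_rows)))  # contiguous from top
  expect_identical(generate_mask(mask_spec("eyelid_upper", c(0, 0)), gt),
                   matrix(0, 128, 128))
  expect_error(generate_mask(mask_spec("eyelid_upper"), matrix(0, 8, 8)),
               "empty")
})

test_that("apply_occlusion is the masked logical combination", {
  img <- matrix(0.5, 8, 8)
  expect_identical(apply_occlusion(img, matrix(0, 8, 8)), img)
  expect_identical(apply_occlusion(img, matrix(1, 8, 8)), matrix(0, 8, 8))
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  out <- apply_occlusion(img, chk)
  expect_true(all(out[chk == 1] == 0) && all(out[chk == 0] == 0.5))
  expect_error(apply_occlusion(img, matrix(0, 4, 4)), "shape")
})

test_that("the eight augmentation modes are involutive/distinct as stated", {
  img <- generate_iris(iris_spec(64, texture_seed = 9))$image
  expect_identical(augment(augment(img, "hflip"), "hflip"), img)
  outs <- lapply(1:8, function(m) augment(img, m))
  for (i in 1:7) for (j in (i + 1):8)
    expect_gt(max(abs(outs[[i]] - outs[[j]])), 1e-6)
  cst <- matrix(0.5, 64, 64)
  expect_lt(max(abs(augment(cst, "center_crop") - cst)), 1e-9)
  expect_error(augment(img, 9), "mode")
})

test_that("dataset builder yields 24n valid triplets", {
  ds <- build_dataset(n_base = 2, image_size = 64, seed = 7)
  expect_length(ds$triplets, 48)
  expect_equal(nrow(ds$manifest), 48)
  # triplet invariants on a sample of generated triplets
  set.seed(1)
  for (tr in ds$triplets[sample(48, 20)]) {
    expect_true(all(tr$occluded[tr$mask == 1] == 0))
    expect_identical(tr$occluded[tr$mask == 0], tr$target[tr$mask == 0])
  }
  expect_identical(build_dataset(n_base = 1, image_size = 64, seed = 3),
                   build_dataset(n_base = 1, image_size = 64, seed = 3))
})

test_that("datasets round-trip through the directory layout", {
  ds <- build_dataset(n_base = 1, image_size = 32, seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back$triplets, 24)
  # 8-bit quantization on disk
  expect_lt(max(abs(back$triplets[[1]]$target - ds$triplets[[1]]$target)),
            1 / 255)
  expect_identical(back$triplets[[5]]$mask, ds$triplets[[5]]$mask)
})
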