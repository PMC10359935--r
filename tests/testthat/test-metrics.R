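test_that("PSNR follows its closed form and degenerate cases", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(psnr(img, img), Inf)
  # 8-bit images differing by 16 everywhere
  a <- matrix(100, 8, 8); b <- matrix(116, 8, 8)
  expect_equal(psnr(a, b, peak = 255), 10 * log10(255^2 / 256),
               tolerance = 1e-12)
  expect_equal(psnr(matrix(0, 4, 4), matrix(1, 4, 4), peak = 1), 0)
  expect_error(psnr(img, matrix(0, 4, 4)), "shape")
})

test_that("PSNR decreases monotonically with the noise level", {
  set.seed(3)
  img <- matrix(runif(32 * 32, 0.2, 0.8), 32, 32)
  vals <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08), function(s)
    psnr(img, img + matrix(rnorm(1024, 0, s), 32, 32)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("Frechet distance matches 1-D and diagonal closed forms", {
  gs <- function(m, S) structure(list(mean = m, cov = S),
                                 class = "gaussian_stats")
  a <- gs(1, matrix(4, 1, 1)); b <- gs(3, matrix(9, 1, 1))
  expect_equal(frechet_distance(a, b), (1 - 3)^2 + (2 - 3)^2,
               tolerance = 1e-8)
  # diagonal covariances
  va <- c(1, 4, 9); vb <- c(4, 4, 1); ma <- c(0, 1, 2); mb <- c(1, 0, 2)
  want <- sum((ma - mb)^2 + (sqrt(va) - sqrt(vb))^2)
  expect_equal(frechet_distance(gs(ma, diag(va)), gs(mb, diag(vb))), want,
               tolerance = 1e-8)
  # symmetry, identity, nonnegativity on random PSD pairs
  set.seed(4)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(16), 4)); B <- crossprod(matrix(rnorm(16), 4))
    x <- gs(rnorm(4), A); y <- gs(rnorm(4), B)
    expect_equal(frechet_distance(x, y), frechet_distance(y, x),
                 tolerance = 1e-6)
    expect_gte(frechet_distance(x, y), -1e-8)
    expect_lt(abs(frechet_distance(x, x)), 1e-8)
  }
  bad <- gs(c(0, 0), matrix(c(1, 2, 2, 1), 2))   # eigenvalues 3, -1
  expect_error(frechet_distance(bad, gs(c(0, 0), diag(2))), "semidefinite")
})

test_that("Frechet distance agrees with pracma's matrix square root", {
  set.seed(14)
  A <- crossprod(matrix(rnorm(25), 5)); B <- crossprod(matrix(rnorm(25), 5))
  ma <- rnorm(5); mb <- rnorm(5)
  gs <- function(m, S) structure(list(mean = m, cov = S),
                                 class = "gaussian_stats")
  S <- pracma::sqrtm(A %*% B)$B
  want <- sum((ma - mb)^2) + sum(diag(A + B - 2 * S))
  expect_equal(frechet_distance(gs(ma, A), gs(mb, B)), Re(want),
               tolerance = 1e-6)
})

test_that("FID is zero on identical sets, positive on perturbed ones, and
           matches the closed form under a linear embedding", {
  set.seed(5)
  imgs <- lapply(1:12, function(i) matrix(runif(16 * 16), 16, 16))
  expect_lt(abs(fid(imgs, imgs)), 1e-8)
  imgs2 <- imgs; imgs2[[1]] <- matrix(runif(16 * 16), 16, 16)
  expect_gt(fid(imgs, imgs2), 0)
  # identity embedding on 2-pixel images: FID = Frechet distance of the
  # empirical Gaussian summaries
  emb <- function(images) t(vapply(images, function(im) as.vector(im)[1:2],
                                   numeric(2)))
  sa <- lapply(1:200, function(i) matrix(rnorm(2, 0, 1), 1, 2))
  sb <- lapply(1:200, function(i) matrix(rnorm(2, 1, 2), 1, 2))
  got <- fid(sa, sb, embed = emb)
  want <- frechet_distance(gaussian_stats(emb(sa)), gaussian_stats(emb(sb)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("ROC sweep matches brute-force threshold enumeration", {
  g <- c(0.9, 0.8, 0.4); im <- c(0.7, 0.3, 0.2)
  rc <- roc(score_set(g, im))
  orc <- roc_enum(g, im)
  expect_equal(rc$far, unname(orc[, "far"]))
  expect_equal(rc$tar, unname(orc[, "tar"]))
  expect_true(all(diff(rc$tar) >= 0) && all(diff(rc$far) >= 0))
  expect_error(score_set(numeric(0), im), "length")
})

test_that("EER and TAR match enumeration oracles and their limits", {
  g <- c(0.9, 0.8, 0.4); im <- c(0.7, 0.3, 0.2)
  sc <- score_set(g, im)
  expect_equal(eer(sc), eer_enum(g, im))
  expect_equal(tar_at_far(sc, 1 / 3), tar_enum(g, im, 1 / 3))
  expect_equal(eer(score_set(rep(1, 5), rep(0, 5))), 0)
  expect_equal(eer(score_set(1:20, 1:20)), 50, tolerance = 1e-9)
  expect_equal(tar_at_far(score_set(rep(1, 5), rep(0, 5)), 0.001), 100)
  expect_equal(tar_at_far(sc, 1), 100)
  # random score sets against the oracles
  set.seed(6)
  for (i in 1:10) {
    gg <- rnorm(30, 1); ii <- rnorm(40)
    s2 <- score_set(gg, ii)
    expect_equal(eer(s2), eer_enum(gg, ii), tolerance = 1e-10)
    expect_equal(tar_at_far(s2, 0.05), tar_enum(gg, ii, 0.05),
                 tolerance = 1e-10)
  }
})

test_that("EER and TAR are invariant under strictly monotone transforms", {
  set.seed(7)
  g <- rnorm(40, 1.2); im <- rnorm(60)
  sc <- score_set(g, im)
  for (f in list(function(x) 3 * x + 2, function(x) exp(x),
                 function(x) atan(x))) {
    sc2 <- score_set(f(g), f(im))
    expect_equal(eer(sc2), eer(sc), tolerance = 1e-9)
    expect_equal(tar_at_far(sc2, 0.02), tar_at_far(sc, 0.02),
                 tolerance = 1e-9)
  }
})
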