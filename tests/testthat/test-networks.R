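test_that("He initialization is seeded, distinct across seeds, and scaled", {
  a <- init_params("fine", width_div = 8, seed = 5)
  b <- init_params("fine", width_div = 8, seed = 5)
  c3 <- init_params("fine", width_div = 8, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$params, c3$params))
  # empirical std within 10% of sqrt(2 / fan_in) for a large layer
  d <- init_params("discriminator", seed = 7)     # full widths
  W <- d$params[["c6.W"]]                          # fan_in 25*512 = 12800
  expect_lt(abs(sd(W) - sqrt(2 / (25 * 512))) / sqrt(2 / (25 * 512)), 0.1)
  # biases zero, BN at gain 1 / bias 0
  expect_true(all(d$params[["c1.b"]] == 0))
  expect_true(all(a$params[["e1.g"]] == 1) && all(a$params[["e1.be"]] == 0))
})

test_that("generator forwards preserve size and range; bad sizes error", {
  coarse <- init_params("coarse", width_div = 16, seed = 1)
  fine <- init_params("fine", width_div = 16, seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  yc <- coarse_forward(x, coarse)
  yf <- fine_forward(x, fine)
  expect_identical(dim(yc), dim(x))
  expect_identical(dim(yf), dim(x))
  expect_true(all(yc >= 0 & yc <= 1) && all(yf >= 0 & yf <= 1))
  expect_error(coarse_forward(matrix(0, 24, 24), coarse), "divisible by 16")
  expect_error(fine_forward(matrix(0, 48, 48), fine), "divisible by 32")
  # repeated inference is bit-identical
  expect_identical(coarse_forward(x, coarse), coarse_forward(x, coarse))
  expect_identical(yf, fine_forward(x, fine))
})

test_that("fine-network skip variants are wired differently", {
  fine <- init_params("fine", width_div = 16, seed = 3)
  x <- matrix(runif(64 * 64), 64, 64)
  y1 <- fine_forward(x, fine, skip_mode = "dacc")
  y2 <- fine_forward(x, fine, skip_mode = "concat")
  y3 <- fine_forward(x, fine, skip_mode = "sa_only")
  expect_gt(max(abs(y1 - y2)), 1e-8)
  expect_gt(max(abs(y1 - y3)), 1e-8)
  expect_gt(max(abs(y2 - y3)), 1e-8)
})

test_that("zero-weight output convolution gives the head's constant image", {
  x <- matrix(runif(32 * 32), 32, 32)
  fine <- init_params("fine", width_div = 16, seed = 4, out_act = "sigmoid")
  fine$params[["out.W"]][] <- 0
  fine$params[["out.b"]][] <- 0
  expect_equal(fine_forward(x, fine), matrix(0.5, 32, 32), tolerance = 1e-12)
  finec <- init_params("fine", width_div = 16, seed = 4, out_act = "clamp")
  finec$params[["out.W"]][] <- 0
  finec$params[["out.b"]][] <- 0
  expect_equal(fine_forward(x, finec), matrix(0, 32, 32), tolerance = 1e-12)
})

test_that("discriminator contracts: batch scores, zero weights, size check", {
  disc <- init_params("discriminator", width_div = 16, seed = 5)
  imgs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64))
  s <- discriminator_forward(imgs, disc)
  expect_length(s, 3)
  expect_true(all(is.finite(s)))
  expect_error(discriminator_forward(matrix(0, 32, 32), disc), "divisible")
  d0 <- disc
  for (nm in names(d0$params)) d0$params[[nm]][] <- 0
  expect_identical(discriminator_forward(imgs, d0), rep(0, 3))
})

test_that("finite-difference gradients match the tape through both generators", {
  fine <- init_params("fine", width_div = 16, seed = 13)
  coarse <- init_params("coarse", width_div = 16, seed = 14)
  set.seed(7)
  xb <- irisinpaint:::img_batch(list(matrix(runif(32 * 32), 32, 32),
                                     matrix(runif(32 * 32), 32, 32)))
  r1 <- fd_gradcheck(fine, int("fine_net_fwd"), xb$mat, 32, 32, 2, 1,
                     nsample = 10, sample_seed = 3)
  r2 <- fd_gradcheck(coarse, int("coarse_net_fwd"), xb$mat, 32, 32, 2, 1,
                     nsample = 10, sample_seed = 4)
  expect_gte(length(r1), 10)
  expect_gte(length(r2), 10)
  expect_lt(max(r1), 1e-4)
  expect_lt(max(r2), 1e-4)
})

test_that("discriminator backward and input gradients match finite differences", {
  disc <- init_params("discriminator", width_div = 16, seed = 15)
  set.seed(8)
  b <- irisinpaint:::img_batch(list(matrix(runif(64 * 64), 64, 64),
                                    matrix(runif(64 * 64), 64, 64)))
  fwd <- int("disc_fwd_raw"); bwd <- int("disc_bwd_raw")
  cache <- fwd(b$mat, 64, 64, 2, disc$params, 0.2)
  gr <- bwd(cache, disc$params, c(0.5, 0.5), 0.2, need_dx = TRUE)
  f <- function(p) mean(fwd(b$mat, 64, 64, 2, p, 0.2)$score)
  set.seed(9); h <- 1e-5
  for (rep in 1:8) {
    nm <- sample(names(disc$params), 1)
    i <- sample(length(disc$params[[nm]]), 1)
    pp <- disc$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- disc$params; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (f(pp) - f(pm)) / (2 * h)
    expect_lt(abs(fd - gr$grads[[nm]][i]) / max(abs(fd), 1e-6), 1e-4)
  }
  # gradient w.r.t. the input
  ig <- int("disc_input_grad")(cache, disc$params, 0.2)
  i <- 1517
  bm <- b$mat; bm[i, 1] <- bm[i, 1] + h
  sp <- sum(fwd(bm, 64, 64, 2, disc$params, 0.2)$score)
  bm[i, 1] <- bm[i, 1] - 2 * h
  sm <- sum(fwd(bm, 64, 64, 2, disc$params, 0.2)$score)
  fd <- (sp - sm) / (2 * h)
  expect_lt(abs(fd - ig$g[i, 1]) / max(abs(fd), 1e-6), 1e-4)
})

test_that("gradient-penalty double backward matches finite differences", {
  disc <- init_params("discriminator", width_div = 16, seed = 16)
  set.seed(10)
  b <- irisinpaint:::img_batch(list(matrix(runif(64 * 64), 64, 64),
                                    matrix(runif(64 * 64), 64, 64)))
  gpi <- int("gp_internal_net")
  r <- gpi(disc$params, 0.2, b$mat, 64, 64, 2, 1e-8)
  f <- function(p) gpi(p, 0.2, b$mat, 64, 64, 2, 1e-8)$value
  set.seed(11); h <- 1e-5
  wnames <- grep("\\.W$", names(disc$params), value = TRUE)
  for (rep in 1:6) {
    nm <- sample(wnames, 1)
    i <- sample(length(disc$params[[nm]]), 1)
    pp <- disc$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- disc$params; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (f(pp) - f(pm)) / (2 * h)
    an <- r$grads[[nm]][i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-3)
  }
})

test_that("checkpoints round-trip bit-exactly", {
  nets <- list(coarse = init_params("coarse", width_div = 16, seed = 21),
               fine = init_params("fine", width_div = 16, seed = 22),
               disc = init_params("discriminator", width_div = 16, seed = 23))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(nets, path)
  expect_identical(load_checkpoint(path), nets)
})
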