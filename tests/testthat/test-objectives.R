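# helpers to build a feature space with given channel values
fs_blank <- function(p = 0, dx = 0, dy = 0, N = 1, sx = 1, sy = 1, sN = 1,
                     B = 0, H = 9, W = 9) {
  fs <- array(0, dim = c(H, W, 8))
  fs[, , 1] <- p; fs[, , 2] <- dx; fs[, , 3] <- dy; fs[, , 4] <- N
  fs[, , 5] <- sx; fs[, , 6] <- sy; fs[, , 7] <- sN; fs[, , 8] <- B
  fs
}

test_that("printed mixture evaluates to 1/sqrt((2 pi)^3) on the exact single-pixel match", {
  fs <- fs_blank()
  fs[5, 5, 1] <- 1                         # single active pixel
  gt <- list(x = 4.5, y = 4.5, N = 1)      # its center, exact intensity
  expect_equal(gmm_mixture_printed(fs, gt), 1 / sqrt((2 * pi)^3),
               tolerance = 1e-4)
  # doubling sigma_x at an exact match scales the density by 1/sqrt(2)
  fs2 <- fs; fs2[, , 5] <- 2
  expect_equal(gmm_mixture_printed(fs2, gt) / gmm_mixture_printed(fs, gt),
               1 / sqrt(2), tolerance = 1e-4)
})

test_that("localization loss grows as the prediction moves off the truth", {
  gt <- list(x = 4.5, y = 4.5, N = 1)
  loss_at <- function(dx) {
    fs <- fs_blank(dx = dx)
    fs[5, 5, 1] <- 1
    localisation_loss(fs, gt)
  }
  ls <- vapply(c(0, 0.2, 0.5, 0.9), loss_at, numeric(1))
  expect_true(all(diff(ls) > 0))
  expect_equal(localisation_loss(fs_blank(), list(x = numeric(), y = numeric(),
                                                  N = numeric())), 0)
})

test_that("count loss closed forms: printed value, quadratic minimum, vanishing variance", {
  p <- c(0.5, 0.5)
  expect_equal(count_loss(p, 1, printed = TRUE), -log(sqrt(pi)),
               tolerance = 1e-5)
  expect_equal(count_loss(p, 1, printed = TRUE), -0.5724, tolerance = 1e-3)
  # sum p == c_t kills the quadratic term in both forms
  expect_equal(count_loss(p, 1) - 0.5 * log(2 * pi * (0.5 + 1e-6)), 0,
               tolerance = 1e-9)
  # pushing p toward {0,1} at fixed sum shrinks sigma_c
  sc <- function(p) sum(p * (1 - p))
  expect_lt(sc(c(0.9, 0.1)), sc(c(0.5, 0.5)))
  expect_lt(sc(c(0.99, 0.01)), sc(c(0.9, 0.1)))
})

test_that("background loss is the mean absolute deviation and is symmetric", {
  fs <- fs_blank(B = 5, H = 1, W = 1)
  expect_equal(background_loss(fs, matrix(3, 1, 1)), 2)
  expect_equal(background_loss(fs, matrix(5, 1, 1)), 0)
  set.seed(8)
  a <- matrix(rnorm(81), 9, 9); b <- matrix(rnorm(81), 9, 9)
  expect_equal(background_loss(a, b), background_loss(b, a))
})

test_that("total loss is the sum of components and empty crops only count", {
  fs <- fs_blank()
  fs[5, 5, 1] <- 1
  gt <- list(x = 4.5, y = 4.5, N = 1)
  nl <- matrix(0.2, 9, 9)
  expect_equal(total_loss(fs, gt, nl),
               localisation_loss(fs, gt) + count_loss(fs, 1) +
                 background_loss(fs, nl))
  gt0 <- list(x = numeric(), y = numeric(), N = numeric())
  expect_equal(total_loss(fs_blank(), gt0, nl),
               count_loss(fs_blank(), 0) + background_loss(fs_blank(), nl))
})

test_that("batched tape loss gradients match finite differences on every channel", {
  set.seed(99)
  crops <- small_crops()[1:3]
  gtb <- scanloc:::prepare_gt_batch(crops, 1000)
  raw0 <- array(rnorm(8 * 9 * 9 * 3, 0, 0.5), dim = c(8, 9, 9, 3))
  loss_of <- function(rawv) {
    tape <- scanloc:::ad_tape()
    raw <- scanloc:::ad_leaf(tape, rawv)
    act <- scanloc:::activations_tape(raw)
    scanloc:::nval(scanloc:::loss_tape(tape, act, gtb)$total)
  }
  tape <- scanloc:::ad_tape()
  raw <- scanloc:::ad_leaf(tape, raw0)
  act <- scanloc:::activations_tape(raw)
  ls <- scanloc:::loss_tape(tape, act, gtb)
  scanloc:::ad_backward(ls$total)
  g <- raw$grad
  # probe a handful of entries in every channel
  set.seed(100)
  for (ch in 1:8) {
    for (rep in 1:3) {
      i <- sample(9, 1); j <- sample(9, 1); b <- sample(3, 1)
      f <- function(v) { r <- raw0; r[ch, i, j, b] <- v; loss_of(r) }
      gn <- (f(raw0[ch, i, j, b] + 1e-4) - f(raw0[ch, i, j, b] - 1e-4)) / 2e-4
      expect_equal(g[ch, i, j, b], gn, tolerance = 1e-3)
    }
  }
  expect_true(any(abs(g) > 0))
})

test_that("a perfect feature space scores better than random perturbations", {
  cr <- isolated_crops(3)[[1]]
  tr <- cr$truth
  fs <- fs_blank(sx = 0.5, sy = 0.5, sN = 0.5, B = 0)
  fs[, , 8] <- cr$noiseless[, , 2] / 1000
  r <- floor(tr$y[1]); cc <- floor(tr$x[1])
  fs[r + 1, cc + 1, 1] <- 1
  fs[r + 1, cc + 1, 2] <- tr$x[1] - (cc + 0.5)
  fs[r + 1, cc + 1, 3] <- tr$y[1] - (r + 0.5)
  fs[r + 1, cc + 1, 4] <- tr$photons[1] / 1000
  gt <- list(x = tr$x, y = tr$y, N = tr$photons / 1000)
  nl <- cr$noiseless[, , 2] / 1000
  base <- total_loss(fs, gt, nl)
  set.seed(42)
  worse <- replicate(100, {
    fp <- fs
    fp[, , 2:4] <- fp[, , 2:4] + array(rnorm(243, 0, 0.3), dim = c(9, 9, 3))
    fp[, , 2:3] <- pmax(pmin(fp[, , 2:3], 1), -1)
    total_loss(fp, gt, nl)
  })
  expect_true(all(worse > base))
})
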