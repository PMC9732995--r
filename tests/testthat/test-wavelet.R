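test_that("Gram-Schmidt coupling orthogonalizes while keeping the high pass", {
  c1 <- gram_schmidt_couple(c(1, 0), c(0, 1))
  expect_equal(c1$lp_n, c(0, 1))
  c2 <- gram_schmidt_couple(c(1, 0), c(1, 1))
  expect_equal(c2$lp_n, c(0, 1))
  expect_equal(c2$hp_n, c(1, 0))
  set.seed(11)
  for (i in 1:50) {
    cc <- gram_schmidt_couple(rnorm(2), rnorm(2))
    expect_lt(abs(sum(cc$hp_n * cc$lp_n)), 1e-10)
  }
  expect_error(gram_schmidt_couple(c(0, 0), c(1, 1)), "degenerate")
})

test_that("decomposition matches an independent Haar reference and kills constants", {
  set.seed(3)
  x <- matrix(abs(rnorm(64)), 8, 8)
  bank <- filter_bank(levels = 1L, bias = numeric(4))
  dc <- decompose(x, bank, activation = FALSE)
  ref <- haar_ref(x)
  expect_equal(dc$LL, ref$LL, tolerance = 1e-12)
  expect_equal(dc$subbands[[1]]$HL, ref$HL, tolerance = 1e-12)
  expect_equal(dc$subbands[[1]]$LH, ref$LH, tolerance = 1e-12)
  expect_equal(dc$subbands[[1]]$HH, ref$HH, tolerance = 1e-12)
  # vanishing moment: constant image has zero high-pass content
  dc2 <- decompose(matrix(4, 8, 8), filter_bank(), activation = FALSE)
  expect_true(all(abs(dc2$subbands[[1]]$HH) < 1e-12))
  expect_true(all(abs(dc2$subbands[[2]]$LH) < 1e-12))
  # zero image, zero bias -> all subbands zero (with activation)
  dc3 <- decompose(matrix(0, 8, 8), filter_bank(), activation = TRUE)
  expect_true(all(dc3$LL == 0) && all(dc3$subbands[[1]]$HH == 0))
})

test_that("reconstruction is exact for coupled random taps and zero for zero subbands", {
  set.seed(21)
  for (i in 1:25) {
    bank <- filter_bank(hp = rnorm(2), lp = rnorm(2), levels = 2L)
    x <- matrix(rnorm(144), 12, 12)
    expect_equal(reconstruct(decompose(x, bank, activation = FALSE), bank), x,
                 tolerance = 1e-6)
  }
  bank <- filter_bank()
  dc <- decompose(matrix(0, 8, 8), bank, activation = FALSE)
  expect_true(all(abs(reconstruct(dc, bank)) < 1e-12))
  # thresholding high-frequency content of pure noise reduces variance
  set.seed(4)
  nimg <- matrix(rnorm(256), 16, 16)
  dc <- decompose(nimg, bank, activation = FALSE)
  for (l in 1:2) for (s in names(dc$subbands[[l]])) dc$subbands[[l]][[s]][] <- 0
  expect_lt(var(as.vector(reconstruct(dc, bank))), var(as.vector(nimg)))
})

test_that("peak detection finds isolated PSF maxima and is translation equivariant", {
  expect_equal(nrow(detect_peaks(matrix(3, 30, 30), threshold = 0)), 0)
  img <- matrix(0, 45, 45)
  k <- airy_psf(5.4, 21, normalize = "peak")
  place <- function(im, r, cc, kk = k) {
    h <- (nrow(kk) - 1) / 2
    im[(r - h):(r + h) + 1, (cc - h):(cc + h) + 1] <-
      im[(r - h):(r + h) + 1, (cc - h):(cc + h) + 1] + kk
    im
  }
  img1 <- place(img, 20, 17)
  p1 <- detect_peaks(img1, threshold = 0.5)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$row, p1$col), c(20, 17))
  img2 <- place(img1, 20, 27)
  p2 <- detect_peaks(img2, threshold = 0.5)
  expect_equal(nrow(p2), 2)
  expect_setequal(p2$col, c(17, 27))
  # translation equivariance away from borders
  img3 <- place(img, 23, 20)
  p3 <- detect_peaks(img3, threshold = 0.5)
  expect_equal(c(p3$row, p3$col), c(20, 17) + 3)
})

test_that("ROI crops are centered, zero-padded, and carry their origin", {
  frames <- array(rnorm(9 * 9 * 1), dim = c(9, 9, 1))
  pk <- data.frame(frame = 0L, row = 4L, col = 4L, score = 1)
  cr <- crop_rois(frames, pk)[[1]]
  expect_equal(dim(cr$pixels), c(9, 9, 3))
  expect_true(all(cr$pixels[, , 1] == 0))  # no previous frame
  expect_equal(cr$pixels[, , 2], frames[, , 1])
  expect_equal(unname(cr$origin), c(0, 0, 0))
  # corner peak: padded but still 9x9x3, center pixel preserved
  big <- array(rnorm(20 * 20 * 3), dim = c(20, 20, 3))
  pk2 <- data.frame(frame = 1L, row = 0L, col = 19L, score = 1)
  cr2 <- crop_rois(big, pk2)[[1]]
  expect_equal(dim(cr2$pixels), c(9, 9, 3))
  expect_equal(cr2$pixels[5, 5, 2], big[1, 20, 2])
  expect_true(all(cr2$pixels[1:4, , 2] == 0))
  pk3 <- data.frame(frame = 1L, row = 10L, col = 10L, score = 1)
  cr3 <- crop_rois(big, pk3)[[1]]
  expect_equal(cr3$pixels[5, 5, 2], big[11, 11, 2])
})

trained_bank <- function() fixture("trained_bank", function() {
  set.seed(5)
  train_wavelet_denoiser(small_crops()[1:48], epochs = 8L,
                         batch_size = 16L)$bank
})

test_that("denoiser training lowers reconstruction error and keeps orthogonality", {
  bank <- trained_bank()
  expect_lt(abs(sum(bank$hp * bank$lp)), 1e-6)
  # denoised MSE beats raw MSE against the noiseless target on held-out crops
  held <- small_crops()[49:80]
  mse_den <- mean(vapply(held, function(cr) {
    mean((wavelet_denoise(cr$pixels[, , 2], bank) - cr$noiseless[, , 2])^2)
  }, numeric(1)))
  mse_raw <- mean(vapply(held, function(cr) {
    mean((cr$pixels[, , 2] - cr$noiseless[, , 2])^2)
  }, numeric(1)))
  expect_lt(mse_den, mse_raw)
})

test_that("denoising does not displace an isolated PSF maximum by more than one pixel", {
  bank <- trained_bank()
  set.seed(61)
  for (i in 1:20) {
    img <- synth_psf_frame(runif(1, 2.5, 6.5), runif(1, 2.5, 6.5),
                           radius_px = runif(1, 5.25, 5.55))
    den <- wavelet_denoise(img, bank)
    p0 <- which(img == max(img), arr.ind = TRUE)[1, ]
    p1 <- which(den == max(den), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(p0 - p1)), 1)
  }
})
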