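test_that("airy kernel is normalized, centered, and zeroes at the stated radius", {
  k <- airy_psf(540, 1081)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  ctr <- which(k == max(k), arr.ind = TRUE)
  expect_equal(as.vector(ctr), c(541, 541))
  # independent check of the radial law via quadrature-based J1:
  # at distance = radius the argument is the first J1 root, so the
  # normalized intensity (2 J1(x)/x)^2 vanishes
  x0 <- 3.8317059702
  expect_lt(abs(j1_quad(x0)), 1e-8)
  peak <- k[541, 541]
  expect_lt(k[541, 541 + 540] / peak, 1e-9)
  # mid-radius value matches the independent Bessel evaluation
  d <- 270
  expect_equal(k[541, 541 + d] / peak,
               (2 * j1_quad(x0 * d / 540) / (x0 * d / 540))^2,
               tolerance = 1e-6)
})

test_that("airy first zero moves outward with the radius parameter", {
  first_zero <- function(radius) {
    k <- airy_psf(radius, 401)
    prof <- k[201, 201:401]
    which(diff(prof) > 0)[1]  # first index where the profile turns up
  }
  expect_gt(first_zero(111), first_zero(105))
  expect_error(airy_psf(-5, 11), "positive")
  expect_error(airy_psf(10, 12), "odd")
})

test_that("emitter state machine honors countdown, lifetime, and zero rate", {
  cfg <- scan_config(lambda_on = 0)
  set.seed(1)
  expect_equal(nrow(step_emitter_states(empty_set <- scanloc:::empty_emitters(), cfg)), 0)
  em <- scanloc:::new_emitters(1, cfg, 1L)
  em$countdown_ms <- 12; em$lifetime_ms <- 18
  s1 <- step_emitter_states(em, cfg)
  expect_equal(s1$countdown_ms, 6); expect_false(attr(s1, "on"))
  s2 <- step_emitter_states(s1, cfg)
  expect_equal(s2$countdown_ms, 0); expect_false(attr(s2, "on"))
  s3 <- step_emitter_states(s2, cfg)
  expect_true(attr(s3, "on"))           # rendered starting with line 3
  expect_equal(s3$lifetime_ms, 12)
  s4 <- step_emitter_states(s3, cfg); s5 <- step_emitter_states(s4, cfg)
  expect_equal(s5$lifetime_ms, 0)
  s6 <- step_emitter_states(s5, cfg)    # exhausted -> deleted
  expect_equal(nrow(s6), 0)
})

test_that("lifetime and countdown distributions match their Poisson means", {
  cfg <- scan_config()
  set.seed(7)
  em <- scanloc:::new_emitters(1e4, cfg, 1L)
  se <- sqrt(90 / 1e4)
  expect_lt(abs(mean(em$lifetime_ms) - 90), 3 * se)
  expect_lt(abs(mean(em$countdown_ms) - 90), 3 * se)
  expect_true(all(em$photons >= 800 & em$photons <= 1500))
})

test_that("ground-truth acceptance applies the 40% rendered fraction rule", {
  cfg <- scan_config()
  expect_true(accept_ground_truth(list(lines_rendered = 10, lines_on = 10), cfg))
  expect_true(accept_ground_truth(list(lines_rendered = 4, lines_on = 10), cfg))
  expect_false(accept_ground_truth(list(lines_rendered = 3, lines_on = 10), cfg))
  expect_false(accept_ground_truth(list(lines_rendered = 0, lines_on = 0), cfg))
})

test_that("line rendering clips PSFs to the scanned band", {
  cfg <- scan_config(s_px = 10L, s_im = 9L, airy_radius_range = c(52.5, 55.5),
                     lambda_on = 0)
  N <- cfg$s_px * cfg$s_im
  em <- data.frame(id = 1L, Lx = 44.3, Ly = 43.7, photons = 1000,
                   countdown_ms = 0, lifetime_ms = 60, radius = 54,
                   brightness = 1000, lines_rendered = 0L, lines_on = 0L,
                   frame_index = NA_integer_)
  on <- TRUE
  S_empty <- render_line(3L, em[0, ], matrix(0, N, N), cfg)
  expect_true(all(S_empty == 0))
  # full render = sum of all line bands (partition of the kernel)
  S_full <- matrix(0, N, N)
  for (l in 0:8) S_full <- render_line(l, em, S_full, cfg, on = on)
  # emitter switching OFF after line 3: upper part only
  S_half <- matrix(0, N, N)
  for (l in 0:3) S_half <- render_line(l, em, S_half, cfg, on = on)
  expect_true(all(S_half[41:N, ] == 0))
  expect_equal(S_half[1:40, ], S_full[1:40, ])
  expect_gt(sum(S_full[41:N, ]), 0)
  # photon conservation against the dense kernel mass inside the field
  amp_mass <- sum(S_full)
  w <- cfg$kernel_window_zeros * 54
  rows <- 0:(N - 1); cols <- 0:(N - 1)
  d <- sqrt(outer((rows + 0.5 - em$Ly)^2, (cols + 0.5 - em$Lx)^2, "+"))
  prof <- scanloc:::airy_radial_fast(3.8317059702 * d / 54,
                                     x_cut = cfg$kernel_window_zeros * 3.8317059702)
  expect_equal(amp_mass, 1000 * sum(prof), tolerance = 1e-8)
})

test_that("frame finalization preserves constants and respects noise toggles", {
  cfg <- scan_config(s_px = 4L, s_im = 9L, shot_noise = FALSE,
                     read_noise = FALSE)
  S <- matrix(5.5, 36, 36)
  fr <- finalize_frame(S, cfg, sigma = 180)
  expect_true(all(abs(fr$noiseless - 5.5) < 1e-12))
  expect_identical(fr$noisy, fr$noiseless)
  # read-noise only: mean offset ~ 0 and sd ~ sigma
  cfg2 <- scan_config(s_px = 4L, s_im = 9L, shot_noise = FALSE)
  set.seed(2)
  resid <- replicate(200, {
    fr <- finalize_frame(S, cfg2, sigma = 180)
    fr$noisy - fr$noiseless
  })
  expect_lt(abs(mean(resid)), 3 * 180 / sqrt(length(resid)))
  expect_lt(abs(sd(resid) - 180), 5)
})

test_that("training crops hold bounded truth, pure-noise zero crops, and are reproducible", {
  cfg0 <- scan_config(lambda_on = 0)
  cr0 <- make_training_crops(1, cfg0, seed = 5)
  expect_equal(nrow(cr0[[1]]$truth), 0)
  expect_true(all(cr0[[1]]$noiseless == 0))
  expect_equal(dim(cr0[[1]]$pixels), c(9, 9, 3))

  crops <- small_crops()
  ns <- vapply(crops, function(cr) nrow(cr$truth), numeric(1))
  expect_true(all(ns >= 0 & ns <= 10))
  xs <- unlist(lapply(crops, function(cr) cr$truth$x))
  expect_true(all(xs >= 0 & xs < 9))

  a <- make_training_crops(3, scan_config(), seed = 77)
  b <- make_training_crops(3, scan_config(), seed = 77)
  expect_identical(a, b)
})

test_that("simulated stacks are deterministic and round-trip through TIFF/CSV", {
  cfg <- scan_config(s_im = 16L, lambda_on = 0.4)
  s1 <- simulate_stack(cfg, 4, seed = 9)
  s2 <- simulate_stack(cfg, 4, seed = 9)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(s1$truth$x_px >= 0 & s1$truth$x_px < 16))

  tf <- tempfile(fileext = ".tif")
  write_stack_tiff(s1, tf)
  back <- read_stack_tiff(tf)
  expect_equal(back, round(pmax(pmin(s1$frames, 65535), 0)), tolerance = 1e-9)

  cf <- tempfile(fileext = ".csv")
  write_truth_csv(s1$truth, cf)
  tr <- utils::read.csv(cf)
  expect_equal(names(tr), c("frame", "x_px", "y_px", "photons"))
  expect_equal(nrow(tr), nrow(s1$truth))
})

test_that("crop datasets round-trip through the array container + CSV pair", {
  crops <- small_crops()[1:6]
  pre <- tempfile()
  write_crops(crops, pre)
  back <- read_crops(pre)
  expect_length(back, 6)
  expect_equal(back[[3]]$pixels, crops[[3]]$pixels)
  expect_equal(back[[3]]$noiseless, crops[[3]]$noiseless)
  expect_equal(back[[3]]$truth$x, crops[[3]]$truth$x)
  expect_equal(back[[5]]$sigma, crops[[5]]$sigma)
})

test_that("scan configuration validates and round-trips through YAML", {
  expect_error(scan_config(min_on_fraction = 0))
  expect_error(scan_config(photon_range = c(1500, 800)))
  cfg <- scan_config(s_im = 12L, lambda_on = 0.3, seed = 42L)
  yf <- tempfile(fileext = ".yaml")
  write_scan_config(cfg, yf)
  cfg2 <- read_scan_config(yf)
  expect_equal(cfg2, cfg)
  # a reloaded config reproduces the identical simulation run
  expect_identical(simulate_stack(cfg2, 2)$frames, simulate_stack(cfg, 2)$frames)
})
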