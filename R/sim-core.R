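# Line-scan SMLM simulator.
#
# The scanner rasterizes the sub-lattice S in horizontal lines of one
# camera-pixel row (s_px sub-lattice cells high). Because line bands align
# exactly with camera-pixel rows, the area-mean downsample of a band-clipped
# PSF equals the row-masked downsampled PSF; the fast rendering path exploits
# this and never materializes S densely.

AIRY_FIRST_ZERO <- 3.8317059702

# radial Airy intensity profile (2 J1(x)/x)^2 with value 1 at x = 0
airy_radial <- function(x) {
  out <- x
  out[] <- 1
  nz <- x != 0
  out[nz] <- (2 * besselJ(x[nz], 1) / x[nz])^2
  out
}

.airy_tab <- new.env(parent = emptyenv())

airy_radial_fast <- function(x, x_cut = Inf) {
  if (is.null(.airy_tab$grid)) {
    .airy_tab$step <- 0.005
    .airy_tab$grid <- seq(0, 25, by = .airy_tab$step)
    .airy_tab$val <- airy_radial(.airy_tab$grid)
  }
  i <- x / .airy_tab$step
  i0 <- pmin(floor(i), length(.airy_tab$grid) - 2)
  fr <- i - i0
  v <- .airy_tab$val[i0 + 1] * (1 - fr) + .airy_tab$val[i0 + 2] * fr
  v[x >= min(x_cut, 25)] <- 0
  dim(v) <- dim(x)
  v
}

#' Airy-disk point spread function kernel
#'
#' Evaluates the Airy intensity pattern `(2 J1(x)/x)^2` on a square grid,
#' with the first zero of the pattern at `radius` grid cells from the
#' center.
#'
#' @param radius first-zero radius in grid (sub-lattice) units.
#' @param size odd kernel side length.
#' @param normalize `"sum"` scales the kernel to unit mass, `"peak"` to unit
#'   central amplitude (the scale used by the renderer, where an emitter's
#'   photon count multiplies the kernel).
#' @return a `size x size` numeric matrix.
#' @export
airy_psf <- function(radius, size, normalize = c("sum", "peak")) {
  normalize <- match.arg(normalize)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (size %% 2 == 0) stop("size must be odd")
  off <- seq_len(size) - (size + 1) / 2
  d <- sqrt(outer(off^2, off^2, "+"))
  k <- airy_radial(AIRY_FIRST_ZERO * d / radius)
  if (normalize == "sum") k / sum(k) else k / max(k)
}

empty_emitters <- function() {
  data.frame(id = integer(), Lx = numeric(), Ly = numeric(),
             photons = numeric(), countdown_ms = numeric(),
             lifetime_ms = numeric(), radius = numeric(),
             brightness = numeric(), lines_rendered = integer(),
             lines_on = integer(), frame_index = integer())
}

new_emitters <- function(k, config, next_id) {
  data.frame(id = next_id + seq_len(k) - 1L,
             Lx = stats::runif(k, 0, config$s_px * config$s_im),
             Ly = stats::runif(k, 0, config$s_px * config$s_im),
             photons = floor(stats::runif(k, config$photon_range[1],
                                          config$photon_range[2] + 1)),
             countdown_ms = stats::rpois(k, config$mean_countdown),
             lifetime_ms = stats::rpois(k, config$mean_lifetime),
             radius = stats::runif(k, config$airy_radius_range[1],
                                   config$airy_radius_range[2]),
             brightness = NA_real_,
             lines_rendered = 0L, lines_on = 0L, frame_index = NA_integer_)
}

#' Advance the emitter state machine by one scanned line
#'
#' Draws `k ~ Poisson(lambda_on)` new emitters, removes emitters whose ON
#' lifetime is exhausted, decrements pending switch-ON countdowns by the
#' line time step (such emitters are not rendered in the current line) and
#' subtracts the time step from the lifetime of emitters in the ON state.
#'
#' @param active emitter `data.frame` as returned by this function (or
#'   `empty_emitters()`).
#' @param config a [scan_config()].
#' @param ids optional environment with a persistent `next_id` counter so
#'   emitter ids are never reused across a long simulation.
#' @return the updated emitter set with a logical attribute `"on"` flagging
#'   rows that are in the ON state during this line.
#' @export
step_emitter_states <- function(active, config, ids = NULL) {
  dt <- config$dt_line_ms
  # emitters that were ON and have used up their lifetime are deleted
  if (nrow(active)) {
    dead <- active$countdown_ms <= 0 & active$lifetime_ms <= 0
    active <- active[!dead, , drop = FALSE]
  }
  k <- stats::rpois(1, config$lambda_on)
  if (k > 0) {
    nid <- if (!is.null(ids)) ids$next_id
    else if (nrow(active)) max(active$id) + 1L else 1L
    if (!is.null(ids)) ids$next_id <- ids$next_id + k
    active <- rbind(active, new_emitters(k, config, nid))
  }
  on <- logical(nrow(active))
  if (nrow(active)) {
    waiting <- active$countdown_ms > 0
    active$countdown_ms[waiting] <- active$countdown_ms[waiting] - dt
    on <- !waiting
    active$lifetime_ms[on] <- active$lifetime_ms[on] - dt
    active$lines_on[on] <- active$lines_on[on] + 1L
  }
  attr(active, "on") <- on
  active
}

#' Ground-truth acceptance rule
#'
#' An emitter counts as ground truth in a frame only if the scanner captured
#' it during at least `min_on_fraction` (default 40%) of the lines in which
#' it was in the ON state.
#'
#' @param e one emitter record (list or single-row data.frame) with
#'   `lines_rendered` and `lines_on`.
#' @param config a [scan_config()].
#' @return logical.
#' @export
accept_ground_truth <- function(e, config) {
  if (is.na(e$lines_on) || e$lines_on == 0) return(FALSE)
  e$lines_rendered / e$lines_on >= config$min_on_fraction
}

# camera rows whose band intersects the emitter's PSF window
emitter_row_window <- function(Ly, radius, config) {
  w <- config$kernel_window_zeros * radius
  lo <- max(0L, floor((Ly - w) / config$s_px))
  hi <- min(config$s_im - 1L, floor((Ly + w) / config$s_px))
  if (lo > hi) integer() else lo:hi
}

# PSF binned to camera pixels (area mean over msub^2 subsamples per pixel),
# restricted to the given 0-based camera rows; peak-normalized amplitude.
binned_airy_rows <- function(Lx, Ly, radius, rows, config, msub = 4L) {
  s_px <- config$s_px; s_im <- config$s_im
  nr <- length(rows)
  sub <- (seq_len(msub) - 0.5) / msub * s_px
  ys <- rep(rows * s_px, each = msub) + sub - Ly
  xs <- rep((seq_len(s_im) - 1L) * s_px, each = msub) + sub - Lx
  d <- sqrt(outer(ys^2, xs^2, "+"))
  v <- airy_radial_fast(AIRY_FIRST_ZERO * d / radius,
                        x_cut = config$kernel_window_zeros * AIRY_FIRST_ZERO)
  # block mean msub x msub -> (nr, s_im)
  dim(v) <- c(msub, nr * msub * s_im)
  v <- colMeans(v)
  dim(v) <- c(nr, msub, s_im)
  v <- apply(v, c(1, 3), mean)
  dim(v) <- c(nr, s_im)
  v
}

apply_noise <- function(noiseless, config, sigma) {
  noisy <- noiseless
  if (config$shot_noise) {
    noisy <- matrix(stats::rpois(length(noiseless), pmax(noiseless, 0)),
                    nrow(noiseless))
  }
  if (config$read_noise && sigma > 0) {
    noisy <- noisy + matrix(stats::rnorm(length(noiseless), 0, sigma),
                            nrow(noiseless))
  }
  noisy
}

#' Simulate a line-scanned SMLM frame stack
#'
#' Runs the emitter state machine line by line across `n_frames` frames
#' (after `warmup_frames` discarded frames so the blinking process is in
#' steady state), renders each emitter's Airy PSF only in the lines scanned
#' while it was ON, bins to camera pixels and applies Poisson shot noise
#' plus Gaussian read noise.
#'
#' @param config a [scan_config()].
#' @param n_frames frames to keep.
#' @param warmup_frames discarded lead-in frames.
#' @param sigma read-noise standard deviation; drawn uniformly from
#'   `config$noise_sigma_range` when `NULL`.
#' @param seed RNG seed; defaults to `config$seed`. Pass `NA` to use the
#'   current RNG state.
#' @return a `frame_stack` list with `frames` and `noiseless`
#'   (`s_im x s_im x n_frames` arrays), `truth` (data.frame with 0-based
#'   `frame`, `x_px`, `y_px` in camera-pixel units, `photons`), and `sigma`.
#' @export
simulate_stack <- function(config, n_frames, warmup_frames = 2L,
                           sigma = NULL, seed = config$seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- stats::runif(1, config$noise_sigma_range[1],
                                            config$noise_sigma_range[2])
  s_im <- config$s_im
  frames <- array(0, dim = c(s_im, s_im, n_frames))
  noiseless <- array(0, dim = c(s_im, s_im, n_frames))
  truth <- list()
  active <- empty_emitters()
  ids <- new.env(parent = emptyenv())
  ids$next_id <- 1L
  total <- warmup_frames + n_frames
  for (f in seq_len(total)) {
    keep <- f > warmup_frames
    # per-frame records survive emitters that die mid-frame
    rec <- new.env(parent = emptyenv())
    for (line in 0:(s_im - 1L)) {
      active <- step_emitter_states(active, config, ids)
      on <- attr(active, "on")
      if (!any(on)) next
      for (i in which(on)) {
        key <- as.character(active$id[i])
        r <- rec[[key]]
        if (is.null(r)) {
          r <- list(Lx = active$Lx[i], Ly = active$Ly[i],
                    radius = active$radius[i], photons = active$photons[i],
                    brightness = NA_real_, rows = integer(),
                    lines_on = 0L, lines_rendered = 0L)
        }
        r$lines_on <- r$lines_on + 1L
        rows <- emitter_row_window(r$Ly, r$radius, config)
        if (line %in% rows) {
          r$lines_rendered <- r$lines_rendered + 1L
          r$rows <- c(r$rows, line)
          if (is.na(r$brightness)) {
            r$brightness <- max(r$photons +
              stats::rnorm(1, 0, config$photon_sigma_frac * r$photons), 1)
          }
        }
        rec[[key]] <- r
      }
    }
    img <- matrix(0, s_im, s_im)
    for (key in ls(rec)) {
      r <- rec[[key]]
      if (!length(r$rows)) next
      kr <- binned_airy_rows(r$Lx, r$Ly, r$radius, r$rows, config)
      img[r$rows + 1L, ] <- img[r$rows + 1L, ] + r$brightness * kr
    }
    if (keep) {
      fi <- f - warmup_frames
      noiseless[, , fi] <- img
      frames[, , fi] <- apply_noise(img, config, sigma)
      for (key in ls(rec)) {
        r <- rec[[key]]
        if (accept_ground_truth(r, config) && length(r$rows)) {
          truth[[length(truth) + 1]] <- data.frame(
            frame = fi - 1L,
            x_px = r$Lx / config$s_px,
            y_px = r$Ly / config$s_px,
            photons = r$brightness)
        }
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
               photons = numeric())
  structure(list(frames = frames, noiseless = noiseless, truth = truth,
                 sigma = sigma, config = config),
            class = "frame_stack")
}

# ---- dense sub-lattice path (reference contract) -------------------------

#' Render one scanned line into a dense sub-lattice
#'
#' Adds, for every emitter in the ON state, the band-clipped slice of its
#' peak-normalized Airy kernel (scaled by its brightness) into the
#' horizontal band of `s_px` sub-lattice rows at `line_index`. Emitters that
#' are OFF in this line contribute nothing, which is what produces
#' top/bottom-truncated PSFs.
#'
#' @param line_index 0-based camera-row / line index.
#' @param active emitter data.frame; only rows flagged by the logical `on`
#'   argument are rendered (defaults to the `"on"` attribute set by
#'   [step_emitter_states()]).
#' @param S `N x N` sub-lattice matrix (N = `s_px * s_im`).
#' @param config a [scan_config()].
#' @param on logical vector of emitters to render.
#' @return the updated `S`.
#' @export
render_line <- function(line_index, active, S, config,
                        on = attr(active, "on")) {
  stopifnot(line_index >= 0, line_index < config$s_im)
  if (!nrow(active)) return(S)
  if (is.null(on)) on <- rep(TRUE, nrow(active))
  s_px <- config$s_px
  N <- s_px * config$s_im
  band <- (line_index * s_px):((line_index + 1L) * s_px - 1L)  # 0-based rows
  for (i in which(on)) {
    w <- config$kernel_window_zeros * active$radius[i]
    rows <- band[abs(band + 0.5 - active$Ly[i]) <= w]
    if (!length(rows)) next
    cols <- max(0, floor(active$Lx[i] - w)):min(N - 1, ceiling(active$Lx[i] + w))
    dy <- rows + 0.5 - active$Ly[i]
    dx <- cols + 0.5 - active$Lx[i]
    d <- sqrt(outer(dy^2, dx^2, "+"))
    k <- airy_radial_fast(AIRY_FIRST_ZERO * d / active$radius[i],
                          x_cut = config$kernel_window_zeros * AIRY_FIRST_ZERO)
    amp <- if (is.na(active$brightness[i])) active$photons[i] else
      active$brightness[i]
    S[rows + 1L, cols + 1L] <- S[rows + 1L, cols + 1L] + amp * k
  }
  S
}

#' Downsample a dense sub-lattice to camera pixels and add noise
#'
#' Area-mean (InterArea-style) binning of the `N x N` sub-lattice to
#' `s_im x s_im`, followed by the configured noise stages.
#'
#' @param S dense sub-lattice matrix.
#' @param config a [scan_config()].
#' @param sigma read-noise sd; drawn from the configured range when `NULL`.
#' @return list with `noisy` and `noiseless` `s_im x s_im` matrices.
#' @export
finalize_frame <- function(S, config, sigma = NULL) {
  N <- config$s_px * config$s_im
  stopifnot(nrow(S) == N, ncol(S) == N)
  if (is.null(sigma)) sigma <- stats::runif(1, config$noise_sigma_range[1],
                                            config$noise_sigma_range[2])
  s <- config$s_px
  dim(S) <- c(s, config$s_im, s, config$s_im)
  noiseless <- apply(S, c(2, 4), mean)
  noisy <- apply_noise(noiseless, config, sigma)
  list(noisy = noisy, noiseless = noiseless)
}

# ---- training crops -------------------------------------------------------

#' Simulate 9x9x3 training crops
#'
#' Each crop is three consecutive simulated frames of a 9x9-pixel field with
#' up to `n_max` accepted ground-truth emitters in the central frame, plus
#' the noiseless frames and the local ground truth. One read-noise sigma is
#' drawn per call (per batch); shot noise is independent per crop.
#'
#' @param n_crops number of crops.
#' @param config a [scan_config()] with `s_im = 9`.
#' @param sigma per-batch read-noise sd; drawn from the configured range
#'   when `NULL`.
#' @param seed RNG seed; `NA` uses the current RNG state.
#' @param n_max crops whose central frame holds more accepted emitters are
#'   re-simulated.
#' @return list of `roi_crop` objects: `pixels` and `noiseless`
#'   (`9 x 9 x 3`), `truth` (crop-local `x`, `y` in pixels, `photons`),
#'   `origin`, `sigma`.
#' @export
make_training_crops <- function(n_crops, config, sigma = NULL,
                                seed = config$seed, n_max = 10L) {
  stopifnot(n_crops > 0)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  if (config$s_im != 9L) stop("training crops require s_im = 9")
  if (is.null(sigma)) sigma <- stats::runif(1, config$noise_sigma_range[1],
                                            config$noise_sigma_range[2])
  crops <- vector("list", n_crops)
  i <- 1L
  while (i <= n_crops) {
    st <- simulate_stack(config, n_frames = 3L, warmup_frames = 2L,
                         sigma = sigma, seed = NA)
    tr <- st$truth[st$truth$frame == 1L, , drop = FALSE]  # central frame
    if (nrow(tr) > n_max) next
    crops[[i]] <- structure(list(
      pixels = st$frames, noiseless = st$noiseless,
      truth = data.frame(x = tr$x_px, y = tr$y_px, photons = tr$photons),
      origin = c(frame = 1L, row = 0L, col = 0L),
      sigma = sigma), class = "roi_crop")
    i <- i + 1L
  }
  crops
}

# ---- I/O ------------------------------------------------------------------

#' Write / read a frame stack as multi-page TIFF
#'
#' Frames are stored as 16-bit unsigned pages; values are clipped to
#' `[0, 65535]` detector units.
#'
#' @param stack a `frame_stack` or a `s_im x s_im x n` array.
#' @param path output path.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  pages <- lapply(seq_len(dim(frames)[3]), function(i) {
    m <- round(pmax(pmin(frames[, , i], 65535), 0))
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @return `read_stack_tiff` returns a `s_im x s_im x n` array in detector
#'   units.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bad <- which(vapply(pages, function(p) length(dim(p)) != 2, logical(1)))
  if (length(bad)) stop("unsupported TIFF page ", bad[1], " in ", path)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * 65535)
  arr
}

#' Serialize a crop dataset
#'
#' Writes the pixel data of a crop list as one array container
#' (`<prefix>_pixels.rds`, a `9 x 9 x 3 x n` array, with the matching
#' noiseless array alongside) plus the ground truth as a CSV
#' (`<prefix>_truth.csv` with columns `crop`, `x`, `y`, `photons`;
#' 0-based crop index).
#'
#' @param crops list of `roi_crop` from [make_training_crops()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_crops <- function(crops, prefix) {
  n <- length(crops)
  px <- array(0, dim = c(9, 9, 3, n))
  nl <- array(0, dim = c(9, 9, 3, n))
  tr <- list()
  for (i in seq_len(n)) {
    px[, , , i] <- crops[[i]]$pixels
    nl[, , , i] <- crops[[i]]$noiseless
    t1 <- crops[[i]]$truth
    if (nrow(t1)) tr[[length(tr) + 1]] <- cbind(crop = i - 1L, t1)
  }
  saveRDS(list(pixels = px, noiseless = nl,
               sigma = vapply(crops, function(cr) cr$sigma, numeric(1))),
          paste0(prefix, "_pixels.rds"))
  tr <- if (length(tr)) do.call(rbind, tr) else
    data.frame(crop = integer(), x = numeric(), y = numeric(),
               photons = numeric())
  utils::write.csv(tr, paste0(prefix, "_truth.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_crops
#' @return `read_crops` returns the crop list.
#' @export
read_crops <- function(prefix) {
  d <- readRDS(paste0(prefix, "_pixels.rds"))
  tr <- utils::read.csv(paste0(prefix, "_truth.csv"))
  n <- dim(d$pixels)[4]
  lapply(seq_len(n), function(i) {
    ti <- tr[tr$crop == i - 1L, c("x", "y", "photons"), drop = FALSE]
    rownames(ti) <- NULL
    structure(list(pixels = d$pixels[, , , i], noiseless = d$noiseless[, , , i],
                   truth = ti, origin = c(frame = 1L, row = 0L, col = 0L),
                   sigma = d$sigma[i]), class = "roi_crop")
  })
}

#' Write simulator ground truth as CSV
#'
#' Header `frame,x_px,y_px,photons`; 0-based frame index, coordinates in
#' camera-pixel units.
#'
#' @param truth data.frame as in `frame_stack$truth`.
#' @param path output path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth[, c("frame", "x_px", "y_px", "photons")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
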