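# Trainable orthogonal wavelet filter bank for denoising and ROI detection.
#
# Analysis and synthesis share the same taps; the low pass is re-coupled to
# the high pass by Gram-Schmidt after every update, so the stacked analysis
# operator has orthogonal rows and synthesis is its norm-corrected
# transpose, giving exact reconstruction for the 2-tap bank at any tap
# values. Circular boundary handling keeps the operator square.

#' Orthogonalize a filter pair by Gram-Schmidt
#'
#' Keeps the high pass and removes its component from the low pass so the
#' coupled pair is exactly orthogonal: `lp_n = lp - (<hp,lp>/<hp,hp>) hp`.
#'
#' @param hp,lp numeric tap vectors of equal length; `hp` must be nonzero.
#' @return list with `hp_n`, `lp_n`.
#' @export
gram_schmidt_couple <- function(hp, lp) {
  stopifnot(length(hp) == length(lp))
  nhp <- sum(hp * hp)
  if (nhp == 0) stop("degenerate filter: hp is zero")
  list(hp_n = hp, lp_n = lp - (sum(hp * lp) / nhp) * hp)
}

#' Construct a wavelet filter bank
#'
#' @param hp,lp tap vectors (Haar-like 2-tap initialization by default);
#'   `lp` is re-coupled to `hp` on construction.
#' @param levels decomposition depth.
#' @param bias per-subband biases, length `3 * levels + 1` (LH/HL/HH per
#'   level plus the final LL), applied before the ReLU in the denoising
#'   path.
#' @param scale intensity normalization: images are divided by `scale`
#'   before the transform (so the biases live on a unit scale) and
#'   multiplied back after reconstruction.
#' @return a `filter_bank` list.
#' @export
filter_bank <- function(hp = c(1, -1) / sqrt(2), lp = c(1, 1) / sqrt(2),
                        levels = 2L, bias = numeric(3 * levels + 1),
                        scale = 1000) {
  cpl <- gram_schmidt_couple(hp, lp)
  stopifnot(length(bias) == 3 * levels + 1, scale > 0)
  structure(list(hp = cpl$hp_n, lp = cpl$lp_n, levels = as.integer(levels),
                 bias = bias, scale = scale), class = "filter_bank")
}

# strided circular analysis matrix (n/2 x n) for taps h
analysis_matrix <- function(h, n) {
  stopifnot(n %% 2 == 0)
  m <- n / 2
  A <- matrix(0, m, n)
  for (k in seq_len(m)) {
    pos <- ((2 * (k - 1) + seq_along(h) - 1) %% n) + 1
    A[k, pos] <- A[k, pos] + h
  }
  A
}

wavelet_pad <- function(img, levels) {
  mult <- 2^levels
  n1 <- ceiling(nrow(img) / mult) * mult
  n2 <- ceiling(ncol(img) / mult) * mult
  out <- matrix(0, n1, n2)
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

#' Separable 2D wavelet decomposition
#'
#' Standard strided analysis producing LH/HL/HH subbands per level and a
#' final LL, using the coupled `(lp_n, hp_n)` pair with circular boundaries.
#' In the denoising path a per-subband bias followed by a ReLU is applied;
#' disable with `activation = FALSE` for the linear (perfectly
#' reconstructing) transform.
#'
#' @param image numeric matrix; padded with zeros to a multiple of
#'   `2^levels` if needed.
#' @param bank a [filter_bank()].
#' @param activation apply bias + ReLU to each subband.
#' @return a `wavelet_decomposition` list (`subbands`, `LL`, original dims).
#' @export
decompose <- function(image, bank, activation = TRUE) {
  d0 <- dim(image)
  x <- wavelet_pad(image, bank$levels)
  sub <- vector("list", bank$levels)
  bi <- 1L
  act <- function(s) {
    if (!activation) return(s)
    b <- bank$bias[bi]; bi <<- bi + 1L
    pmax(s + b, 0)
  }
  for (lev in seq_len(bank$levels)) {
    Ar_lp <- analysis_matrix(bank$lp, nrow(x))
    Ar_hp <- analysis_matrix(bank$hp, nrow(x))
    Ac_lp <- analysis_matrix(bank$lp, ncol(x))
    Ac_hp <- analysis_matrix(bank$hp, ncol(x))
    L <- Ar_lp %*% x
    H <- Ar_hp %*% x
    sub[[lev]] <- list(LH = act(L %*% t(Ac_hp)),
                       HL = act(H %*% t(Ac_lp)),
                       HH = act(H %*% t(Ac_hp)))
    x <- L %*% t(Ac_lp)
  }
  LL <- act(x)
  structure(list(subbands = sub, LL = LL, dims = d0,
                 levels = bank$levels), class = "wavelet_decomposition")
}

#' Inverse wavelet transform
#'
#' Synthesis with the same (shared-weight) filter bank, norm-corrected so
#' that `reconstruct(decompose(x, bank, activation = FALSE), bank)`
#' recovers `x` exactly for the coupled 2-tap bank.
#'
#' @param dec a `wavelet_decomposition`.
#' @param bank the [filter_bank()] used for decomposition.
#' @return numeric matrix with the original image dims.
#' @export
reconstruct <- function(dec, bank) {
  if (dec$levels != bank$levels) stop("levels mismatch")
  nlp <- sum(bank$lp^2)
  nhp <- sum(bank$hp^2)
  x <- dec$LL
  for (lev in rev(seq_len(bank$levels))) {
    sb <- dec$subbands[[lev]]
    if (any(dim(sb$HH) != dim(x))) stop("subband shape mismatch")
    n1 <- 2 * nrow(x); n2 <- 2 * ncol(x)
    Ar_lp <- analysis_matrix(bank$lp, n1); Ar_hp <- analysis_matrix(bank$hp, n1)
    Ac_lp <- analysis_matrix(bank$lp, n2); Ac_hp <- analysis_matrix(bank$hp, n2)
    L <- (x %*% Ac_lp) / nlp + (sb$LH %*% Ac_hp) / nhp
    H <- (sb$HL %*% Ac_lp) / nlp + (sb$HH %*% Ac_hp) / nhp
    x <- t(Ar_lp) %*% L / nlp + t(Ar_hp) %*% H / nhp
  }
  x[seq_len(dec$dims[1]), seq_len(dec$dims[2]), drop = FALSE]
}

#' Denoise an image with a trained filter bank
#'
#' One decompose (bias + ReLU on each subband) / reconstruct pass.
#'
#' @param image numeric matrix.
#' @param bank a [filter_bank()].
#' @return denoised matrix.
#' @export
wavelet_denoise <- function(image, bank) {
  sc <- bank$scale %||% 1
  reconstruct(decompose(image / sc, bank, activation = TRUE), bank) * sc
}

#' Detect candidate emitters as strict local maxima
#'
#' @param image numeric matrix (one denoised frame) or a 3D array of
#'   frames.
#' @param threshold minimum value; default is the image median plus three
#'   MAD-based robust standard deviations.
#' @return data.frame `frame`, `row`, `col` (0-based), `score`.
#' @export
detect_peaks <- function(image, threshold = NULL) {
  if (length(dim(image)) == 3) {
    out <- lapply(seq_len(dim(image)[3]), function(f) {
      p <- detect_peaks(image[, , f], threshold)
      p$frame <- f - 1L
      p
    })
    return(do.call(rbind, out))
  }
  if (is.null(threshold)) {
    threshold <- stats::median(image) + 3 * stats::mad(image)
  }
  stopifnot(threshold >= 0 || !is.null(threshold))
  n1 <- nrow(image); n2 <- ncol(image)
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- image
  # >= against later neighbors, > against earlier ones (row-major), so a
  # plateau of tied values yields exactly its first pixel; a pixel must
  # still exceed at least one neighbor, so constant regions yield nothing
  padhi <- matrix(Inf, n1 + 2, n2 + 2)   # out-of-bounds never counts as
  padhi[2:(n1 + 1), 2:(n2 + 1)] <- image # an exceeded neighbor
  ismax <- matrix(TRUE, n1, n2)
  above_any <- matrix(FALSE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(n1 + 1) + di, 2:(n2 + 1) + dj]
    earlier <- di < 0 || (di == 0 && dj < 0)
    ismax <- ismax & if (earlier) image > nb else image >= nb
    above_any <- above_any | (image > padhi[2:(n1 + 1) + di, 2:(n2 + 1) + dj])
  }
  ismax <- ismax & above_any & (image > threshold)
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(frame = integer(), row = integer(), col = integer(),
                      score = numeric()))
  }
  # row-major first occurrence on ties in downstream use
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  data.frame(frame = 0L, row = idx[, 1] - 1L, col = idx[, 2] - 1L,
             score = image[idx])
}

#' Crop 9x9x3 ROIs around detected peaks
#'
#' For every peak, a `size x size` window centered on the peak is cut from
#' the previous, current and next frame (zero-padded at stack borders and
#' image edges); the crop origin maps local to global coordinates.
#'
#' @param stack a `frame_stack` or `s_im x s_im x n` array.
#' @param peaks data.frame from [detect_peaks()] with 0-based `frame`,
#'   `row`, `col`.
#' @param size odd window size.
#' @return list of `roi_crop` objects (pixels plus `origin`).
#' @export
crop_rois <- function(stack, peaks, size = 9L) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  h <- (size - 1L) %/% 2L
  nf <- dim(frames)[3]
  lapply(seq_len(nrow(peaks)), function(i) {
    f <- peaks$frame[i]; r <- peaks$row[i]; cc <- peaks$col[i]
    px <- array(0, dim = c(size, size, 3))
    for (k in -1:1) {
      fi <- f + k
      if (fi < 0 || fi >= nf) next
      rows <- (r - h):(r + h); cols <- (cc - h):(cc + h)
      okr <- rows >= 0 & rows < dim(frames)[1]
      okc <- cols >= 0 & cols < dim(frames)[2]
      px[which(okr), which(okc), k + 2] <-
        frames[rows[okr] + 1L, cols[okc] + 1L, fi + 1L]
    }
    structure(list(pixels = px,
                   origin = c(frame = f, row = r - h, col = cc - h)),
              class = "roi_crop")
  })
}

#' Train the wavelet denoiser on paired noisy/noiseless crops
#'
#' Optimizes the filter taps and subband biases to minimize the mean
#' squared error between the reconstructed and the noiseless central frame;
#' Gram-Schmidt coupling is re-applied after every update so orthogonality
#' holds throughout training. Gradients of the roughly a dozen parameters
#' are computed by central finite differences.
#'
#' @param crops list of `roi_crop` objects with `noiseless` (from
#'   [make_training_crops()]).
#' @param bank starting [filter_bank()].
#' @param epochs passes over the crop set.
#' @param batch_size crops per step.
#' @param lr Adam learning rate.
#' @return list with the trained `bank` and the per-step `loss` trace.
#' @export
train_wavelet_denoiser <- function(crops, bank = filter_bank(), epochs = 8L,
                                   batch_size = 16L, lr = 2e-2) {
  L <- length(bank$hp)
  theta <- c(bank$hp, bank$lp, bank$bias)
  nb <- length(bank$bias)
  sc <- bank$scale %||% 1
  unpack <- function(th) {
    filter_bank(hp = th[seq_len(L)], lp = th[L + seq_len(L)],
                levels = bank$levels, bias = th[2 * L + seq_len(nb)],
                scale = sc)
  }
  batch_loss <- function(th, idx) {
    bk <- unpack(th)
    tot <- 0
    for (i in idx) {
      den <- wavelet_denoise(crops[[i]]$pixels[, , 2], bk)
      tot <- tot + mean((den - crops[[i]]$noiseless[, , 2])^2) / sc^2
    }
    tot / length(idx)
  }
  m <- v <- numeric(length(theta))
  trace <- numeric(0)
  t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(length(crops))
    starts <- seq(1, length(crops), by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, length(crops))]
      g <- numeric(length(theta))
      eps <- 1e-4
      for (j in seq_along(theta)) {
        tp <- theta; tp[j] <- tp[j] + eps
        tm <- theta; tm[j] <- tm[j] - eps
        g[j] <- (batch_loss(tp, idx) - batch_loss(tm, idx)) / (2 * eps)
      }
      t <- t + 1
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g * g
      theta <- theta - lr * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
      cur <- batch_loss(theta, idx)
      if (!is.finite(cur)) stop("wavelet training diverged (non-finite loss)")
      trace <- c(trace, cur)
    }
  }
  list(bank = unpack(theta), loss = trace)
}
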