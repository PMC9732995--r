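# Composite training objective: Gaussian-mixture localization loss,
# count loss and background loss, following the DECODE family of
# probabilistic SMLM losses.
#
# The printed mixture expression is a likelihood (larger is better); the
# trained loss is its negative log. Both forms are exposed: the printed
# evaluators back the closed-form checks, the negative-log form drives
# optimization. The count loss is likewise exposed in its printed form
# (with a negative log-sigma term) and trained with the proper Gaussian
# negative log-likelihood sign, which is the form that actually pushes
# pixel probabilities toward 0/1.

LOSS_EPS <- 1e-6

#' Printed-form Gaussian mixture localization likelihood
#'
#' Direct evaluation of the per-truth-emitter mixture
#' `P_t = sum_i p_i exp(-[(x_i-x_t)^2/sx_i^2 + (y_i-y_t)^2/sy_i^2 +
#' (N_i-N_t)^2/sN_i^2])` normalized by `sqrt((2 pi)^3 sx sy sN) sum_m p_m`,
#' summed over truth emitters.
#'
#' @param fs feature-space array `(H, W, 8)` with channels
#'   `p, dx, dy, N, sx, sy, sN, B` (activated values).
#' @param gt list with vectors `x`, `y` (crop-local pixel coordinates) and
#'   `N` (intensity in the same units as the `N` channel).
#' @return scalar likelihood value.
#' @export
gmm_mixture_printed <- function(fs, gt) {
  if (length(gt$x) == 0) return(0)
  H <- dim(fs)[1]; W <- dim(fs)[2]
  rr <- rep(seq_len(H) - 1L, W); cc <- rep(seq_len(W) - 1L, each = H)
  p <- as.vector(fs[, , 1])
  xi <- cc + 0.5 + as.vector(fs[, , 2])
  yi <- rr + 0.5 + as.vector(fs[, , 3])
  Ni <- as.vector(fs[, , 4])
  sx <- as.vector(fs[, , 5]); sy <- as.vector(fs[, , 6])
  sN <- as.vector(fs[, , 7])
  tot <- 0
  for (t in seq_along(gt$x)) {
    ex <- exp(-((xi - gt$x[t])^2 / sx^2 + (yi - gt$y[t])^2 / sy^2 +
                  (Ni - gt$N[t])^2 / sN^2))
    # the normalizer carries the component sigmas, so it sits inside the
    # pixel sum; with one active component this is the printed expression
    comp <- p * ex / sqrt((2 * pi)^3 * sx * sy * sN)
    tot <- tot + sum(comp) / (sum(p) + LOSS_EPS)
  }
  tot
}

#' Localization loss
#'
#' Negative log of the per-emitter Gaussian-mixture likelihood, the form
#' minimized during training. Each pixel contributes a mixture component
#' with weight `p_i / sum_m p_m`, mean `(x_i, y_i, N_i)` and per-component
#' standard deviations `(sx_i, sy_i, sN_i)`.
#'
#' @inheritParams gmm_mixture_printed
#' @return scalar loss; 0 when `gt` holds no emitters.
#' @export
localisation_loss <- function(fs, gt) {
  if (length(gt$x) == 0) return(0)
  H <- dim(fs)[1]; W <- dim(fs)[2]
  rr <- rep(seq_len(H) - 1L, W); cc <- rep(seq_len(W) - 1L, each = H)
  p <- as.vector(fs[, , 1])
  xi <- cc + 0.5 + as.vector(fs[, , 2])
  yi <- rr + 0.5 + as.vector(fs[, , 3])
  Ni <- as.vector(fs[, , 4])
  sx <- as.vector(fs[, , 5]); sy <- as.vector(fs[, , 6])
  sN <- as.vector(fs[, , 7])
  wsum <- sum(p) + LOSS_EPS
  tot <- 0
  for (t in seq_along(gt$x)) {
    comp <- p / ((2 * pi)^1.5 * sx * sy * sN + LOSS_EPS) *
      exp(-0.5 * ((xi - gt$x[t])^2 / sx^2 + (yi - gt$y[t])^2 / sy^2 +
                    (Ni - gt$N[t])^2 / sN^2))
    tot <- tot - log(sum(comp) / wsum + LOSS_EPS)
  }
  tot
}

#' Count loss
#'
#' `(sum p_i - c_t)^2 / (2 sigma_c) +/- ln(sqrt(2 pi sigma_c))` with
#' `sigma_c = sum p_i (1 - p_i) + eps`. `printed = TRUE` evaluates the
#' form with the negative log term; the default is the Gaussian negative
#' log-likelihood (positive log term), whose minimization drives the pixel
#' probabilities toward 0 and 1.
#'
#' @param fs feature-space array or a plain probability vector/matrix.
#' @param c_t true emitter count.
#' @param printed evaluate the printed form.
#' @return scalar loss.
#' @export
count_loss <- function(fs, c_t, printed = FALSE) {
  p <- if (length(dim(fs)) == 3) as.vector(fs[, , 1]) else as.vector(fs)
  sc <- sum(p * (1 - p)) + LOSS_EPS
  quad <- (sum(p) - c_t)^2 / (2 * sc)
  if (printed) quad - log(sqrt(2 * pi * sc)) else quad + log(sqrt(2 * pi * sc))
}

#' Background loss
#'
#' Mean absolute deviation `mean |B_i - n_i|` between the predicted
#' background channel and the noiseless target image.
#'
#' @param fs feature-space array `(H, W, 8)` or a background matrix.
#' @param noiseless target image.
#' @return scalar loss.
#' @export
background_loss <- function(fs, noiseless) {
  B <- if (length(dim(fs)) == 3) fs[, , 8] else fs
  mean(abs(B - noiseless))
}

#' Total loss
#'
#' Sum of localization, count and background components.
#'
#' @inheritParams gmm_mixture_printed
#' @param noiseless noiseless target image for the background term.
#' @return scalar.
#' @export
total_loss <- function(fs, gt, noiseless) {
  localisation_loss(fs, gt) + count_loss(fs, length(gt$x)) +
    background_loss(fs, noiseless)
}

# ---- batched tape version used in training -------------------------------

# Pad per-crop ground truth into (E,B) arrays; intensities scaled.
prepare_gt_batch <- function(crops, scale = 1000) {
  B <- length(crops)
  counts <- vapply(crops, function(cr) nrow(cr$truth), numeric(1))
  E <- max(1, counts)
  xt <- yt <- Nt <- mask <- matrix(0, E, B)
  noiseless <- matrix(0, 81, B)
  for (b in seq_len(B)) {
    tr <- crops[[b]]$truth
    if (nrow(tr)) {
      k <- seq_len(nrow(tr))
      xt[k, b] <- tr$x; yt[k, b] <- tr$y
      Nt[k, b] <- tr$photons / scale
      mask[k, b] <- 1
    }
    noiseless[, b] <- as.vector(crops[[b]]$noiseless[, , 2]) / scale
  }
  list(xt = xt, yt = yt, Nt = Nt, mask = mask, count = counts,
       noiseless = noiseless, E = E, B = B, scale = scale)
}

# act: list of (81,B) activated channel nodes (p,dx,dy,N,sx,sy,sN,Bg)
loss_tape <- function(tape, act, gtb) {
  B <- gtb$B; E <- gtb$E; P <- 81L
  H <- 9L
  rr <- rep(seq_len(H) - 1L, H); cc <- rep(seq_len(H) - 1L, each = H)
  xi <- ad_shift(act$dx, cc + 0.5)
  yi <- ad_shift(act$dy, rr + 0.5)

  expand <- function(nd) ad_expand_mid(nd, E)
  dx2 <- ad_square(ad_div(ad_sub(expand(xi), ad_expand_first(ad_leaf(tape, gtb$xt), P)),
                          expand(act$sx)))
  dy2 <- ad_square(ad_div(ad_sub(expand(yi), ad_expand_first(ad_leaf(tape, gtb$yt), P)),
                          expand(act$sy)))
  dN2 <- ad_square(ad_div(ad_sub(expand(act$N), ad_expand_first(ad_leaf(tape, gtb$Nt), P)),
                          expand(act$sN)))
  qd <- ad_scale(ad_add(ad_add(dx2, dy2), dN2), -0.5)
  norm <- ad_div(expand(act$p),
                 ad_shift(ad_scale(ad_mul(ad_mul(expand(act$sx), expand(act$sy)),
                                          expand(act$sN)), (2 * pi)^1.5), LOSS_EPS))
  comp <- ad_mul(norm, ad_exp(qd))
  mixt <- ad_sum_first(comp)                                  # (E,B)
  psum_nd <- ad_shift(colsum_rows(act$p), LOSS_EPS)
  mixn <- ad_div(mixt, ad_expand_rows(psum_nd, E))
  nll <- ad_neg(ad_log(ad_shift(mixn, LOSS_EPS)))
  l_loc <- ad_scale(ad_sum(ad_mul(nll, ad_leaf(tape, gtb$mask))), 1 / B)

  # count loss (Gaussian NLL sign)
  one <- ad_shift(ad_neg(act$p), 1)
  sc_nd <- ad_shift(colsum_rows(ad_mul(act$p, one)), LOSS_EPS)  # (1,B)
  dif <- ad_sub(colsum_rows(act$p), ad_leaf(tape, matrix(gtb$count, 1, B)))
  l_cnt_vec <- ad_add(ad_div(ad_square(dif), ad_scale(sc_nd, 2)),
                      ad_scale(ad_log(ad_scale(sc_nd, 2 * pi)), 0.5))
  l_cnt <- ad_scale(ad_sum(l_cnt_vec), 1 / B)

  # background loss
  l_bg <- ad_mean(ad_abs_smooth(ad_sub(act$Bg, ad_leaf(tape, gtb$noiseless))))

  total <- ad_add(ad_add(l_loc, l_cnt), l_bg)
  list(total = total,
       parts = c(loc = nval(l_loc), count = nval(l_cnt), bg = nval(l_bg)))
}

# column sums of an (P,B) node -> (1,B) node
colsum_rows <- function(a) {
  v <- nval(a); P <- nrow(v); B <- ncol(v)
  ad_push(a$tape, matrix(colSums(v), 1, B), list(a), function(g) {
    list(matrix(rep(as.vector(g), each = P), P, B))
  })
}
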