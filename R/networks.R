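# Fitter architectures: 9x9x3 crop -> 8-channel feature space.
#
# All four share the output activations; the compressed-sensing variants
# run the unrolled FISTA layer with a learned per-crop shrinkage weight as
# a differentiable prior, and the recursive U-Net replaces the CS matrix
# iterations with a weight-shared encode/decode refinement loop.

FS_CHANNELS <- c("p", "dx", "dy", "N", "sx", "sy", "sN", "B")

#' Apply the output activations to a raw feature-space stack
#'
#' `p` passes a sigmoid; the subpixel offsets `dx`, `dy` a tanh (range
#' `[-1, 1]` relative to the pixel center); the uncertainties `sx, sy, sN`
#' a sigmoid scaled by three (range `[0, 3]`); intensity `N` and
#' background `B` a softplus (non-negative).
#'
#' @param raw numeric array `(H, W, 8)` of pre-activation outputs.
#' @return array `(H, W, 8)` with channel dimnames
#'   `p, dx, dy, N, sx, sy, sN, B`.
#' @export
apply_output_activations <- function(raw) {
  stopifnot(length(dim(raw)) == 3, dim(raw)[3] == 8)
  sig <- function(x) 1 / (1 + exp(-x))
  sp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  out <- raw
  out[, , 1] <- sig(raw[, , 1])
  out[, , 2] <- tanh(raw[, , 2])
  out[, , 3] <- tanh(raw[, , 3])
  out[, , 4] <- sp(raw[, , 4])
  out[, , 5] <- 3 * sig(raw[, , 5])
  out[, , 6] <- 3 * sig(raw[, , 6])
  out[, , 7] <- 3 * sig(raw[, , 7])
  out[, , 8] <- sp(raw[, , 8])
  dimnames(out) <- list(NULL, NULL, FS_CHANNELS)
  out
}

# tape version: raw (8,9,9,B) node -> list of activated (81,B) nodes
activations_tape <- function(raw) {
  B <- dim(nval(raw))[4]
  ch <- function(i) ad_reshape(ad_slice_channels(raw, i), c(81L, B))
  list(p = ad_sigmoid(ch(1)),
       dx = ad_tanh(ch(2)), dy = ad_tanh(ch(3)),
       N = ad_softplus(ch(4)),
       sx = ad_scale(ad_sigmoid(ch(5)), 3),
       sy = ad_scale(ad_sigmoid(ch(6)), 3),
       sN = ad_scale(ad_sigmoid(ch(7)), 3),
       Bg = ad_softplus(ch(8)))
}

# ---- building blocks ------------------------------------------------------

make_unet <- function(Cin, Cout, w) {
  list(e1 = layer_conv(Cin, w), e1b = layer_conv(w, w),
       e2 = layer_conv(w, 2L * w), e2b = layer_conv(2L * w, 2L * w),
       bott = layer_conv(2L * w, 2L * w),
       u2 = layer_conv(4L * w, 2L * w), u1 = layer_conv(3L * w, w),
       out = layer_conv(w, Cout, 1L, 1L))
}

unet_forward <- function(tape, x, un, training = FALSE) {
  d <- dim(nval(x)); H <- d[2]; W <- d[3]
  H2 <- ceiling(H / 2); W2 <- ceiling(W / 2)
  H3 <- ceiling(H2 / 2); W3 <- ceiling(W2 / 2)
  e1 <- ad_relu(nn_conv(tape, x, un$e1))
  e1 <- ad_relu(nn_conv(tape, e1, un$e1b))
  p1 <- ad_spatial_map(e1, avgpool2_matrix(H, W), H2, W2)
  e2 <- ad_relu(nn_conv(tape, p1, un$e2))
  e2 <- ad_relu(nn_conv(tape, e2, un$e2b))
  p2 <- ad_spatial_map(e2, avgpool2_matrix(H2, W2), H3, W3)
  b <- ad_relu(nn_conv(tape, p2, un$bott))
  u2 <- ad_spatial_map(b, upsample_matrix(H3, W3, H2, W2), H2, W2)
  h <- ad_relu(nn_conv(tape, ad_concat_channels(list(u2, e2)), un$u2))
  u1 <- ad_spatial_map(h, upsample_matrix(H2, W2, H, W), H, W)
  h <- ad_relu(nn_conv(tape, ad_concat_channels(list(u1, e1)), un$u1))
  nn_conv(tape, h, un$out)
}

# CS prior: central frame -> unrolled FISTA -> area-binned lattice image
cs_prior <- function(tape, x, lnet, op, n_iter) {
  d <- dim(nval(x)); B <- d[4]
  lam <- forward_lambda(tape, x, lnet)
  y <- ad_reshape(ad_slice_channels(x, 2L), c(81L, B))
  b <- fista_unrolled(tape, nval(y), lam, op, n_iter)
  nf <- op$size * op$u
  blat <- ad_reshape(b, c(1L, nf, nf, B))
  ad_spatial_map(blat, binmean_matrix(op$size, op$size, op$u),
                 op$size, op$size)
}

# ---- model constructor ----------------------------------------------------

#' Construct a fitter network
#'
#' Architectures: `"cs_cnn"` (unrolled-FISTA prior + plain convolutions),
#' `"cs_inception"` (two stacked inception blocks, each with a CS path of
#' its own iteration count and shrinkage estimator, an asymmetric-filter
#' path, a bottleneck path and a pass-through path), `"cs_unet"` (CS prior
#' + U-Net), `"rec_unet"` (recursive U-Net refining the feature space with
#' weight-shared encode/decode steps and a batch-normalized image-space
#' state).
#'
#' @param arch architecture key.
#' @param width convolution width of the CNN/inception paths.
#' @param unet_width base U-Net width.
#' @param n_recursions refinement steps of the recursive U-Net.
#' @param cs_u lattice upsampling factor of the CS layer.
#' @param cs_iter1,cs_iter2 unrolled FISTA iteration counts (first /
#'   second inception block; `cs_iter2` is used by the non-inception CS
#'   architectures).
#' @param scale intensity normalization (detector units mapped to 1).
#' @param seed RNG seed for weight initialization.
#' @return a `fitter_net` object.
#' @export
fitter_net <- function(arch = c("rec_unet", "cs_cnn", "cs_inception", "cs_unet"),
                       width = 32L, unet_width = 16L, n_recursions = 3L,
                       cs_u = 4L, cs_iter1 = 5L, cs_iter2 = 20L,
                       scale = 1000, seed = NULL) {
  arch <- match.arg(arch)
  if (n_recursions < 1) stop("n_recursions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cfg <- list(arch = arch, width = as.integer(width),
              unet_width = as.integer(unet_width),
              n_recursions = as.integer(n_recursions),
              cs_u = as.integer(cs_u), cs_iter1 = as.integer(cs_iter1),
              cs_iter2 = as.integer(cs_iter2), scale = scale)
  op <- NULL
  w <- cfg$width
  layers <- switch(arch,
    cs_cnn = list(lnet = lambda_net(),
                  c1 = layer_conv(4L, w), c2 = layer_conv(w, w),
                  c3 = layer_conv(w, w), c4 = layer_conv(w, w),
                  out = layer_conv(w, 8L, 1L, 1L)),
    cs_inception = {
      blk <- function(Cin) list(
        lnet = lambda_net(),
        cs1x1 = layer_conv(1L, w, 1L, 1L),
        a13 = layer_conv(Cin, w, 1L, 3L), a31 = layer_conv(w, w, 3L, 1L),
        bneck = layer_conv(Cin, w, 1L, 1L),
        pass = layer_conv(Cin, w, 1L, 1L))
      list(b1 = blk(3L), b2 = blk(4L * w),
           c1 = layer_conv(4L * w, w), out = layer_conv(w, 8L, 1L, 1L))
    },
    cs_unet = list(lnet = lambda_net(),
                   unet = make_unet(4L, 8L, cfg$unet_width)),
    rec_unet = list(unet0 = make_unet(3L, 8L, cfg$unet_width),
                    bg1 = layer_conv(3L, cfg$unet_width),
                    bg2 = layer_conv(cfg$unet_width, 3L, 1L, 1L),
                    dec1 = layer_conv(8L, cfg$unet_width),
                    dec2 = layer_conv(cfg$unet_width, 3L, 1L, 1L),
                    enc1 = layer_conv(3L, cfg$unet_width),
                    enc2 = layer_conv(cfg$unet_width, cfg$unet_width),
                    enc3 = layer_conv(cfg$unet_width, 8L, 1L, 1L),
                    bn = layer_bn(3L)))
  # temper the feature-space heads: small weights and a negative initial
  # probability bias keep p off the 0/1 rails, where the count loss has an
  # exploding curvature
  temper <- function(ly, p_bias = NA) {
    ly$W$value <- ly$W$value * 0.1
    if (!is.na(p_bias)) ly$b$value[1] <- p_bias
    ly
  }
  if (arch %in% c("cs_cnn", "cs_inception")) layers$out <- temper(layers$out, -2)
  if (arch == "cs_unet") layers$unet$out <- temper(layers$unet$out, -2)
  if (arch == "rec_unet") {
    layers$unet0$out <- temper(layers$unet0$out, -2)
    layers$enc3 <- temper(layers$enc3)
  }
  if (arch != "rec_unet") {
    # PSF at the fine-lattice sampling: first zero 5.4 px * u cells
    psf <- airy_psf(5.4 * cfg$cs_u, 2L * ceiling(5.4 * cfg$cs_u * 2.2) + 1L)
    op <- build_measurement_operator(psf, cfg$cs_u, 9L)
  }
  structure(list(arch = arch, cfg = cfg, layers = layers, op = op),
            class = "fitter_net")
}

inception_block <- function(tape, h, x, blk, op, n_iter) {
  prior <- cs_prior(tape, x, blk$lnet, op, n_iter)
  p1 <- ad_relu(nn_conv(tape, prior, blk$cs1x1))
  p2 <- ad_relu(nn_conv(tape, ad_relu(nn_conv(tape, h, blk$a13)), blk$a31))
  p3 <- ad_relu(nn_conv(tape, h, blk$bneck))
  p4 <- ad_relu(nn_conv(tape, h, blk$pass))
  ad_concat_channels(list(p1, p2, p3, p4))
}

# raw forward pass: x (3,9,9,B) node -> raw (8,9,9,B) node
net_forward <- function(tape, model, x, training = FALSE) {
  ly <- model$layers
  cfg <- model$cfg
  switch(model$arch,
    cs_cnn = {
      prior <- cs_prior(tape, x, ly$lnet, model$op, cfg$cs_iter2)
      h <- ad_concat_channels(list(prior, x))
      for (l in list(ly$c1, ly$c2, ly$c3, ly$c4)) h <- ad_relu(nn_conv(tape, h, l))
      nn_conv(tape, h, ly$out)
    },
    cs_inception = {
      h <- inception_block(tape, x, x, ly$b1, model$op, cfg$cs_iter1)
      h <- inception_block(tape, h, x, ly$b2, model$op, cfg$cs_iter2)
      h <- ad_relu(nn_conv(tape, h, ly$c1))
      nn_conv(tape, h, ly$out)
    },
    cs_unet = {
      prior <- cs_prior(tape, x, ly$lnet, model$op, cfg$cs_iter2)
      unet_forward(tape, ad_concat_channels(list(prior, x)), ly$unet, training)
    },
    rec_unet = {
      f <- unet_forward(tape, x, ly$unet0, training)
      fbg <- nn_conv(tape, ad_relu(nn_conv(tape, x, ly$bg1)), ly$bg2)
      xstate <- NULL
      for (k in seq_len(cfg$n_recursions)) {
        dec <- nn_conv(tape, ad_relu(nn_conv(tape, f, ly$dec1)), ly$dec2)
        if (is.null(xstate)) {
          x0 <- dec
          xstate <- nn_bn(tape, dec, ly$bn, training, key = k)
        } else {
          xstate <- nn_bn(tape, ad_add(ad_add(xstate, x0), dec), ly$bn,
                          training, key = k)
        }
        resid <- ad_sub(x, ad_add(xstate, fbg))
        upd <- ad_relu(nn_conv(tape, resid, ly$enc1))
        upd <- ad_relu(nn_conv(tape, upd, ly$enc2))
        f <- ad_add(f, nn_conv(tape, upd, ly$enc3))
      }
      f
    })
}

crops_to_tensor <- function(crops, scale) {
  B <- length(crops)
  x <- array(0, dim = c(3, 9, 9, B))
  for (b in seq_len(B)) {
    px <- if (inherits(crops[[b]], "roi_crop")) crops[[b]]$pixels else crops[[b]]
    if (!all(dim(px) == c(9, 9, 3))) stop("crops must be 9 x 9 x 3")
    x[, , , b] <- aperm(px, c(3, 1, 2)) / scale
  }
  x
}

#' Predict feature spaces for ROI crops
#'
#' Runs the fitter forward (inference mode, running batch-norm statistics)
#' and applies the output activations. Intensity `N` and background `B`
#' are rescaled to detector units.
#'
#' @param model a [fitter_net()].
#' @param crops a single `roi_crop` / `9 x 9 x 3` array, or a list of
#'   them.
#' @param chunk crops per forward pass.
#' @return a feature-space array `(9, 9, 8)` or a list of them.
#' @export
predict_features <- function(model, crops, chunk = 256L) {
  single <- !is.list(crops) || inherits(crops, "roi_crop")
  if (single) crops <- list(crops)
  out <- vector("list", length(crops))
  for (s in seq(1, length(crops), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(crops))
    x <- crops_to_tensor(crops[idx], model$cfg$scale)
    if (any(!is.finite(x))) stop("non-finite crop values")
    if (any(dim(x)[1:3] != c(3, 9, 9))) stop("crops must be 9 x 9 x 3")
    tape <- ad_tape()
    xn <- ad_leaf(tape, x)
    xn$is_input <- TRUE
    raw <- net_forward(tape, model, xn, training = FALSE)
    rv <- nval(raw)
    for (j in seq_along(idx)) {
      fs <- apply_output_activations(aperm(rv[, , , j, drop = FALSE][, , , 1],
                                           c(2, 3, 1)))
      fs[, , 4] <- fs[, , 4] * model$cfg$scale
      fs[, , 8] <- fs[, , 8] * model$cfg$scale
      out[[idx[j]]] <- fs
    }
  }
  if (single) out[[1]] else out
}

#' Architecture-specific forward passes
#'
#' Convenience wrappers around [predict_features()] that assert the model
#' matches the named architecture.
#'
#' @param crop a `roi_crop` or `9 x 9 x 3` array.
#' @param model a [fitter_net()] of the matching architecture.
#' @return a feature-space array `(9, 9, 8)`.
#' @export
forward_cs_cnn <- function(crop, model) {
  stopifnot(model$arch == "cs_cnn")
  predict_features(model, crop)
}

#' @rdname forward_cs_cnn
#' @export
forward_cs_inception <- function(crop, model) {
  stopifnot(model$arch == "cs_inception")
  predict_features(model, crop)
}

#' @rdname forward_cs_cnn
#' @export
forward_cs_unet <- function(crop, model) {
  stopifnot(model$arch == "cs_unet")
  predict_features(model, crop)
}

#' @rdname forward_cs_cnn
#' @param n_recursions optional override of the refinement depth for this
#'   call.
#' @export
forward_recursive_unet <- function(crop, model, n_recursions = NULL) {
  stopifnot(model$arch == "rec_unet")
  if (!is.null(n_recursions)) {
    if (n_recursions < 1) stop("n_recursions must be >= 1")
    model$cfg$n_recursions <- as.integer(n_recursions)
  }
  predict_features(model, crop)
}

#' Number of trainable parameters of a fitter
#'
#' @param model a [fitter_net()].
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  n_params(model$layers)
}
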