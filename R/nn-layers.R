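# Neural-network layers on the autodiff tape.
#
# Convolutions use an im2col gather with cached index matrices, so the
# heavy work is one BLAS matmul per layer; the input gradient is computed
# as a convolution with the channel-transposed, spatially flipped kernel
# (exact for the odd kernel sizes used here).

.nn_cache <- new.env(parent = emptyenv())

conv_index <- function(C, H, W, B, kh, kw) {
  key <- paste("ci", C, H, W, B, kh, kw, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  cs <- seq_len(C); us <- seq_len(kh); vs <- seq_len(kw)
  Af <- as.vector(outer(outer(cs, C * (us - 1L), "+"), C * Hp * (vs - 1L), "+"))
  is <- seq_len(H); js <- seq_len(W); bs <- seq_len(B)
  Bp <- as.vector(outer(outer(C * (is - 1L), C * Hp * (js - 1L), "+"),
                        C * Hp * Wp * (bs - 1L), "+"))
  idx <- outer(Af, Bp, "+")
  .nn_cache[[key]] <- idx
  idx
}

conv_pad <- function(x, kh, kw) {
  d <- dim(x)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, dim = c(d[1], d[2] + 2L * ph, d[3] + 2L * pw, d[4]))
  xp[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  xp
}

# raw 'same' convolution, returns value and the patch matrix
conv_raw <- function(x, Wm, bias, kh, kw) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  xp <- conv_pad(x, kh, kw)
  idx <- conv_index(C, H, W, B, kh, kw)
  Pm <- xp[idx]
  dim(Pm) <- dim(idx)
  out <- crossprod(Wm, Pm)
  if (!is.null(bias)) out <- out + bias
  dim(out) <- c(ncol(Wm), H, W, B)
  list(out = out, Pm = Pm)
}

conv_flip_weights <- function(Wm, C, kh, kw) {
  Cout <- ncol(Wm)
  Wa <- array(Wm, c(C, kh, kw, Cout))
  Wf <- aperm(Wa[, rev(seq_len(kh)), rev(seq_len(kw)), , drop = FALSE], c(4, 2, 3, 1))
  dim(Wf) <- c(Cout * kh * kw, C)
  Wf
}

# x: (C,H,W,B) node; w,b: bound parameter nodes (ad_use); odd kernel, 'same'
ad_conv2d <- function(x, w, b, kh, kw) {
  xv <- nval(x); Wm <- nval(w); bv <- nval(b)
  d <- dim(xv); C <- d[1]
  fr <- conv_raw(xv, Wm, bv, kh, kw)
  Pm <- fr$Pm
  skip_gx <- isTRUE(x$is_input)
  ad_push(x$tape, fr$out, list(x, w, b), function(g) {
    Cout <- ncol(Wm)
    gm <- g; dim(gm) <- c(Cout, length(g) %/% Cout)
    gW <- tcrossprod(Pm, gm)
    gb <- rowSums(gm)
    gx <- if (skip_gx) NULL else {
      conv_raw(g, conv_flip_weights(Wm, C, kh, kw), NULL, kh, kw)$out
    }
    list(gx, gW, gb)
  })
}

# x: (F,B) matrix node; dense layer y = t(W) x + b
ad_dense <- function(x, w, b) {
  xv <- nval(x); Wv <- nval(w); bv <- nval(b)
  out <- crossprod(Wv, xv) + bv
  ad_push(x$tape, out, list(x, w, b), function(g) {
    list(Wv %*% g, xv %*% t(g), rowSums(g))
  })
}

# batch normalization per channel of (C,H,W,B); running stats in layer$state
ad_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.9,
                         eps = 1e-5) {
  xv <- nval(x); d <- dim(xv)
  C <- d[1]; M <- prod(d[-1])
  xm <- xv; dim(xm) <- c(C, M)
  gv <- nval(gamma); bv <- nval(beta)
  if (training) {
    mu <- rowMeans(xm)
    va <- pmax(rowMeans(xm * xm) - mu * mu, 0)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- pmax(state$var, 0)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  ym <- gv * xhat + bv
  out <- ym; dim(out) <- d
  ad_push(x$tape, out, list(x, gamma, beta), function(g) {
    gm <- g; dim(gm) <- c(C, M)
    ggamma <- rowSums(gm * xhat)
    gbeta <- rowSums(gm)
    gxh <- gm * gv
    if (training) {
      gx <- istd * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
    } else {
      gx <- gxh * istd
    }
    dim(gx) <- d
    list(gx, ggamma, gbeta)
  })
}

# linear spatial resampling: out[c,q,b] = sum_p M[q,p] x[c,p,b]
ad_spatial_map <- function(x, M, Ho, Wo) {
  xv <- nval(x); d <- dim(xv)
  xperm <- aperm(xv, c(2, 3, 1, 4))
  dim(xperm) <- c(d[2] * d[3], d[1] * d[4])
  om <- M %*% xperm
  dim(om) <- c(Ho, Wo, d[1], d[4])
  out <- aperm(om, c(3, 1, 2, 4))
  ad_push(x$tape, out, list(x), function(g) {
    gp <- aperm(g, c(2, 3, 1, 4))
    dim(gp) <- c(Ho * Wo, d[1] * d[4])
    gx <- crossprod(M, gp)
    dim(gx) <- c(d[2], d[3], d[1], d[4])
    list(aperm(gx, c(3, 1, 2, 4)))
  })
}

avgpool2_matrix <- function(H, W) {
  key <- paste("ap", H, W, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- ceiling(H / 2); Wo <- ceiling(W / 2)
  M <- matrix(0, Ho * Wo, H * W)
  for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
    ii <- intersect(c(2 * i - 1, 2 * i), seq_len(H))
    jj <- intersect(c(2 * j - 1, 2 * j), seq_len(W))
    cells <- as.vector(outer(ii, H * (jj - 1), "+"))
    M[i + Ho * (j - 1), cells] <- 1 / length(cells)
  }
  .nn_cache[[key]] <- M
  M
}

upsample_matrix <- function(Hi, Wi, Ho, Wo) {
  key <- paste("up", Hi, Wi, Ho, Wo, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  M <- matrix(0, Ho * Wo, Hi * Wi)
  si <- pmin(pmax(floor((seq_len(Ho) - 0.5) * Hi / Ho) + 1, 1), Hi)
  sj <- pmin(pmax(floor((seq_len(Wo) - 0.5) * Wi / Wo) + 1, 1), Wi)
  for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
    M[i + Ho * (j - 1), si[i] + Hi * (sj[j] - 1)] <- 1
  }
  .nn_cache[[key]] <- M
  M
}

# area binning by an integer factor u: (H*u, W*u) -> (H, W) block mean
binmean_matrix <- function(H, W, u) {
  key <- paste("bm", H, W, u, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hi <- H * u; Wi <- W * u
  M <- matrix(0, H * W, Hi * Wi)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    ii <- (i - 1) * u + seq_len(u)
    jj <- (j - 1) * u + seq_len(u)
    cells <- as.vector(outer(ii, Hi * (jj - 1), "+"))
    M[i + H * (j - 1), cells] <- 1 / (u * u)
  }
  .nn_cache[[key]] <- M
  M
}

# ---- layer constructors ---------------------------------------------------

rnorm_trunc <- function(n, mean = 0, sd = 1, lo = mean - 2 * sd, hi = mean + 2 * sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

layer_conv <- function(Cin, Cout, kh = 3L, kw = 3L) {
  sd <- sqrt(2 / (kh * kw * Cin))
  list(type = "conv", kh = kh, kw = kw, Cin = Cin, Cout = Cout,
       W = ad_param(matrix(stats::rnorm(Cin * kh * kw * Cout, 0, sd),
                           Cin * kh * kw, Cout)),
       b = ad_param(numeric(Cout)))
}

layer_dense <- function(Fin, Fout, init = c("he", "lambda")) {
  init <- match.arg(init)
  if (init == "he") {
    W <- matrix(stats::rnorm(Fin * Fout, 0, sqrt(2 / Fin)), Fin, Fout)
    b <- numeric(Fout)
  } else {
    # shrinkage-estimator initialization: normal(0.5, 0.3) weights with
    # fan-in scaling (keeps the sigmoid off its rails at these layer
    # widths, where saturation would kill the gradient), truncated-normal
    # bias
    W <- matrix(stats::rnorm(Fin * Fout, 0.5, 0.3) * (2 / Fin), Fin, Fout)
    b <- rnorm_trunc(Fout, 0, 0.1)
  }
  list(type = "dense", W = ad_param(W), b = ad_param(b))
}

# gamma/beta are shared wherever the layer is reused (e.g. across
# recursion steps); running statistics are kept per use-site key because
# the activation distribution differs between steps
layer_bn <- function(C) {
  sts <- new.env(parent = emptyenv())
  list(type = "bn", C = C, gamma = ad_param(rep(1, C)),
       beta = ad_param(numeric(C)), states = sts)
}

bn_state <- function(ly, key = 1L) {
  k <- as.character(key)
  if (is.null(ly$states[[k]])) {
    st <- new.env(parent = emptyenv())
    st$mean <- numeric(ly$C)
    st$var <- rep(1, ly$C)
    ly$states[[k]] <- st
  }
  ly$states[[k]]
}

nn_conv <- function(tape, x, ly) {
  ad_conv2d(x, ad_use(tape, ly$W), ad_use(tape, ly$b), ly$kh, ly$kw)
}

nn_dense <- function(tape, x, ly) {
  ad_dense(x, ad_use(tape, ly$W), ad_use(tape, ly$b))
}

nn_bn <- function(tape, x, ly, training, key = 1L) {
  ad_batchnorm(x, ad_use(tape, ly$gamma), ad_use(tape, ly$beta),
               bn_state(ly, key), training)
}

# all parameters of a nested layer list
nn_params <- function(layers) {
  out <- list()
  rec <- function(x) {
    if (is.environment(x) && isTRUE(x$is_param)) out[[length(out) + 1]] <<- x
    else if (is.list(x)) for (el in x) rec(el)
  }
  rec(layers)
  out
}

n_params <- function(layers) {
  sum(vapply(nn_params(layers), function(p) length(p$value), numeric(1)))
}
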