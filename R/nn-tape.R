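# Reverse-mode automatic differentiation on a linear tape.
#
# Tensors are plain numeric arrays; batched image tensors use layout
# (C, H, W, B) so that per-channel quantities broadcast over the first
# dimension and a flattened view is directly the (C, H*W*B) matrix.
# Every op appends one node to the tape; backward() walks the tape in
# reverse creation order, so the forward program order is the topological
# order and no explicit graph sort is needed.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_push <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_leaf <- function(tape, value) ad_push(tape, value)

is_node <- function(x) is.environment(x) && !is.null(x$value)

nval <- function(x) if (is_node(x)) x$value else x

ad_acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

#' @keywords internal
ad_backward <- function(root, seed = 1) {
  tape <- root$tape
  root$grad <- array(seed, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (is_node(p) && !is.null(gs[[j]])) ad_acc(p, gs[[j]])
    }
  }
  invisible(root)
}

# ---- elementwise ----------------------------------------------------------

ad_add <- function(a, b) {
  tape <- if (is_node(a)) a$tape else b$tape
  ad_push(tape, nval(a) + nval(b), list(a, b),
          function(g) list(g, g))
}

ad_sub <- function(a, b) {
  tape <- if (is_node(a)) a$tape else b$tape
  ad_push(tape, nval(a) - nval(b), list(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  tape <- if (is_node(a)) a$tape else b$tape
  na <- is_node(a); nb <- is_node(b)
  av <- nval(a); bv <- nval(b)
  ad_push(tape, av * bv, list(a, b),
          function(g) list(if (na) g * bv else NULL,
                           if (nb) g * av else NULL))
}

ad_div <- function(a, b) {
  tape <- if (is_node(a)) a$tape else b$tape
  av <- nval(a); bv <- nval(b)
  ad_push(tape, av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_neg <- function(a) ad_push(a$tape, -a$value, list(a), function(g) list(-g))

ad_scale <- function(a, s) ad_push(a$tape, a$value * s, list(a), function(g) list(g * s))

ad_shift <- function(a, s) ad_push(a$tape, a$value + s, list(a), function(g) list(g))

ad_relu <- function(a) {
  v <- nval(a); m <- v > 0
  ad_push(a$tape, v * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-nval(a)))
  ad_push(a$tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  t <- tanh(nval(a))
  ad_push(a$tape, t, list(a), function(g) list(g * (1 - t * t)))
}

ad_softplus <- function(a) {
  v <- nval(a)
  # numerically stable log(1+exp(v))
  sp <- ifelse(v > 30, v, log1p(exp(pmin(v, 30))))
  sig <- 1 / (1 + exp(-v))
  out <- array(sp, dim = dim(v))
  ad_push(a$tape, out, list(a), function(g) list(g * sig))
}

ad_exp <- function(a) {
  e <- exp(nval(a))
  ad_push(a$tape, e, list(a), function(g) list(g * e))
}

ad_log <- function(a) {
  v <- nval(a)
  ad_push(a$tape, log(v), list(a), function(g) list(g / v))
}

ad_square <- function(a) {
  v <- nval(a)
  ad_push(a$tape, v * v, list(a), function(g) list(2 * g * v))
}

# smooth |x| = sqrt(x^2 + eps); eps keeps the gradient finite at 0
ad_abs_smooth <- function(a, eps = 1e-12) {
  v <- nval(a)
  r <- sqrt(v * v + eps)
  ad_push(a$tape, r, list(a), function(g) list(g * v / r))
}

# ---- reductions and shape ops --------------------------------------------

ad_sum <- function(a) {
  v <- nval(a); d <- dim(v)
  ad_push(a$tape, sum(v), list(a),
          function(g) list(array(as.numeric(g), dim = d)))
}

ad_mean <- function(a) {
  v <- nval(a); d <- dim(v); n <- length(v)
  ad_push(a$tape, mean(v), list(a),
          function(g) list(array(as.numeric(g) / n, dim = d)))
}

ad_reshape <- function(a, dm) {
  v <- nval(a); d0 <- dim(v)
  out <- v; dim(out) <- dm
  ad_push(a$tape, out, list(a),
          function(g) { dim(g) <- d0; list(g) })
}

# matrix product; either side may be a constant matrix (no gradient is
# computed for constant operands)
ad_matmul <- function(a, b) {
  tape <- if (is_node(a)) a$tape else b$tape
  na <- is_node(a); nb <- is_node(b)
  av <- nval(a); bv <- nval(b)
  ad_push(tape, av %*% bv, list(a, b),
          function(g) list(if (na) tcrossprod(g, bv) else NULL,
                           if (nb) crossprod(av, g) else NULL))
}

# select channels of a (C,H,W,B) tensor
ad_slice_channels <- function(a, idx) {
  v <- nval(a); d <- dim(v)
  out <- v[idx, , , , drop = FALSE]
  ad_push(a$tape, out, list(a), function(g) {
    gx <- array(0, dim = d)
    gx[idx, , , ] <- g
    list(gx)
  })
}

# concatenate (C_i,H,W,B) tensors along channels
ad_concat_channels <- function(xs) {
  tape <- NULL
  for (x in xs) if (is_node(x)) { tape <- x$tape; break }
  vals <- lapply(xs, nval)
  cs <- vapply(vals, function(v) dim(v)[1], numeric(1))
  d <- dim(vals[[1]])
  out <- array(0, dim = c(sum(cs), d[2], d[3], d[4]))
  at <- 0L
  for (v in vals) { out[at + seq_len(dim(v)[1]), , , ] <- v; at <- at + dim(v)[1] }
  offs <- cumsum(c(0, cs))
  ad_push(tape, out, xs, function(g) {
    lapply(seq_along(xs), function(j) g[offs[j] + seq_len(cs[j]), , , , drop = FALSE])
  })
}

# (E,B) -> (P,E,B): repeat over a leading axis
ad_expand_first <- function(a, P) {
  v <- nval(a); E <- nrow(v); B <- ncol(v)
  out <- array(rep(as.vector(v), each = P), dim = c(P, E, B))
  ad_push(a$tape, out, list(a), function(g) {
    list(matrix(colSums(matrix(g, P, E * B)), E, B))
  })
}

# (P,B) -> (P,E,B): repeat over the middle axis
ad_expand_mid <- function(a, E) {
  v <- nval(a); P <- nrow(v); B <- ncol(v)
  out <- array(v[, rep(seq_len(B), each = E)], dim = c(P, E, B))
  ad_push(a$tape, out, list(a), function(g) {
    ga <- aperm(array(g, c(P, E, B)), c(2, 1, 3))  # (E,P,B)
    list(array(colSums(ga), dim = c(P, B)))
  })
}

# (1,B) -> (L,B): broadcast a per-sample scalar over rows
ad_expand_rows <- function(a, L) {
  v <- nval(a); B <- ncol(v)
  out <- matrix(rep(as.vector(v), each = L), L, B)
  ad_push(a$tape, out, list(a),
          function(g) list(matrix(colSums(g), 1, B)))
}

# sum a (P,E,B) array over its first axis -> (E,B)
ad_sum_first <- function(a) {
  v <- nval(a); d <- dim(v)
  out <- colSums(matrix(v, d[1], d[2] * d[3]))
  dim(out) <- d[2:3]
  ad_push(a$tape, out, list(a), function(g) {
    list(array(rep(as.vector(g), each = d[1]), dim = d))
  })
}

# ---- optimizer ------------------------------------------------------------

# A parameter is an environment {value, m, v}; layers hold lists of them.
ad_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$is_param <- TRUE
  p$value <- value
  p$m <- value * 0
  p$v <- p$m
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bind a persistent parameter into the current tape
ad_use <- function(tape, param) {
  nd <- ad_leaf(tape, param$value)
  nd$param <- param
  nd
}

# collect gradients from bound parameter nodes and take one Adam step;
# gradients are clipped to a global norm so occasional sharp curvature of
# the count loss cannot blow up the weights
adam_step <- function(tape, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1, clip = 10) {
  gscale <- 1
  if (is.finite(clip) && clip > 0) {
    sq <- 0
    for (i in seq_len(tape$n)) {
      nd <- tape$nodes[[i]]
      if (!is.null(nd$param) && !is.null(nd$grad)) sq <- sq + sum(nd$grad^2)
    }
    gn <- sqrt(sq)
    if (is.finite(gn) && gn > clip) gscale <- clip / gn
  }
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$param) || is.null(nd$grad)) next
    p <- nd$param
    g <- nd$grad * gscale
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}
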