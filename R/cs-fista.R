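# Compressed-sensing super-resolution on 9x9 crops.
#
# The measurement operator A maps a sparse emitter lattice (u-fold
# upsampled) to the camera crop: convolve with the PSF on the fine lattice,
# then bin u x u cells into each camera pixel. FISTA minimizes
# 0.5 ||A b - y||^2 + lambda ||b||_1 with b >= 0; the same iteration is
# also available unrolled on the autodiff tape so gradients reach the
# learned per-crop lambda estimator.

#' Compressed-sensing solver configuration
#'
#' @param lambda_max upper bound of the learned shrinkage weight; the
#'   estimator output is `sigmoid(.) * lambda_max`.
#' @param n_iter maximum FISTA iterations.
#' @param tol stop when the relative objective change falls below this.
#' @return a `cs_config` list.
#' @export
cs_config <- function(lambda_max = 0.025, n_iter = 200L, tol = 1e-9) {
  stopifnot(lambda_max > 0, n_iter >= 1)
  structure(list(lambda_max = lambda_max, n_iter = as.integer(n_iter),
                 tol = tol), class = "cs_config")
}

#' Build the lattice-to-image measurement operator
#'
#' Columns of `A` are the PSF placed at each fine-lattice cell, clipped to
#' the crop, and summed into `u x u` blocks (camera pixels). A unit spike
#' therefore images to the PSF centered at the corresponding location.
#'
#' @param psf PSF kernel sampled at the fine-lattice resolution (odd size).
#' @param u integer upsampling factor (fine cells per camera pixel and
#'   axis).
#' @param size crop side in camera pixels.
#' @return a `measurement_operator` with `A` (`size^2 x (size*u)^2`), its
#'   cached `At`, the Lipschitz constant `lip` of `t(A) A`, `u`, `size`.
#' @export
build_measurement_operator <- function(psf, u, size = 9L) {
  if (u < 1) stop("u must be >= 1")
  u <- as.integer(u)
  nf <- size * u
  kh <- nrow(psf); hw <- (kh - 1L) %/% 2L
  A <- matrix(0, size * size, nf * nf)
  fine <- matrix(0, nf, nf)
  for (q in seq_len(nf * nf)) {
    qi <- (q - 1L) %% nf + 1L
    qj <- (q - 1L) %/% nf + 1L
    ri <- max(1L, qi - hw):min(nf, qi + hw)
    rj <- max(1L, qj - hw):min(nf, qj + hw)
    fine[] <- 0
    fine[ri, rj] <- psf[ri - qi + hw + 1L, rj - qj + hw + 1L]
    dim(fine) <- c(u, size, u, size)
    A[, q] <- as.vector(apply(fine, c(2, 4), sum))
    dim(fine) <- c(nf, nf)
  }
  # Lipschitz constant of t(A) A by power iteration
  v <- stats::rnorm(ncol(A))
  v <- v / sqrt(sum(v^2))
  lip <- 1
  for (i in 1:20) {
    w <- crossprod(A, A %*% v)
    lip <- sqrt(sum(w^2))
    if (lip == 0) break
    v <- w / lip
  }
  structure(list(A = A, At = t(A), lip = max(lip, 1e-12), u = u,
                 size = as.integer(size)),
            class = "measurement_operator")
}

fista_objective <- function(op, b, y, lambda) {
  r <- op$A %*% b - y
  0.5 * sum(r * r) + lambda * sum(abs(b))
}

#' FISTA sparse reconstruction of a crop
#'
#' Accelerated proximal gradient for
#' `0.5 ||A b - y||^2 + lambda ||b||_1, b >= 0` (the shrinkage step is a
#' one-sided soft threshold since emitter intensities are non-negative).
#' Returns the best-objective iterate, so the result never exceeds the
#' objective at `b = 0`.
#'
#' @param y crop image (`size x size` matrix or vector).
#' @param op a [build_measurement_operator()] result.
#' @param lambda shrinkage weight, `>= 0`.
#' @param config a [cs_config()].
#' @return fine-lattice coefficient matrix (`size*u x size*u`) with
#'   attributes `objective` and `iterations`.
#' @export
fista <- function(y, op, lambda, config = cs_config()) {
  y <- as.vector(y)
  if (!all(is.finite(y))) stop("non-finite input")
  stopifnot(lambda >= 0, length(y) == nrow(op$A))
  step <- 1 / op$lip
  L <- ncol(op$A)
  b <- numeric(L); z <- b
  tk <- 1
  best <- b; best_obj <- fista_objective(op, b, y, lambda)
  obj_prev <- best_obj
  it <- 0L
  for (k in seq_len(config$n_iter)) {
    it <- k
    g <- z - step * as.vector(op$At %*% (op$A %*% z - y))
    b_new <- pmax(g - step * lambda, 0)
    t_new <- (1 + sqrt(1 + 4 * tk * tk)) / 2
    z <- b_new + ((tk - 1) / t_new) * (b_new - b)
    b <- b_new; tk <- t_new
    obj <- fista_objective(op, b, y, lambda)
    if (obj < best_obj) { best_obj <- obj; best <- b }
    if (abs(obj_prev - obj) <= config$tol * max(1, abs(obj_prev))) break
    obj_prev <- obj
  }
  out <- matrix(best, op$size * op$u, op$size * op$u)
  attr(out, "objective") <- best_obj
  attr(out, "iterations") <- it
  out
}

# unrolled differentiable FISTA: y (P,B) constant, lambda (1,B) node
fista_unrolled <- function(tape, y, lambda, op, n_iter) {
  step <- 1 / op$lip
  L <- ncol(op$A)
  B <- ncol(y)
  b <- ad_leaf(tape, matrix(0, L, B))
  z <- b
  tk <- 1
  lam_rows <- ad_expand_rows(lambda, L)
  for (k in seq_len(n_iter)) {
    az <- ad_matmul(op$A, z)
    atr <- ad_matmul(op$At, ad_sub(az, y))
    g <- ad_sub(z, ad_scale(atr, step))
    b_new <- ad_relu(ad_sub(g, ad_scale(lam_rows, step)))
    t_new <- (1 + sqrt(1 + 4 * tk * tk)) / 2
    z <- ad_add(b_new, ad_scale(ad_sub(b_new, b), (tk - 1) / t_new))
    b <- b_new; tk <- t_new
  }
  b
}

#' Per-crop shrinkage-weight estimator network
#'
#' Three convolutional layers followed by three dense layers; the output
#' passes a sigmoid and is scaled by `lambda_max`, so
#' `lambda` is always in `(0, lambda_max)`. Dense layers are initialized
#' from a normal distribution with mean 0.5 and sd 0.3, biases from a
#' truncated normal.
#'
#' @param width convolution width.
#' @param config a [cs_config()].
#' @return a `lambda_net` list of layers.
#' @export
lambda_net <- function(width = 8L, config = cs_config()) {
  structure(list(
    c1 = layer_conv(3L, width), c2 = layer_conv(width, width),
    c3 = layer_conv(width, width),
    d1 = layer_dense(width * 81L, 32L, init = "lambda"),
    d2 = layer_dense(32L, 16L, init = "lambda"),
    d3 = layer_dense(16L, 1L, init = "lambda"),
    lambda_max = config$lambda_max), class = "lambda_net")
}

# crop batch (3,9,9,B) node -> lambda (1,B) node in (0, lambda_max)
forward_lambda <- function(tape, x, net) {
  h <- ad_relu(nn_conv(tape, x, net$c1))
  h <- ad_relu(nn_conv(tape, h, net$c2))
  h <- ad_relu(nn_conv(tape, h, net$c3))
  B <- dim(nval(h))[4]
  h <- ad_reshape(h, c(length(nval(h)) %/% B, B))
  h <- ad_relu(nn_dense(tape, h, net$d1))
  h <- ad_relu(nn_dense(tape, h, net$d2))
  ad_scale(ad_sigmoid(nn_dense(tape, h, net$d3)), net$lambda_max)
}

#' Estimate the FISTA shrinkage weight for a crop
#'
#' @param crop `9 x 9 x 3` array (or a `roi_crop`).
#' @param net a [lambda_net()].
#' @param scale intensity normalization applied to the crop before the
#'   network (detector units per unit input).
#' @return scalar `lambda` in `(0, lambda_max)`.
#' @export
estimate_lambda <- function(crop, net, scale = 1000) {
  px <- if (inherits(crop, "roi_crop")) crop$pixels else crop
  x <- aperm(array(px / scale, c(9, 9, 3, 1)), c(3, 1, 2, 4))
  tape <- ad_tape()
  out <- forward_lambda(tape, ad_leaf(tape, x), net)
  as.numeric(nval(out))
}

#' Sparsity loss of a compressed-sensing reconstruction
#'
#' `sum_i |b_i| + (s_i - n_i)^2` with `s = A b`: an L1 penalty on the
#' lattice plus the squared difference between the reimaged lattice and the
#' noiseless target, which prevents the trivial all-zero solution.
#'
#' @param b fine-lattice coefficients.
#' @param noiseless noiseless target image (camera pixels).
#' @param op the [build_measurement_operator()] used for `b`.
#' @return scalar loss.
#' @export
cs_sparsity_loss <- function(b, noiseless, op) {
  s <- op$A %*% as.vector(b)
  sum(abs(b)) + sum((as.vector(s) - as.vector(noiseless))^2)
}
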