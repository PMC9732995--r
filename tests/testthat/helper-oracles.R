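# Independent oracles and shared fixtures.

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Bessel J1 by numerical quadrature of its integral representation,
# independent of base R's besselJ
j1_quad <- function(x) {
  vapply(x, function(xx) {
    stats::integrate(function(th) cos(th - xx * sin(th)), 0, pi,
                     rel.tol = 1e-10)$value / pi
  }, numeric(1))
}

# one-level 2D Haar reference transform (plain averages/differences)
haar_ref <- function(x) {
  o <- seq(1, nrow(x), by = 2); e <- o + 1
  oc <- seq(1, ncol(x), by = 2); ec <- oc + 1
  a <- x[o, oc, drop = FALSE]; b <- x[e, oc, drop = FALSE]
  c2 <- x[o, ec, drop = FALSE]; d <- x[e, ec, drop = FALSE]
  list(LL = (a + b + c2 + d) / 2, HL = (a - b + c2 - d) / 2,
       LH = (a + b - c2 - d) / 2, HH = (a - b - c2 + d) / 2)
}

# plain proximal-gradient (ISTA) solver, batched over columns of Y
ista_oracle <- function(Y, op, lambdas, iters) {
  B <- matrix(0, ncol(op$A), ncol(Y))
  st <- 1 / op$lip
  lamm <- matrix(rep(lambdas, each = nrow(B)), nrow(B))
  for (k in seq_len(iters)) {
    B <- pmax(B - st * (op$At %*% (op$A %*% B - Y)) - st * lamm, 0)
  }
  B
}

# brute-force optimal assignment cost by exhaustive recursion (n <= 6)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  rec <- function(rowi, used, acc) {
    if (acc >= best) return()
    if (rowi > n) { best <<- acc; return() }
    for (j in seq_len(n)[!used]) {
      used[j] <- TRUE
      rec(rowi + 1, used, acc + cost[rowi, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, n), 0)
  best
}

# fixture cache shared across test files within one run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# a small batch of noisy training crops
small_crops <- function() fixture("small_crops", function() {
  make_training_crops(160, scan_config(), seed = 301)
})

# noiseless crops holding exactly one accepted emitter each
isolated_crops <- function(n = 60, seed = 302) {
  key <- paste0("iso_", n, "_", seed)
  fixture(key, function() {
    cfg <- scan_config(shot_noise = FALSE, read_noise = FALSE)
    set.seed(seed)
    out <- list()
    while (length(out) < n) {
      cs <- make_training_crops(20, cfg, seed = NA)
      out <- c(out, Filter(function(cr) nrow(cr$truth) == 1, cs))
    }
    out[seq_len(n)]
  })
}

# a clean synthetic 9x9 frame holding one binned Airy PSF at (x, y) px
synth_psf_frame <- function(x, y, radius_px = 5.4, amp = 1000) {
  cfg <- scan_config()
  amp * scanloc:::binned_airy_rows(x * cfg$s_px, y * cfg$s_px,
                                   radius_px * cfg$s_px, 0:8, cfg)
}

# the shared small measurement operator (u = 2)
op_u2 <- function() fixture("op_u2", function() {
  build_measurement_operator(airy_psf(5.4 * 2, 2L * ceiling(5.4 * 2 * 2.2) + 1L),
                             2L, 9L)
})
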