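# Quantitative evaluation: optimal localization matching, Jaccard index,
# RMSE, Fourier ring correlation.

# Hungarian algorithm (potentials form), square cost matrix.
# Returns for each row the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  assign
}

# column indexing above uses columns 2..n+1 of the (n+1)-sized workspace;
# cost is addressed with the real 1..n column index (j - 1)

#' Match predicted to true localizations
#'
#' Minimum-total-distance one-to-one assignment per frame (Hungarian
#' algorithm); pairs farther apart than the tolerance are discarded, the
#' remaining predictions count as false positives and remaining truths as
#' false negatives.
#'
#' @param pred,truth data.frames with `frame` and either `x_px`/`y_px`
#'   (pixel units) or `x`/`y`.
#' @param tolerance_nm match radius in nm.
#' @param pixel_size_nm camera pixel size.
#' @return a `match_result` list: `pairs` (data.frame `pred_idx`,
#'   `truth_idx`, `distance_nm`), `TP`, `FP`, `FN`.
#' @export
match_localisations <- function(pred, truth, tolerance_nm = 250,
                                pixel_size_nm = 100) {
  stopifnot(tolerance_nm > 0)
  gx <- function(d) if (!is.null(d$x_px)) d$x_px else d$x
  gy <- function(d) if (!is.null(d$y_px)) d$y_px else d$y
  gf <- function(d) if (!is.null(d$frame)) d$frame else rep(0L, length(gx(d)))
  px <- gx(pred) * pixel_size_nm; py <- gy(pred) * pixel_size_nm
  tx <- gx(truth) * pixel_size_nm; ty <- gy(truth) * pixel_size_nm
  pf <- gf(pred); tf <- gf(truth)
  BIG <- tolerance_nm * 1e6
  pairs <- list()
  TP <- 0L
  for (f in union(unique(pf), unique(tf))) {
    ip <- which(pf == f); it <- which(tf == f)
    np <- length(ip); nt <- length(it)
    if (np == 0 || nt == 0) next
    n <- max(np, nt)
    cost <- matrix(BIG, n, n)
    d <- sqrt(outer(px[ip], tx[it], "-")^2 + outer(py[ip], ty[it], "-")^2)
    cost[seq_len(np), seq_len(nt)] <- ifelse(d <= tolerance_nm, d, BIG)
    # dummy rows/columns are free so they never displace a valid pair
    if (np < n) cost[(np + 1):n, ] <- 0
    if (nt < n) cost[, (nt + 1):n] <- 0
    asg <- hungarian(cost)
    for (r in seq_len(np)) {
      cidx <- asg[r]
      if (cidx <= nt && d[r, cidx] <= tolerance_nm) {
        TP <- TP + 1L
        pairs[[length(pairs) + 1]] <- data.frame(
          pred_idx = ip[r], truth_idx = it[cidx], distance_nm = d[r, cidx])
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pred_idx = integer(), truth_idx = integer(),
               distance_nm = numeric())
  structure(list(pairs = pairs, TP = TP,
                 FP = length(px) - TP, FN = length(tx) - TP),
            class = "match_result")
}

#' Jaccard index of a match result
#'
#' `TP / (TP + FP + FN)`; 1 when all three are zero.
#'
#' @param m a `match_result`.
#' @return scalar in `[0, 1]`.
#' @export
jaccard_index <- function(m) {
  den <- m$TP + m$FP + m$FN
  if (den == 0) return(1)
  m$TP / den
}

#' Localization RMSE of a match result
#'
#' Root mean squared 2D Euclidean distance over matched pairs, in nm.
#'
#' @param m a `match_result`.
#' @return scalar nm; `NaN` (with a warning) when there are no pairs.
#' @export
rmse <- function(m) {
  if (m$TP == 0) {
    warning("no matched pairs; RMSE undefined")
    return(NaN)
  }
  sqrt(mean(m$pairs$distance_nm^2))
}

#' Fourier ring correlation
#'
#' Correlation of the Fourier spectra of two renderings over rings of
#' constant spatial frequency:
#' `FRC(r) = Re sum F1 F2* / sqrt(sum |F1|^2 sum |F2|^2)` per ring. The
#' summary coefficient is the mean of the curve over rings up to Nyquist;
#' the full curve is returned so other reductions can be recomputed.
#'
#' @param I1,I2 images of identical square shape.
#' @return list: `curve` (data.frame `ring`, `frc`), `mean`.
#' @export
frc <- function(I1, I2) {
  if (!all(dim(I1) == dim(I2))) stop("shape mismatch")
  n <- nrow(I1)
  F1 <- stats::fft(I1); F2 <- stats::fft(I2)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kk <- sqrt(outer(k^2, k^2, "+"))
  ring <- round(kk)
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2; d2 <- Mod(F2)^2
  rings <- 1:(n %/% 2 - 1)
  vals <- vapply(rings, function(r) {
    sel <- ring == r
    s1 <- sum(d1[sel]); s2 <- sum(d2[sel])
    if (s1 == 0 || s2 == 0) return(0)
    sum(num[sel]) / sqrt(s1 * s2)
  }, numeric(1))
  list(curve = data.frame(ring = rings, frc = vals), mean = mean(vals))
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

#' FRC between two halves of a localization table
#'
#' Splits the table at the median frame, renders both halves as 2D
#' histograms on a common extent, zero-pads to a square power of two and
#' computes the FRC.
#'
#' @param table localization table.
#' @param bin_nm rendering bin size (nm).
#' @param pixel_size_nm camera pixel size.
#' @return as [frc()].
#' @export
frc_halves <- function(table, bin_nm = 10, pixel_size_nm = 100) {
  med <- stats::median(table$frame)
  h1 <- table[table$frame <= med, ]
  h2 <- table[table$frame > med, ]
  ext <- c(0, max(table$x_px) * pixel_size_nm + bin_nm,
           0, max(table$y_px) * pixel_size_nm + bin_nm)
  r1 <- render_histogram(h1, bin_nm, pixel_size_nm, ext)
  r2 <- render_histogram(h2, bin_nm, pixel_size_nm, ext)
  n <- next_pow2(max(dim(r1)))
  p1 <- matrix(0, n, n); p2 <- matrix(0, n, n)
  p1[seq_len(nrow(r1)), seq_len(ncol(r1))] <- r1
  p2[seq_len(nrow(r2)), seq_len(ncol(r2))] <- r2
  frc(p1, p2)
}

#' Evaluate predictions against ground truth
#'
#' @param pred,truth localization tables.
#' @param tolerance_nm match radius (nm).
#' @param pixel_size_nm camera pixel size.
#' @return list `JI`, `RMSE`, `match`.
#' @export
evaluate_predictions <- function(pred, truth, tolerance_nm = 250,
                                 pixel_size_nm = 100) {
  m <- match_localisations(pred, truth, tolerance_nm, pixel_size_nm)
  list(JI = jaccard_index(m),
       RMSE = if (m$TP > 0) rmse(m) else NaN,
       match = m)
}
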