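# Deterministic extraction of localizations from the feature space.
#
# Probability mass of an emitter near a pixel edge spreads over adjacent
# pixels; summing each pixel's 4-neighborhood with a cross-shaped filter
# recovers the total mass of such split formations before thresholding.

#' Cross-shaped probability filter
#'
#' Convolution with `F = [[0,1,0],[1,1,1],[0,1,0]]`, zero-padded borders:
#' every pixel receives its own value plus its 4-neighbors'.
#'
#' @param p_map 2D probability map.
#' @return filtered map of the same shape.
#' @export
cross_filter <- function(p_map) {
  n1 <- nrow(p_map); n2 <- ncol(p_map)
  pad <- matrix(0, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- p_map
  pad[2:(n1 + 1), 2:(n2 + 1)] +
    pad[1:n1, 2:(n2 + 1)] + pad[3:(n1 + 2), 2:(n2 + 1)] +
    pad[2:(n1 + 1), 1:n2] + pad[2:(n1 + 1), 3:(n2 + 2)]
}

cross_cells <- function(r, cc, n1, n2) {
  cand <- rbind(c(r, cc), c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
  cand[cand[, 1] >= 1 & cand[, 1] <= n1 & cand[, 2] >= 1 & cand[, 2] <= n2, ,
       drop = FALSE]
}

#' Extract localizations from a feature space
#'
#' Every pixel whose probability exceeds `t_cls` seeds a cross formation.
#' If the cross-filtered value exceeds `t_re`, the highest-probability
#' pixel of the formation is accepted; if it exceeds `2 t_re`, the
#' second-highest is accepted as well. Each accepted pixel `(r, c)` emits
#' a localization at `(origin_col + c + 0.5 + dx, origin_row + r + 0.5 +
#' dy)` with intensity and uncertainties read at that pixel; overlapping
#' formations are deduplicated by pixel identity.
#'
#' @param fs feature-space array `(H, W, 8)` from [predict_features()].
#' @param origin `(frame, row, col)` of the crop corner (0-based).
#' @param t_cls classifier gate on single pixels.
#' @param t_re acceptance threshold on the cross sum.
#' @return data.frame `frame`, `x_px`, `y_px`, `photons`, `sigma_x`,
#'   `sigma_y`, `sigma_N`, `p_score` (0-based frame, pixel units).
#' @export
extract_localisations <- function(fs, origin = c(frame = 0L, row = 0L, col = 0L),
                                  t_cls = 0.3, t_re = 0.7) {
  stopifnot(t_cls > 0, t_cls <= 1)
  p <- fs[, , 1]
  n1 <- nrow(p); n2 <- ncol(p)
  cf <- cross_filter(p)
  accept <- matrix(FALSE, n1, n2)
  seeds <- which(p > t_cls, arr.ind = TRUE)
  if (nrow(seeds)) {
    seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(seeds))) {
      r <- seeds[k, 1]; cc <- seeds[k, 2]
      if (cf[r, cc] <= t_re) next
      cells <- cross_cells(r, cc, n1, n2)
      vals <- p[cells]
      ord <- order(-vals, cells[, 1], cells[, 2])  # ties row-major
      accept[cells[ord[1], 1], cells[ord[1], 2]] <- TRUE
      if (cf[r, cc] > 2 * t_re && length(ord) >= 2) {
        accept[cells[ord[2], 1], cells[ord[2], 2]] <- TRUE
      }
    }
  }
  idx <- which(accept, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      photons = numeric(), sigma_x = numeric(),
                      sigma_y = numeric(), sigma_N = numeric(),
                      p_score = numeric()))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  r <- idx[, 1]; cc <- idx[, 2]
  lin <- cbind(r, cc)
  data.frame(
    frame = as.integer(origin[["frame"]]),
    x_px = origin[["col"]] + (cc - 1) + 0.5 + fs[, , 2][lin],
    y_px = origin[["row"]] + (r - 1) + 0.5 + fs[, , 3][lin],
    photons = fs[, , 4][lin],
    sigma_x = fs[, , 5][lin],
    sigma_y = fs[, , 6][lin],
    sigma_N = fs[, , 7][lin],
    p_score = fs[, , 1][lin])
}

#' Apply a global linear drift correction
#'
#' @param table localization table with `frame`, `x_px`, `y_px`.
#' @param vx,vy drift velocity in pixels per frame.
#' @return corrected table (`x' = x - vx * frame`).
#' @export
apply_linear_drift <- function(table, vx, vy) {
  table$x_px <- table$x_px - vx * table$frame
  table$y_px <- table$y_px - vy * table$frame
  table
}

#' Render a 2D localization histogram
#'
#' @param table localization table (`x_px`, `y_px` in pixel units).
#' @param bin_nm histogram bin size in nm.
#' @param pixel_size_nm camera pixel size.
#' @param extent `c(xmin, xmax, ymin, ymax)` in nm; derived from the data
#'   when `NULL`.
#' @return count matrix (rows = y bins, cols = x bins) with `extent`
#'   attribute.
#' @export
render_histogram <- function(table, bin_nm = 10, pixel_size_nm = 100,
                             extent = NULL) {
  stopifnot(bin_nm > 0)
  x <- table$x_px * pixel_size_nm
  y <- table$y_px * pixel_size_nm
  if (is.null(extent)) {
    if (!length(x)) extent <- c(0, bin_nm, 0, bin_nm)
    else extent <- c(0, max(x) + bin_nm, 0, max(y) + bin_nm)
  }
  nx <- max(1L, ceiling((extent[2] - extent[1]) / bin_nm))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / bin_nm))
  img <- matrix(0, ny, nx)
  ix <- floor((x - extent[1]) / bin_nm) + 1L
  iy <- floor((y - extent[3]) / bin_nm) + 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  for (k in which(ok)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 1
  attr(img, "extent") <- extent
  img
}

#' Write a localization table in ThunderSTORM CSV dialect
#'
#' Quoted header `"frame","x [nm]","y [nm]","intensity [photon]",
#' "uncertainty_x [nm]","uncertainty_y [nm]"`; frames 1-based,
#' coordinates in nm.
#'
#' @param table localization table from [extract_localisations()].
#' @param path output path.
#' @param pixel_size_nm camera pixel size.
#' @export
write_thunderstorm_csv <- function(table, path, pixel_size_nm = 100) {
  out <- data.frame(
    frame = table$frame + 1L,
    x = table$x_px * pixel_size_nm,
    y = table$y_px * pixel_size_nm,
    intensity = table$photons,
    ux = table$sigma_x * pixel_size_nm,
    uy = table$sigma_y * pixel_size_nm)
  names(out) <- c("frame", "x [nm]", "y [nm]", "intensity [photon]",
                  "uncertainty_x [nm]", "uncertainty_y [nm]")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table from ThunderSTORM CSV
#'
#' @param path CSV path.
#' @param pixel_size_nm camera pixel size used to convert nm back to
#'   pixels.
#' @return localization table with 0-based `frame`, pixel-unit
#'   coordinates.
#' @export
read_thunderstorm_csv <- function(path, pixel_size_nm = 100) {
  d <- utils::read.csv(path, check.names = FALSE)
  data.frame(frame = d[["frame"]] - 1L,
             x_px = d[["x [nm]"]] / pixel_size_nm,
             y_px = d[["y [nm]"]] / pixel_size_nm,
             photons = d[["intensity [photon]"]],
             sigma_x = d[["uncertainty_x [nm]"]] / pixel_size_nm,
             sigma_y = d[["uncertainty_y [nm]"]] / pixel_size_nm)
}
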