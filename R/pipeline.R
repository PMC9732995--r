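# Training loop, dataset management and end-to-end inference.

#' Build a simulated training/evaluation dataset
#'
#' `n_batches` batches of `subbatches x crops_per_subbatch` crops; the
#' read-noise sigma is drawn once per batch from the configured range,
#' shot noise is independent per crop. Three of the four sub-batches go to
#' the training split, one to evaluation.
#'
#' @param config a [scan_config()].
#' @param n_batches number of batches.
#' @param crops_per_subbatch crops per sub-batch.
#' @param subbatches sub-batches per batch (last one is the eval split).
#' @param seed RNG seed.
#' @return list `train`, `eval` (crop lists), `sigmas`.
#' @export
build_dataset <- function(config, n_batches = 40L, crops_per_subbatch = 1000L,
                          subbatches = 4L, seed = config$seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  train <- list(); eval <- list(); sigmas <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    sigmas[b] <- stats::runif(1, config$noise_sigma_range[1],
                              config$noise_sigma_range[2])
    crops <- make_training_crops(subbatches * crops_per_subbatch, config,
                                 sigma = sigmas[b], seed = NA)
    n_tr <- (subbatches - 1L) * crops_per_subbatch
    train <- c(train, crops[seq_len(n_tr)])
    eval <- c(eval, crops[(n_tr + 1L):length(crops)])
  }
  list(train = train, eval = eval, sigmas = sigmas)
}

#' Evaluate a fitter on ground-truth crops
#'
#' Predicts feature spaces, extracts localizations and matches them to the
#' crop ground truth.
#'
#' @param model a [fitter_net()].
#' @param crops list of `roi_crop` with `truth`.
#' @param t_cls,t_re extraction thresholds.
#' @param tolerance_nm match radius (nm).
#' @param pixel_size_nm camera pixel size.
#' @return list `JI`, `RMSE`, `pred`, `truth`.
#' @export
evaluate_crops <- function(model, crops, t_cls = 0.3, t_re = 0.7,
                           tolerance_nm = 250, pixel_size_nm = 100) {
  fss <- predict_features(model, crops)
  pred <- list(); truth <- list()
  for (i in seq_along(crops)) {
    loc <- extract_localisations(fss[[i]],
                                 origin = c(frame = i - 1L, row = 0L, col = 0L),
                                 t_cls = t_cls, t_re = t_re)
    if (nrow(loc)) pred[[length(pred) + 1]] <- loc
    tr <- crops[[i]]$truth
    if (nrow(tr)) {
      truth[[length(truth) + 1]] <- data.frame(frame = i - 1L, x_px = tr$x,
                                               y_px = tr$y)
    }
  }
  empty <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric())
  pred <- if (length(pred)) do.call(rbind, pred) else empty
  truth <- if (length(truth)) do.call(rbind, truth) else empty
  m <- match_localisations(pred, truth, tolerance_nm, pixel_size_nm)
  list(JI = jaccard_index(m),
       RMSE = if (m$TP > 0) rmse(m) else NaN,
       pred = pred, truth = truth)
}

bn_states <- function(layers) {
  out <- list()
  rec <- function(x) {
    if (is.list(x)) {
      if (identical(x$type, "bn")) {
        for (k in sort(ls(x$states))) out[[length(out) + 1]] <<- x$states[[k]]
      } else for (el in x) rec(el)
    }
  }
  rec(layers)
  out
}

snapshot_params <- function(model) {
  list(params = lapply(nn_params(model$layers), function(p) p$value),
       bn = lapply(bn_states(model$layers),
                   function(s) list(mean = s$mean, var = s$var)))
}

restore_params <- function(model, snap) {
  ps <- nn_params(model$layers)
  for (i in seq_along(ps)) ps[[i]]$value <- snap$params[[i]]
  st <- bn_states(model$layers)
  for (i in seq_len(min(length(st), length(snap$bn)))) {
    st[[i]]$mean <- snap$bn[[i]]$mean
    st[[i]]$var <- snap$bn[[i]]$var
  }
  invisible(model)
}

#' Train a fitter network
#'
#' Adam on the composite localization + count + background loss. Every
#' `eval_every` steps the validation loss, Jaccard index and RMSE are
#' computed on (a subsample of) the evaluation split and logged; the
#' parameters with the best validation loss are kept and restored at the
#' end. A non-finite training loss aborts with the last good parameters.
#'
#' @param model a [fitter_net()] (modified in place and returned).
#' @param train_crops,eval_crops crop lists from [build_dataset()] or
#'   [make_training_crops()].
#' @param steps optimizer steps.
#' @param batch_size crops per step.
#' @param lr Adam learning rate.
#' @param eval_every evaluation cadence in steps.
#' @param eval_max at most this many eval crops per evaluation cycle.
#' @param log_path optional CSV path for the training log.
#' @param component_log_path optional CSV path logging the individual loss
#'   components (`step`, `loc`, `count`, `bg`) per evaluation cycle.
#' @param verbose print evaluation rows.
#' @return list `model`, `log` (data.frame `step`, `loss`, `val_loss`,
#'   `JI`, `RMSE`).
#' @export
train_fitter <- function(model, train_crops, eval_crops = list(),
                         steps = 2000L, batch_size = 32L, lr = 1e-4,
                         eval_every = 150L, eval_max = 200L,
                         log_path = NULL, component_log_path = NULL,
                         verbose = FALSE) {
  scale <- model$cfg$scale
  X <- crops_to_tensor(train_crops, scale)
  log <- data.frame(step = integer(), loss = numeric(), val_loss = numeric(),
                    JI = numeric(), RMSE = numeric())
  clog <- data.frame(step = integer(), loc = numeric(), count = numeric(),
                     bg = numeric())
  best_val <- Inf
  best_snap <- snapshot_params(model)
  last_good <- best_snap
  ema_loss <- NA
  ev_idx <- if (length(eval_crops)) {
    seq_len(min(length(eval_crops), eval_max))
  } else integer()
  for (st in seq_len(steps)) {
    idx <- sample.int(length(train_crops), min(batch_size, length(train_crops)))
    tape <- ad_tape()
    x <- ad_leaf(tape, X[, , , idx, drop = FALSE])
    x$is_input <- TRUE
    raw <- net_forward(tape, model, x, training = TRUE)
    act <- activations_tape(raw)
    gtb <- prepare_gt_batch(train_crops[idx], scale)
    ls <- loss_tape(tape, act, gtb)
    cur <- nval(ls$total)
    if (!is.finite(cur)) {
      warning("non-finite training loss at step ", st,
              "; restoring last good parameters")
      restore_params(model, last_good)
      break
    }
    ad_backward(ls$total)
    adam_step(tape, lr = lr, t = st)
    last_good <- snapshot_params(model)
    ema_loss <- if (is.na(ema_loss)) cur else 0.95 * ema_loss + 0.05 * cur
    if (st %% eval_every == 0 && length(ev_idx)) {
      vl <- validation_loss(model, eval_crops[ev_idx])
      ev <- evaluate_crops(model, eval_crops[ev_idx])
      log <- rbind(log, data.frame(step = st, loss = ema_loss, val_loss = vl,
                                   JI = ev$JI, RMSE = ev$RMSE))
      clog <- rbind(clog, data.frame(step = st, loc = ls$parts[["loc"]],
                                     count = ls$parts[["count"]],
                                     bg = ls$parts[["bg"]]))
      if (verbose) {
        message(sprintf("step %d loss %.4f val %.4f JI %.3f RMSE %.1f",
                        st, ema_loss, vl, ev$JI, ev$RMSE))
      }
      if (is.finite(vl) && vl < best_val) {
        best_val <- vl
        best_snap <- snapshot_params(model)
      }
    }
  }
  if (is.finite(best_val)) restore_params(model, best_snap)
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  if (!is.null(component_log_path)) {
    utils::write.csv(clog, component_log_path, row.names = FALSE)
  }
  list(model = model, log = log)
}

#' Validation loss on crops
#'
#' Composite loss in inference mode (running batch-norm statistics).
#'
#' @param model a [fitter_net()].
#' @param crops crop list with ground truth.
#' @return scalar.
#' @export
validation_loss <- function(model, crops) {
  tape <- ad_tape()
  x <- ad_leaf(tape, crops_to_tensor(crops, model$cfg$scale))
  x$is_input <- TRUE
  raw <- net_forward(tape, model, x, training = FALSE)
  act <- activations_tape(raw)
  gtb <- prepare_gt_batch(crops, model$cfg$scale)
  nval(loss_tape(tape, act, gtb)$total)
}

#' Save / load a fitter checkpoint
#'
#' The checkpoint is an RDS snapshot of the model (architecture
#' configuration, weights, batch-norm statistics, measurement operator).
#'
#' @param model a `fitter_net`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the restored `fitter_net`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "fitter_net"))
  m
}

#' Run the full reconstruction pipeline on a frame stack
#'
#' Per frame: wavelet denoising, local-maximum detection, 9x9x3 ROI
#' cropping with temporal context, fitter forward pass, threshold-based
#' extraction, and assembly into a global localization table. Candidates
#' detected from overlapping ROIs are deduplicated per pixel, keeping the
#' highest-probability row.
#'
#' @param input TIFF path, `s x s x n` array, or `frame_stack`.
#' @param model a [fitter_net()].
#' @param bank [filter_bank()] used for denoising before peak detection.
#' @param threshold peak-detection threshold (default: robust per-frame).
#' @param t_cls,t_re extraction thresholds.
#' @param merge_px duplicate-suppression radius in pixels.
#' @return localization table (0-based `frame`, pixel-unit coordinates).
#' @export
infer_stack <- function(input, model, bank = filter_bank(),
                        threshold = NULL, t_cls = 0.3, t_re = 0.7,
                        merge_px = 1.2) {
  frames <- if (is.character(input)) read_stack_tiff(input)
  else if (inherits(input, "frame_stack")) input$frames
  else input
  nf <- dim(frames)[3]
  out <- list()
  for (f in seq_len(nf)) {
    den <- wavelet_denoise(frames[, , f], bank)
    pk <- detect_peaks(den, threshold)
    if (!nrow(pk)) next
    pk$frame <- f - 1L
    crops <- crop_rois(frames, pk)
    fss <- predict_features(model, crops)
    for (i in seq_along(crops)) {
      loc <- extract_localisations(fss[[i]], crops[[i]]$origin,
                                   t_cls = t_cls, t_re = t_re)
      if (nrow(loc)) out[[length(out) + 1]] <- loc
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      photons = numeric(), sigma_x = numeric(),
                      sigma_y = numeric(), sigma_N = numeric(),
                      p_score = numeric()))
  }
  tab <- do.call(rbind, out)
  # overlapping ROIs re-detect the same emitter at slightly different
  # pixels; suppress duplicates within merge_px per frame, keeping the
  # highest-probability row
  tab <- tab[order(tab$frame, -tab$p_score), ]
  keep <- logical(nrow(tab))
  for (f in unique(tab$frame)) {
    idx <- which(tab$frame == f)
    taken_x <- numeric(0); taken_y <- numeric(0)
    for (i in idx) {
      if (length(taken_x)) {
        d2 <- (tab$x_px[i] - taken_x)^2 + (tab$y_px[i] - taken_y)^2
        if (min(d2) < merge_px^2) next
      }
      keep[i] <- TRUE
      taken_x <- c(taken_x, tab$x_px[i]); taken_y <- c(taken_y, tab$y_px[i])
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$frame, tab$y_px, tab$x_px), ]
  rownames(tab) <- NULL
  tab
}
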